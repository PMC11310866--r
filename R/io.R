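#' Read / write gene-by-sample matrices as TSV
#'
#' Matrices are stored genes-in-rows, samples-in-columns (the dominant omics
#' convention): first column `gene_id`, header row of sample ids. A heuristic
#' warns when a file looks transposed (many more columns than rows while the
#' column names look like gene symbols); `transpose = TRUE` overrides the
#' orientation explicitly.
#'
#' @param path file path.
#' @param transpose read the file as samples-in-rows and flip it.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, transpose = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  check_matrix(m, basename(path))
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix to write.
#' @param id_col name for the first column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Tab-separated: set name, description (may be blank), then member genes.
#' Reading delegates to [fgsea::gmtPathways()].
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  assert_that(!anyDuplicated(names(sets)), "duplicate set names in GMT")
  assert_that(all(lengths(sets) > 0), "empty gene set in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  assert_that(length(names(sets)) == length(sets) && !anyDuplicated(names(sets)),
              "sets must be uniquely named")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write clinical survival tables
#'
#' Columns: sample, time, event, and optionally purity and true_label.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  assert_that(all(c("sample", "time", "event") %in% colnames(df)),
              "clinical table needs sample/time/event columns")
  assert_that(!anyDuplicated(df$sample), "duplicate sample ids")
  assert_that(all(df$time > 0), "survival times must be positive")
  assert_that(all(df$event %in% c(0, 1)), "event flags must be 0/1")
  df
}

#' @rdname read_clinical_tsv
#' @param df clinical data.frame.
#' @export
write_clinical_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
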