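#' K-group log-rank test
#'
#' Observed-vs-expected events over the pooled risk sets at each distinct
#' event time, chi-square on K-1 df (delegates to [survival::survdiff()]).
#'
#' @param survival data.frame with `time` and `event` columns.
#' @param groups group label per row (>= 2 groups).
#' @return List: `chisq`, `df`, `p`, `n_events`.
#' @export
logrank_test <- function(survival, groups) {
  assert_that(all(c("time", "event") %in% colnames(survival)),
              "survival table needs time/event columns")
  assert_that(all(survival$time > 0), "times must be positive")
  assert_that(all(survival$event %in% c(0, 1)), "events must be 0/1")
  g <- as.factor(groups)
  assert_that(nlevels(g) >= 2, "need >= 2 groups")
  assert_that(length(g) == nrow(survival), "one group per subject required")
  if (sum(survival$event) == 0)
    stop("log-rank undefined: zero events", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(survival$time, survival$event) ~ g)
  df <- length(sd_fit$n) - 1
  list(chisq = sd_fit$chisq, df = df,
       p = pchisq(sd_fit$chisq, df = df, lower.tail = FALSE),
       n_events = sum(survival$event))
}

#' Kruskal-Wallis test with degenerate-input handling
#'
#' Rank-based H with tie correction and chi-square p on K-1 df (delegates to
#' [stats::kruskal.test()]); when every value is tied the statistic is 0 and
#' p = 1, with a warning.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups).
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- as.factor(groups)
  assert_that(nlevels(g) >= 2, "need >= 2 groups")
  assert_that(length(values) == length(g), "one group per value required")
  if (length(unique(values)) == 1) {
    warning("all values tied: H = 0, p = 1")
    return(list(H = 0, df = nlevels(g) - 1, p = 1))
  }
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Kruskal-Wallis across multiple endpoints with BH adjustment
#'
#' @param value_matrix endpoints-by-samples matrix.
#' @param groups group label per sample.
#' @return data.frame: endpoint, H, p, q, stars.
#' @export
kruskal_wallis_table <- function(value_matrix, groups) {
  res <- t(apply(value_matrix, 1, function(v) {
    k <- kruskal_wallis(v, groups)
    c(H = k$H, p = k$p)
  }))
  data.frame(endpoint = rownames(value_matrix), H = res[, "H"], p = res[, "p"],
             q = bh_adjust(res[, "p"]), stars = signif_stars(res[, "p"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance asterisks
#'
#' The conventional annotation: * p<0.05, ** p<0.01, *** p<0.001,
#' **** p<0.0001.
#' @param p numeric p-values.
#' @return Character vector of stars ("ns" above 0.05).
#' @export
signif_stars <- function(p) {
  cut(p, c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
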