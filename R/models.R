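# Model competition over five multi-class families and the deployable
# classifier. The cross-platform contract: every cohort (training or
# incoming) is standardized per-gene by its own median and MAD before the
# model sees it, which makes predictions invariant to per-gene affine
# rescaling of a cohort's expression.

#' Per-cohort median/MAD standardization
#'
#' @param X genes-by-samples matrix.
#' @return Standardized matrix; genes with zero MAD fall back to sd, then to
#'   leaving the centered values unscaled.
#' @export
standardize_cohort <- function(X) {
  med <- apply(X, 1, median)
  scl <- apply(X, 1, mad)
  zero <- scl == 0
  if (any(zero)) scl[zero] <- apply(X[zero, , drop = FALSE], 1, sd)
  scl[scl == 0] <- 1
  (X - med) / scl
}

fit_family <- function(family, Xtr, ytr, seed = 1L) {
  # Xtr: samples x genes (standardized); ytr factor
  switch(family,
    svm_linear = {
      m <- e1071::svm(x = Xtr, y = ytr, kernel = "linear", cost = 1,
                      probability = TRUE)
      list(family = family, model = m, levels = levels(ytr))
    },
    random_forest = {
      m <- ranger::ranger(x = as.data.frame(Xtr), y = ytr, num.trees = 300,
                          probability = TRUE, seed = seed, num.threads = 1)
      list(family = family, model = m, levels = levels(ytr))
    },
    knn = {
      k <- max(3L, min(11L, min(table(ytr))))
      list(family = family, X = Xtr, y = ytr, k = k, levels = levels(ytr))
    },
    multinomial_glmnet = {
      m <- glmnet::cv.glmnet(Xtr, ytr, family = "multinomial", alpha = 0,
                             nfolds = 5, type.multinomial = "grouped")
      list(family = family, model = m, levels = levels(ytr))
    },
    xgboost = {
      d <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr) - 1L)
      m <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                            num_class = nlevels(ytr),
                                            max_depth = 3, eta = 0.3,
                                            nthread = 1, verbosity = 0),
                              data = d, nrounds = 80)
      list(family = family, model = m, levels = levels(ytr))
    },
    stop("unknown model family: ", family)
  )
}

predict_posterior <- function(fit, Xte) {
  lv <- fit$levels
  post <- switch(fit$family,
    svm_linear = {
      p <- attr(predict(fit$model, Xte, probability = TRUE), "probabilities")
      p[, lv, drop = FALSE]
    },
    random_forest = {
      p <- predict(fit$model, data = as.data.frame(Xte), num.threads = 1)$predictions
      p[, lv, drop = FALSE]
    },
    knn = {
      D <- as.matrix(dist(rbind(fit$X, Xte)))
      ntr <- nrow(fit$X)
      p <- t(apply(D[(ntr + 1):(ntr + nrow(Xte)), seq_len(ntr), drop = FALSE], 1,
                   function(dr) {
                     nn <- order(dr)[seq_len(fit$k)]
                     tab <- table(factor(fit$y[nn], levels = lv))
                     as.numeric(tab) / fit$k
                   }))
      colnames(p) <- lv
      p
    },
    multinomial_glmnet = {
      p <- predict(fit$model, Xte, s = "lambda.min", type = "response")[, , 1]
      if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
      p[, lv, drop = FALSE]
    },
    xgboost = {
      p <- predict(fit$model, xgboost::xgb.DMatrix(Xte))
      if (is.null(dim(p))) p <- matrix(p, ncol = length(lv), byrow = TRUE)
      colnames(p) <- lv
      p
    }
  )
  post / rowSums(post)
}

#' Cross-validated competition of five classifier families
#'
#' Evaluates linear-kernel SVM, random forest, k-nearest-neighbour, penalized
#' multinomial regression, and gradient-boosted trees over `n_repeats x
#' folds` shuffled stratified train/test splits (train fraction
#' `1 - test_frac`). Metrics per split: balanced accuracy, one-vs-rest macro
#' AUROC, macro AUPRC. The winner has the highest mean balanced accuracy,
#' ties broken by AUROC then AUPRC. All split assignments are seeded.
#'
#' @param X_panel genes-by-samples matrix restricted to the panel.
#' @param y subtype labels.
#' @param model_space families to compete (default all five).
#' @param n_repeats,folds repeats and splits per repeat (default 5 x 10).
#' @param test_frac held-out fraction per split (default 0.2).
#' @param seed master seed.
#' @return List: `metrics` (long data.frame), `summary` (per-family means),
#'   `winner`.
#' @export
model_competition <- function(X_panel, y,
                              model_space = c("svm_linear", "random_forest",
                                              "knn", "multinomial_glmnet",
                                              "xgboost"),
                              n_repeats = 5L, folds = 10L, test_frac = 0.2,
                              seed = 1L) {
  y <- as.factor(y)
  assert_that(min(table(y)) >= 5, "need >= 5 samples per class")
  res <- list()
  split_id <- 0L
  for (rep_i in seq_len(n_repeats)) {
    for (f in seq_len(folds)) {
      split_id <- split_id + 1L
      set.seed(derive_seed(seed, split_id))
      te <- stratified_subsample(y, test_frac)
      tr <- setdiff(seq_along(y), te)
      if (length(unique(y[tr])) < nlevels(y))
        stop("stratification error: class absent from a training split", call. = FALSE)
      # both splits come from one cohort: standardization parameters are fit
      # on the training portion only (no leakage, one shared scale)
      med <- apply(X_panel[, tr, drop = FALSE], 1, median)
      scl <- apply(X_panel[, tr, drop = FALSE], 1, mad)
      zero <- scl == 0
      if (any(zero)) scl[zero] <- apply(X_panel[zero, tr, drop = FALSE], 1, sd)
      scl[scl == 0] <- 1
      Xtr <- t((X_panel[, tr, drop = FALSE] - med) / scl)
      Xte <- t((X_panel[, te, drop = FALSE] - med) / scl)
      for (fam in model_space) {
        fit <- fit_family(fam, Xtr, droplevels(y[tr]), seed = derive_seed(seed, split_id + 100000L))
        post <- predict_posterior(fit, Xte)
        pred <- colnames(post)[max.col(post, ties.method = "first")]
        res[[length(res) + 1L]] <- data.frame(
          family = fam, repeat_id = rep_i, fold = f,
          balanced_accuracy = balanced_accuracy(pred, y[te]),
          auroc = macro_auroc(post, y[te]),
          auprc = macro_auprc(post, y[te]), stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, res)
  summary <- aggregate(cbind(balanced_accuracy, auroc, auprc) ~ family,
                       data = metrics, FUN = mean)
  summary <- summary[order(-summary$balanced_accuracy, -summary$auroc,
                           -summary$auprc), ]
  rownames(summary) <- NULL
  list(metrics = metrics, summary = summary, winner = summary$family[1])
}

#' Train the deployable subtype classifier
#'
#' Fits the chosen family on the median/MAD-standardized training cohort
#' restricted to the panel genes.
#'
#' @param X_panel genes-by-samples training matrix (panel genes only).
#' @param y subtype labels.
#' @param family one of the five competition families (default winner of a
#'   prior [model_competition()], typically "svm_linear").
#' @param seed RNG seed for stochastic families.
#' @param cv_metrics optional metric table to store alongside the model.
#' @return Object of class `emtsub_classifier`.
#' @export
train_final <- function(X_panel, y, family = "svm_linear", seed = 1L,
                        cv_metrics = NULL) {
  y <- as.factor(y)
  Xtr <- t(standardize_cohort(X_panel))
  fit <- fit_family(family, Xtr, y, seed = seed)
  out <- list(panel = rownames(X_panel), family = family, fit = fit,
              levels = levels(y), cv_metrics = cv_metrics,
              standardization = "per-cohort per-gene median/MAD")
  class(out) <- "emtsub_classifier"
  out
}

#' Predict subtypes for a new cohort
#'
#' The incoming cohort is standardized per-cohort per-gene (median/MAD)
#' before prediction; panel genes missing from the cohort (at most 10%) are
#' imputed at standardized 0 and their count reported.
#'
#' @param object an `emtsub_classifier`.
#' @param expr_new genes-by-samples expression matrix of the new cohort.
#' @param ... unused.
#' @return List: `labels` (factor), `posterior` (samples x classes, rows sum
#'   to 1), `n_missing_genes`.
#' @export
predict.emtsub_classifier <- function(object, expr_new, ...) {
  check_matrix(expr_new, "new cohort")
  present <- intersect(object$panel, rownames(expr_new))
  coverage <- length(present) / length(object$panel)
  if (coverage < 0.9) {
    stop(sprintf("coverage error: only %.0f%% of panel genes present; absent: %s",
                 100 * coverage,
                 paste(setdiff(object$panel, rownames(expr_new)), collapse = ", ")),
         call. = FALSE)
  }
  Z <- matrix(0, length(object$panel), ncol(expr_new),
              dimnames = list(object$panel, colnames(expr_new)))
  Z[present, ] <- standardize_cohort(expr_new[present, , drop = FALSE])
  n_missing <- length(object$panel) - length(present)
  if (n_missing > 0)
    message(n_missing, " missing panel gene(s) imputed at standardized 0")
  post <- predict_posterior(object$fit, t(Z))
  labels <- factor(colnames(post)[max.col(post, ties.method = "first")],
                   levels = object$levels)
  names(labels) <- colnames(expr_new)
  rownames(post) <- colnames(expr_new)
  list(labels = labels, posterior = post, n_missing_genes = n_missing)
}
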