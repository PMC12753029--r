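# One-vs-all outcome prediction: class-weighted linear SVMs under nested
# cross-validation (leave-one-out outer loop, stratified k-fold inner loop for
# C selection), evaluated by balanced accuracy with bootstrap 95% CIs.

#' Build a one-vs-all prediction task
#'
#' @param cohort Data frame with an `outcome` column.
#' @param positive_class Outcome level forming the positive class.
#' @return List of class `prediction_task` with `name`, `positive_class`, and
#'   binary `labels` (1 = positive) over participants.
#' @export
make_task <- function(cohort, positive_class) {
  outcome <- as.character(cohort$outcome)
  if (!positive_class %in% outcome) stop("class '", positive_class, "' absent from cohort")
  labels <- as.integer(outcome == positive_class)
  if (all(labels == 1L)) stop("degenerate task: all participants in the positive class")
  structure(list(name = paste0(positive_class, "-vs-all"),
                 positive_class = positive_class, labels = labels),
            class = "prediction_task")
}

#' Balanced class weights
#'
#' For N samples in K classes, class i with n_i samples receives weight
#' `w_i = N / (K * n_i)`, so the weighted class masses are equal and sum to N.
#'
#' @param labels Binary label vector (0/1).
#' @return Named numeric vector of weights (`"0"`, `"1"`).
#' @export
balanced_class_weights <- function(labels) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  N <- sum(tab)
  K <- length(tab)
  w <- N / (K * as.numeric(tab))
  stats::setNames(w, names(tab))
}

#' Train a class-weighted linear SVM
#'
#' L2-regularized hinge-loss linear classifier with per-class weights scaling
#' the misclassification cost C (so weighting a class by an integer factor is
#' equivalent to replicating its samples). Fitting is delegated to
#' [e1071::svm()] with a linear kernel. When every feature column is constant
#' the problem is degenerate and the model predicts the class with the larger
#' total weight.
#'
#' @param X Numeric matrix (standardize within the training split before
#'   calling).
#' @param y Binary labels (0/1).
#' @param weights Named class weights as from [balanced_class_weights()];
#'   `NULL` for unweighted.
#' @param C Cost parameter (> 0).
#' @return A `linear_svm` model.
#' @export
train_weighted_linear_svm <- function(X, y, weights = NULL, C = 1) {
  if (C <= 0) stop("C must be positive")
  X <- as.matrix(X)
  yf <- factor(y, levels = c(0, 1))
  if (any(table(yf) == 0)) stop("both classes must be present in y")
  col_var <- apply(X, 2, function(v) stats::var(v))
  if (all(col_var < .Machine$double.eps)) {
    w <- if (is.null(weights)) c("0" = 1, "1" = 1) else weights
    mass <- w[c("0", "1")] * table(yf)
    maj <- as.integer(names(mass)[which.max(mass)])
    return(structure(list(degenerate = TRUE, majority = maj), class = "linear_svm"))
  }
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                    cost = C, class.weights = weights, scale = FALSE)
  w_vec <- drop(t(fit$coefs) %*% fit$SV)
  structure(list(degenerate = FALSE, fit = fit, w = w_vec, b = -fit$rho),
            class = "linear_svm")
}

#' Predict with a trained linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Numeric matrix on the training scale.
#' @param ... Unused.
#' @return Integer vector of predicted labels (0/1).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$degenerate) return(rep(object$majority, nrow(newdata)))
  as.integer(as.character(stats::predict(object$fit, newdata)))
}

# deterministic stratified fold assignment: within each class, samples are
# dealt round-robin to folds in index order
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# column means/SDs of a training block; zero SDs fall back to 1 so constant
# columns pass through unscaled
scaling_stats <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < .Machine$double.eps] <- 1
  list(mu = mu, sd = sd_)
}

apply_scaling <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Nested cross-validated predictions
#'
#' Outer leave-one-out loop for generalization assessment; for each held-out
#' sample, an inner stratified k-fold loop on the remaining n-1 samples grid
#' searches C by inner balanced accuracy (ties broken toward the smallest C,
#' i.e. stronger regularization), then the model is refit on all n-1 samples
#' and the hold-out is predicted. Feature standardization statistics are
#' computed inside each training split only, so no information from a
#' held-out sample ever reaches training. If a class is too small for the
#' requested inner fold count, the fold count is reduced to the minority
#' count (with a warning).
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels (0/1).
#' @param C_grid Candidate cost values (default `10^(-3:2)`).
#' @param inner_folds Inner fold count (default 5).
#' @return List with `predictions` (length n), `chosen_C` (per outer fold),
#'   and `inner_folds_used`.
#' @export
nested_cv_predict <- function(X, y, C_grid = 10^(-3:2), inner_folds = 5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("nested cross-validation requires n >= 10")
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    stop("both classes need at least 2 samples")
  }
  C_grid <- sort(C_grid)
  preds <- integer(n)
  chosen <- numeric(n)
  folds_used <- integer(n)
  warned <- FALSE
  for (hold in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), hold)
    X_tr <- X[tr_idx, , drop = FALSE]
    y_tr <- y[tr_idx]
    minority <- min(table(factor(y_tr, levels = c(0, 1))))
    if (minority < 2) stop("minority class too small in an outer training split")
    k <- inner_folds
    if (minority < k) {
      if (!warned) {
        warning("reducing inner folds from ", k, " to the minority class count")
        warned <- TRUE
      }
      k <- minority
    }
    fold <- stratified_folds(y_tr, k)
    inner_ba <- vapply(C_grid, function(C) {
      p_inner <- integer(length(y_tr))
      for (f in seq_len(k)) {
        it <- fold != f
        st <- scaling_stats(X_tr[it, , drop = FALSE])
        w <- balanced_class_weights(y_tr[it])
        m <- train_weighted_linear_svm(apply_scaling(X_tr[it, , drop = FALSE], st),
                                       y_tr[it], w, C)
        p_inner[!it] <- predict(m, apply_scaling(X_tr[!it, , drop = FALSE], st))
      }
      balanced_accuracy(y_tr, p_inner)
    }, numeric(1))
    best_C <- C_grid[which.max(inner_ba)]  # first max = smallest C on ties
    st <- scaling_stats(X_tr)
    m <- train_weighted_linear_svm(apply_scaling(X_tr, st), y_tr,
                                   balanced_class_weights(y_tr), best_C)
    preds[hold] <- predict(m, apply_scaling(X[hold, , drop = FALSE], st))
    chosen[hold] <- best_C
    folds_used[hold] <- k
  }
  list(predictions = preds, chosen_C = chosen, inner_folds_used = folds_used)
}

#' Balanced accuracy
#'
#' `BA = (TPR + TNR) / 2`; equals 0.5 for an all-majority-class prediction at
#' any class imbalance.
#'
#' @param y_true Binary ground-truth labels (0/1), both classes present.
#' @param y_pred Binary predicted labels.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(unique(y_true)) < 2) stop("y_true must contain both classes")
  tpr <- mean(y_pred[y_true == 1] == 1)
  tnr <- mean(y_pred[y_true == 0] == 0)
  (tpr + tnr) / 2
}

#' Bootstrap percentile CI for balanced accuracy
#'
#' Resamples (truth, prediction) pairs with replacement `B` times and returns
#' the percentile interval. Resamples that lose one class entirely are
#' redrawn (up to a capped number of retries).
#'
#' @param y_true,y_pred Paired binary vectors.
#' @param B Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @param max_retries Redraw cap per resample (default 1000).
#' @return Named vector `c(low = , high = )`.
#' @export
bootstrap_ba_ci <- function(y_true, y_pred, B = 1000, level = 0.95,
                            seed = NULL, max_retries = 1000) {
  if (min(table(factor(y_true, levels = c(0, 1)))) == 0) {
    stop("degenerate input: a class is absent from y_true")
  }
  run <- function() {
    n <- length(y_true)
    stat <- numeric(B)
    n_redraws <- 0L
    for (b in seq_len(B)) {
      for (r in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y_true[idx])) == 2) break
        n_redraws <- n_redraws + 1L
        if (r == max_retries) stop("could not draw a two-class bootstrap resample")
      }
      stat[b] <- balanced_accuracy(y_true[idx], y_pred[idx])
    }
    if (n_redraws > 0) message(n_redraws, " single-class bootstrap resample(s) redrawn")
    alpha <- (1 - level) / 2
    ci <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
    c(low = ci[1], high = ci[2])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Default feature sets
#'
#' The five feature sets evaluated by the pipeline: the four verbal rater
#' items (`HiSoC_ve`), the first 15 rater items (`HiSoC_all`; rater-averaged
#' item scores in both cases), the four linguistic features, the five acoustic
#' features, and their union.
#'
#' @param n_hisoc_items Number of rater items in `HiSoC_all` (default 15).
#' @return Named list of column-name vectors.
#' @export
default_feature_sets <- function(n_hisoc_items = 15) {
  linguistic <- c("WPM", "AR", "Dysfluency", "SC")
  acoustic <- c("F0_m", "F0_sd", "Int_m", "Int_sd", "HF500")
  list(
    HiSoC_ve = hisoc_ve_items(),
    HiSoC_all = hisoc_item_names()[seq_len(n_hisoc_items)],
    linguistic = linguistic,
    acoustic = acoustic,
    linguistic_acoustic = c(linguistic, acoustic)
  )
}

#' Average the two raters' item scores into modeling columns
#'
#' For each rated item, adds a column named after the item holding the mean of
#' the `<item>_r1` and `<item>_r2` columns.
#'
#' @param feature_table Data frame with per-rater item columns.
#' @return The table with the 16 rater-averaged item columns appended.
#' @export
aggregate_ratings <- function(feature_table) {
  for (item in hisoc_item_names()) {
    r1 <- paste0(item, "_r1"); r2 <- paste0(item, "_r2")
    if (r1 %in% names(feature_table) && r2 %in% names(feature_table)) {
      feature_table[[item]] <- (feature_table[[r1]] + feature_table[[r2]]) / 2
    }
  }
  feature_table
}

#' Evaluate feature sets across prediction tasks
#'
#' Runs nested cross-validation for every (feature set, task) cell, computes
#' balanced accuracy with sensitivity and specificity, bootstraps the 95% CI,
#' and flags a model significant when the CI lower bound exceeds 0.5
#' (outperforming a random guess).
#'
#' @param feature_table Data frame containing every feature-set column.
#' @param tasks Named list of [make_task()] objects.
#' @param feature_sets Named list of column vectors (default
#'   [default_feature_sets()]).
#' @param C_grid,inner_folds Passed to [nested_cv_predict()].
#' @param B,level Passed to [bootstrap_ba_ci()].
#' @param seed Integer seed for the bootstrap.
#' @return List with `summary` (data frame: `feature_set`, `task`, `ba`,
#'   `ci_low`, `ci_high`, `sensitivity`, `specificity`, `significant`) and
#'   `details` (per-cell outer predictions and chosen C).
#' @export
evaluate_feature_sets <- function(feature_table, tasks,
                                  feature_sets = default_feature_sets(),
                                  C_grid = 10^(-3:2), inner_folds = 5,
                                  B = 1000, level = 0.95, seed = 1L) {
  for (fs in feature_sets) {
    missing_cols <- setdiff(fs, names(feature_table))
    if (length(missing_cols)) stop("feature columns not found: ",
                                   paste(missing_cols, collapse = ", "))
  }
  summary_rows <- list()
  details <- list()
  cell <- 0L
  for (fs_name in names(feature_sets)) {
    X <- as.matrix(feature_table[feature_sets[[fs_name]]])
    for (task_name in names(tasks)) {
      cell <- cell + 1L
      task <- tasks[[task_name]]
      cv <- nested_cv_predict(X, task$labels, C_grid, inner_folds)
      ba <- balanced_accuracy(task$labels, cv$predictions)
      ci <- bootstrap_ba_ci(task$labels, cv$predictions, B = B, level = level,
                            seed = seed + cell)
      summary_rows[[cell]] <- data.frame(
        feature_set = fs_name, task = task$name, ba = ba,
        ci_low = ci["low"], ci_high = ci["high"],
        sensitivity = mean(cv$predictions[task$labels == 1] == 1),
        specificity = mean(cv$predictions[task$labels == 0] == 0),
        significant = unname(ci["low"] > 0.5),
        row.names = NULL, stringsAsFactors = FALSE
      )
      details[[paste(fs_name, task$name, sep = ".")]] <- cv
    }
  }
  list(summary = do.call(rbind, summary_rows), details = details)
}
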