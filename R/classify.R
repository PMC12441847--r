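#' Stratified 4:1:1 train/validation/test split
#'
#' Within each stratum of size n, `floor(4n/6)` samples go to training,
#' `floor(n/6)` to validation and the remainder to test — the unique simple
#' rounding rule consistent with the published split tables for class sizes
#' 34 (22/5/7), 24 (16/4/4), 38 (25/6/7) and 36 (24/6/6). Membership within
#' a stratum is randomized by the seed; the counts are deterministic.
#'
#' @param labels Character vector (`"positive"`/`"negative"`), one per
#'   sample; used as the default stratum.
#' @param strata Optional stratum id per sample (e.g.
#'   `interaction(label, concentration)` to balance doses as well).
#' @param seed Integer seed for the within-stratum shuffle.
#' @return An object of class `split_assignment`: a list with `subset`
#'   (factor `train`/`validation`/`test` per sample) and `strata`.
#' @export
stratified_split <- function(labels, strata = NULL, seed = 1L) {
  n <- length(labels)
  stopifnot(n >= 1L)
  if (is.null(strata)) strata <- labels
  stopifnot(length(strata) == n)
  subset <- character(n)
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ns <- length(idx)
    if (ns < 3L) {
      warning("stratified_split: stratum '", s, "' has only ", ns,
              " sample(s); its test subset may be empty")
    }
    n_tr <- floor(4 * ns / 6)
    n_va <- floor(ns / 6)
    idx <- idx[sample.int(ns)]
    subset[idx[seq_len(n_tr)]] <- "train"
    if (n_va > 0L) subset[idx[n_tr + seq_len(n_va)]] <- "validation"
    rest <- idx[-seq_len(n_tr + n_va)]
    subset[rest] <- "test"
  }
  structure(list(subset = factor(subset,
                                 levels = c("train", "validation", "test")),
                 strata = strata),
            class = "split_assignment")
}

#' Split counts per label
#'
#' @param split A `split_assignment`.
#' @param labels Per-sample labels.
#' @return A `table` of subset x label counts.
#' @export
split_counts <- function(split, labels) {
  table(subset = split$subset, label = labels)
}

# weakly L2-penalized logistic regression by Newton iteration; the penalty
# (never applied to the intercept) keeps the optimum finite on linearly
# separable data, where the unpenalized MLE diverges
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100L,
                           tol = 1e-10) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1L], coef = beta[-1L],
       converged = max(abs(step)) < sqrt(tol))
}

fm_rows <- function(fm, split, subsets) {
  which(split$subset %in% subsets)
}

#' Fit the logistic classifier on selected features
#'
#' Features are z-scored with means and scales computed on the training
#' rows only, then a weakly L2-penalized logistic model is fit on the
#' training rows. Test rows never touch standardization or fitting.
#'
#' @param fm A `feature_matrix` with labels.
#' @param split A `split_assignment`.
#' @param selected Character vector of canonical descriptor names (or column
#'   indices), at most a handful — the published protocol caps at two.
#' @param lambda Ridge penalty (default `1e-3`, weak).
#' @return An object of class `trained_classifier`.
#' @export
fit_classifier <- function(fm, split, selected, lambda = 1e-3) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels),
            length(selected) >= 1L)
  if (is.character(selected)) {
    missing <- setdiff(selected, colnames(fm$values))
    if (length(missing)) {
      stop("fit_classifier: unknown feature(s): ",
           paste(missing, collapse = ", "))
    }
  }
  tr <- fm_rows(fm, split, "train")
  y <- as.integer(fm$labels[tr] == "positive")
  if (length(unique(y)) < 2L) {
    stop("fit_classifier: training set contains a single class")
  }
  X <- fm$values[tr, selected, drop = FALSE]
  mu <- colMeans(X)
  sigma <- apply(X, 2L, stats::sd)
  if (any(sigma == 0)) {
    stop("fit_classifier: zero training variance in ",
         paste(colnames(X)[sigma == 0], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2L, mu), 2L, sigma, "/")
  fitted <- ridge_logistic(Xs, y, lambda)
  structure(
    list(selected = if (is.character(selected)) selected
                    else colnames(fm$values)[selected],
         mu = mu, sigma = sigma, coef = fitted$coef,
         intercept = fitted$intercept, lambda = lambda,
         converged = fitted$converged),
    class = "trained_classifier"
  )
}

#' Score samples and apply the sign decision rule
#'
#' The score is the logistic model's linear decision value on standardized
#' features; a score `>= 0` is classified positive (susceptible), a score
#' `< 0` negative (resistant) — the boundary itself belongs to the positive
#' class. The logistic link maps score 0 to probability 0.5.
#'
#' @param model A `trained_classifier`.
#' @param fm A `feature_matrix` (or a plain numeric matrix with named
#'   columns).
#' @return A `data.frame` with columns `score`, `prob`, `class`.
#' @export
score_and_classify <- function(model, fm) {
  vals <- if (inherits(fm, "feature_matrix")) fm$values else fm
  missing <- setdiff(model$selected, colnames(vals))
  if (length(missing)) {
    stop("score_and_classify: feature(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  X <- vals[, model$selected, drop = FALSE]
  Xs <- sweep(sweep(X, 2L, model$mu), 2L, model$sigma, "/")
  score <- drop(Xs %*% model$coef) + model$intercept
  data.frame(score = score, prob = stats::plogis(score),
             class = ifelse(score >= 0, "positive", "negative"))
}

#' Forward sequential feature selection
#'
#' Greedy selection capped at `max_features` (default two, to prevent
#' overfitting on small cohorts): at each step every unused candidate is
#' added in turn, a logistic model is fit on the training rows, and the
#' candidate whose model scores the highest accuracy on the pooled
#' training + validation rows is kept. Selection stops at the cap or as soon
#' as no addition strictly improves accuracy. Ties are broken by the lowest
#' canonical descriptor name; candidates with zero training variance are
#' skipped with a message.
#'
#' @param fm A `feature_matrix` with labels.
#' @param split A `split_assignment` (test rows are never consulted).
#' @param max_features Selection cap.
#' @param lambda Ridge penalty passed to [fit_classifier()].
#' @param pool `"train+validation"` (published protocol) or
#'   `"validation"` to score candidates on the validation rows alone.
#' @return A list of class `selection_result`: `selected` (names in
#'   selection order), `accuracy` (selection-pool accuracy after each
#'   step).
#' @export
forward_select <- function(fm, split, max_features = 2L, lambda = 1e-3,
                           pool = c("train+validation", "validation")) {
  pool <- match.arg(pool)
  pool_rows <- fm_rows(fm, split,
                       if (pool == "validation") "validation"
                       else c("train", "validation"))
  stopifnot(length(pool_rows) >= 1L)
  tr <- fm_rows(fm, split, "train")
  y_pool <- fm$labels[pool_rows] == "positive"
  candidates <- colnames(fm$values)
  sd_tr <- apply(fm$values[tr, , drop = FALSE], 2L, stats::sd)
  degenerate <- candidates[sd_tr == 0]
  if (length(degenerate)) {
    message("forward_select: skipping ", length(degenerate),
            " zero-variance feature(s)")
    candidates <- setdiff(candidates, degenerate)
  }
  selected <- character(0L)
  acc_trace <- numeric(0L)
  best_acc <- -Inf
  while (length(selected) < max_features && length(candidates)) {
    accs <- vapply(candidates, function(cand) {
      model <- fit_classifier(fm, split, c(selected, cand), lambda)
      pred <- score_and_classify(model, fm)$class[pool_rows]
      mean((pred == "positive") == y_pool)
    }, numeric(1L))
    top <- max(accs)
    if (top <= best_acc) break
    pick <- sort(candidates[accs == top])[1L]  # deterministic tie-break
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
    best_acc <- top
    acc_trace <- c(acc_trace, top)
  }
  if (!length(selected)) {
    # no candidate beats the empty model's (undefined) accuracy: keep the
    # single best candidate anyway so downstream fitting has a feature
    stop("forward_select: no usable candidate features")
  }
  structure(list(selected = selected, accuracy = acc_trace),
            class = "selection_result")
}

#' Average precision (step interpolation)
#'
#' Area under the precision–recall step curve with samples ranked by
#' decreasing score: `AP = sum((R_k - R_{k-1}) * P_k)`. A classifier that
#' ranks at random has expected AP equal to the positive prevalence.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param is_positive Logical vector.
#' @return Scalar AP in `[0, 1]`.
#' @export
average_precision <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  if (!any(is_positive)) stop("average_precision: no positive samples")
  ord <- order(scores, decreasing = TRUE)
  y <- is_positive[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a trained classifier on one subset
#'
#' Accuracy is the proportion of correctly classified samples (both
#' classes) in the subset; per-class recalls, the precision–recall curve,
#' its average precision and the random-classifier AP baseline (the
#' subset's positive prevalence) are reported alongside the per-sample
#' scores.
#'
#' @param model A `trained_classifier`.
#' @param fm A `feature_matrix` with labels.
#' @param split A `split_assignment`.
#' @param subset `"train"`, `"validation"` or `"test"`.
#' @return A list of class `evaluation_report`: `subset`, `n`, `accuracy`,
#'   `recall_positive`, `recall_negative`, `average_precision`,
#'   `baseline_ap`, `pr_curve` (data.frame `recall`, `precision`),
#'   `scores` (per-sample data.frame).
#' @export
evaluate_classifier <- function(model, fm, split,
                                subset = c("test", "validation", "train")) {
  subset <- match.arg(subset)
  rows <- fm_rows(fm, split, subset)
  if (!length(rows)) stop("evaluate_classifier: subset '", subset, "' is empty")
  y <- fm$labels[rows] == "positive"
  if (!any(y)) {
    stop("evaluate_classifier: subset has no positives; AP undefined")
  }
  sc <- score_and_classify(model, if (inherits(fm, "feature_matrix"))
    fm$values[rows, , drop = FALSE] else fm[rows, , drop = FALSE])
  pred_pos <- sc$class == "positive"
  ord <- order(sc$score, decreasing = TRUE)
  tp <- cumsum(y[ord])
  pr <- data.frame(recall = tp / sum(y), precision = tp / seq_along(tp))
  structure(
    list(subset = subset, n = length(rows),
         accuracy = mean(pred_pos == y),
         recall_positive = mean(pred_pos[y]),
         recall_negative = if (any(!y)) mean(!pred_pos[!y]) else NA_real_,
         average_precision = average_precision(sc$score, y),
         baseline_ap = mean(y),
         pr_curve = pr,
         scores = data.frame(sample_id = fm$sample_ids[rows],
                             label = fm$labels[rows],
                             score = sc$score, class = sc$class)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %s (n=%d): accuracy %.3f | recall +%.3f -%.3f | AP %.3f (baseline %.2f)\n",
    x$subset, x$n, x$accuracy, x$recall_positive, x$recall_negative,
    x$average_precision, x$baseline_ap))
  invisible(x)
}

#' Locate the plateau of an accuracy curve
#'
#' The plateau is the first grid point after which no later point exceeds
#' its accuracy by more than `tolerance`.
#'
#' @param grid_min Increasing numeric grid (e.g. exposure durations in
#'   minutes).
#' @param accuracy Accuracy per grid point.
#' @param tolerance Improvement deemed negligible (default 0).
#' @return List with `plateau_min`, `index`, `accuracy`.
#' @export
plateau_point <- function(grid_min, accuracy, tolerance = 0) {
  stopifnot(length(grid_min) == length(accuracy), !is.unsorted(grid_min))
  for (i in seq_along(grid_min)) {
    later <- accuracy[seq_along(accuracy) > i]
    if (!length(later) || all(later <= accuracy[i] + tolerance)) {
      return(list(plateau_min = grid_min[i], index = i,
                  accuracy = accuracy[i]))
    }
  }
}

#' Cross-validated accuracy versus drug-exposure duration
#'
#' For each duration on the grid, features are rebuilt from drug-phase
#' windows that end within that exposure, and forward selection + logistic
#' fitting are run under k-fold cross-validation on the pooled
#' training + validation samples (test samples are never used). The plateau
#' is the first duration after which no longer exposure improves
#' cross-validated accuracy by more than `tolerance`.
#'
#' @param spectrograms List of per-sample `quantile_spectrogram`s whose
#'   windows cover the drug phase.
#' @param labels Per-sample `"positive"`/`"negative"`.
#' @param split A `split_assignment`; only train/validation samples enter
#'   the sweep.
#' @param drug_onset_min Clock minute at which the drug phase starts.
#' @param grid_min Exposure durations (minutes past onset) to evaluate;
#'   durations shorter than one window are skipped with a message.
#' @param grammar Interval-free grammar template (a [feature_grammar()]
#'   whose `intervals` are ignored): kinds, bands, levels, percentiles.
#' @param folds Number of CV folds (default 6, echoing the 4:1:1
#'   granularity).
#' @param max_features Selection cap per fold.
#' @param tolerance Plateau tolerance on accuracy.
#' @param seed Seed for the fold assignment.
#' @return A list of class `exposure_sweep`: `grid_min`, `accuracy`,
#'   `plateau_min`, `plateau_accuracy`.
#' @export
exposure_sweep <- function(spectrograms, labels, split, drug_onset_min,
                           grid_min, grammar, folds = 6L, max_features = 2L,
                           tolerance = 0, seed = 1L) {
  window_min <- spectrograms[[1L]]$window_min
  dev_rows <- which(split$subset %in% c("train", "validation"))
  y_dev <- labels[dev_rows]
  set.seed(seed)
  fold_id <- integer(length(dev_rows))
  for (cl in unique(y_dev)) {   # stratified fold assignment
    idx <- which(y_dev == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  kept <- logical(length(grid_min))
  acc <- rep(NA_real_, length(grid_min))
  for (gi in seq_along(grid_min)) {
    n_win <- floor(grid_min[gi] / window_min)
    if (n_win < 1L) {
      message("exposure_sweep: duration ", grid_min[gi],
              " min is shorter than one window; skipped")
      next
    }
    kept[gi] <- TRUE
    g <- grammar
    g$intervals <- list(c(drug_onset_min, drug_onset_min + n_win * window_min))
    g$combinators <- "value"
    fm <- build_feature_matrix(spectrograms[dev_rows], g,
                               labels = labels[dev_rows])
    correct <- logical(0L)
    for (k in seq_len(folds)) {
      te <- which(fold_id == k)
      if (!length(te)) next
      sub <- structure(list(
        subset = factor(ifelse(seq_along(dev_rows) %in% te, "test", "train"),
                        levels = c("train", "validation", "test")),
        strata = y_dev), class = "split_assignment")
      sel <- forward_select(fm, sub, max_features = max_features)
      model <- fit_classifier(fm, sub, sel$selected)
      pred <- score_and_classify(model, fm)$class[te]
      correct <- c(correct, pred == y_dev[te])
    }
    acc[gi] <- mean(correct)
  }
  grid_kept <- grid_min[kept]
  acc_kept <- acc[kept]
  pl <- plateau_point(grid_kept, acc_kept, tolerance)
  structure(list(grid_min = grid_kept, accuracy = acc_kept,
                 plateau_min = pl$plateau_min,
                 plateau_accuracy = pl$accuracy),
            class = "exposure_sweep")
}
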