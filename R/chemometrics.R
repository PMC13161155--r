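# PCA-LDA classification of preprocessed single-cell spectra:
# covariance-based PCA, >90% cumulative-variance component selection,
# Fisher linear discriminant on the retained scores, stratified ten-fold
# cross-validation with pooled out-of-fold scores, ROC/AUC, label
# permutation testing and patient-level aggregation.

#' Principal component analysis of a spectra matrix
#'
#' Mean-centered singular value decomposition: components ordered by
#' decreasing variance, loading rows orthonormal, and each loading's
#' largest-magnitude element made positive (sign convention).
#'
#' @param x Samples x channels numeric matrix (>= 2 rows).
#' @return A `pca_model`: `mean` (channel vector), `loadings` (components x
#'   channels), `explained_variance_ratio`, `sdev`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("data error: PCA needs at least 2 samples", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- La.svd(xc, nu = 0L, nv = min(dim(xc)))
  loadings <- sv$vt
  # sign convention: largest-|.| element of each loading positive
  flip <- apply(loadings, 1L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- loadings * flip
  var_total <- sum(sv$d^2)
  evr <- if (var_total > 0) sv$d^2 / var_total else rep(0, length(sv$d))
  structure(list(mean = mu, loadings = loadings,
                 explained_variance_ratio = evr,
                 sdev = sv$d / sqrt(max(1, n - 1L))),
            class = "pca_model")
}

#' Project new spectra onto PCA components
#'
#' @param model A `pca_model`.
#' @param x Samples x channels matrix on the training grid.
#' @param k Number of components (default all).
#' @return Samples x k score matrix.
#' @export
pca_scores <- function(model, x, k = nrow(model$loadings)) {
  xc <- sweep(as.matrix(x), 2L, model$mean)
  xc %*% t(model$loadings[seq_len(k), , drop = FALSE])
}

#' Smallest number of components exceeding a cumulative-variance threshold
#'
#' @param evr Explained-variance-ratio vector (non-increasing).
#' @param threshold Cumulative-variance fraction in (0, 1); default 0.90,
#'   i.e. components are retained until they explain more than 90% of the
#'   variance.
#' @return Integer k, the smallest count with `cumsum(evr) > threshold`
#'   (all components if the threshold is never exceeded).
#' @export
select_n_components <- function(evr, threshold = 0.90) {
  if (threshold <= 0 || threshold >= 1) {
    stop("parameter error: threshold must be in (0, 1)", call. = FALSE)
  }
  cs <- cumsum(evr)
  hit <- which(cs > threshold)
  if (length(hit) == 0L) length(evr) else hit[1L]
}

#' Fisher linear discriminant for two classes
#'
#' Finds the direction maximizing the between- to within-class scatter
#' ratio; the pooled within-class scatter is inverted via the pseudo-inverse
#' when singular. The decision threshold sits at the midpoint of the
#' projected class means (equal priors). With two classes a single
#' discriminant axis carries all between-group variance.
#'
#' @param scores Samples x k matrix of (PCA) scores.
#' @param labels Vector with exactly two distinct values.
#' @param positive_class The class mapped to higher scores; default `"NR"`
#'   when present, otherwise the second sorted level.
#' @return An `lda_model`: `weights` (unit vector, length k), `threshold`,
#'   `class_means` (projected), `classes`, `positive_class`.
#' @export
fit_lda <- function(scores, labels, positive_class = NULL) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("label error: exactly two classes required", call. = FALSE)
  }
  if (is.null(positive_class)) {
    positive_class <- if ("NR" %in% classes) "NR" else classes[2L]
  }
  negative_class <- setdiff(classes, positive_class)
  m_pos <- colMeans(scores[labels == positive_class, , drop = FALSE])
  m_neg <- colMeans(scores[labels == negative_class, , drop = FALSE])
  sw <- matrix(0, ncol(scores), ncol(scores))
  for (cl in classes) {
    xc <- sweep(scores[labels == cl, , drop = FALSE], 2L,
                colMeans(scores[labels == cl, , drop = FALSE]))
    sw <- sw + crossprod(xc)
  }
  w <- tryCatch(drop(solve(sw, m_pos - m_neg)),
                error = function(e) drop(pracma::pinv(sw) %*% (m_pos - m_neg)))
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  proj_pos <- sum(w * m_pos)
  proj_neg <- sum(w * m_neg)
  threshold <- (proj_pos + proj_neg) / 2
  structure(list(weights = w, threshold = threshold,
                 class_means = c(stats::setNames(proj_neg, negative_class),
                                 stats::setNames(proj_pos, positive_class)),
                 classes = classes, positive_class = positive_class),
            class = "lda_model")
}

#' Fit the combined PCA-LDA classifier on a spectra set
#'
#' PCA on all rows, component count chosen by [select_n_components()] at the
#' cumulative-variance threshold, then a Fisher discriminant on the retained
#' scores.
#'
#' @param dataset A preprocessed [spectra_set()].
#' @param labels Class labels (default `dataset$meta$group`).
#' @param var_threshold Cumulative-variance threshold (default 0.90).
#' @param positive_class See [fit_lda()].
#' @return A `pca_lda_model`: `pca`, `n_components`, `lda`, `wavenumbers`.
#' @export
fit_pca_lda <- function(dataset, labels = dataset$meta$group,
                        var_threshold = 0.90, positive_class = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  pca <- fit_pca(dataset$matrix)
  k <- select_n_components(pca$explained_variance_ratio, var_threshold)
  scores <- pca_scores(pca, dataset$matrix, k)
  lda <- fit_lda(scores, labels, positive_class)
  structure(list(pca = pca, n_components = k, lda = lda,
                 var_threshold = var_threshold,
                 wavenumbers = dataset$wavenumbers),
            class = "pca_lda_model")
}

#' @export
print.pca_lda_model <- function(x, ...) {
  cat(sprintf(
    "<pca_lda_model> %d PCs (>%.0f%% cumulative variance), positive class %s\n",
    x$n_components, 100 * x$var_threshold, x$lda$positive_class))
  invisible(x)
}

#' Per-sample discriminant scores
#'
#' Projects spectra through the fitted PCA onto the retained components and
#' then onto the LD1 axis; the stored class-midpoint threshold is
#' subtracted, so the decision boundary is at 0 and higher scores indicate
#' the positive (by convention NR) class.
#'
#' @param model A `pca_lda_model`.
#' @param dataset A [spectra_set()] on the training grid.
#' @return Numeric vector of scores, one per row.
#' @export
decision_scores <- function(model, dataset) {
  stopifnot(inherits(model, "pca_lda_model"), inherits(dataset, "spectra_set"))
  if (!isTRUE(all.equal(model$wavenumbers, dataset$wavenumbers))) {
    stop("alignment error: dataset grid differs from training grid",
         call. = FALSE)
  }
  sc <- pca_scores(model$pca, dataset$matrix, model$n_components)
  drop(sc %*% model$lda$weights) - model$lda$threshold
}

#' Predict class labels
#'
#' @param model A `pca_lda_model`.
#' @param dataset A [spectra_set()].
#' @return Character vector of predicted labels.
#' @export
predict_response <- function(model, dataset) {
  s <- decision_scores(model, dataset)
  neg <- setdiff(model$lda$classes, model$lda$positive_class)
  ifelse(s > 0, model$lda$positive_class, neg)
}

#' ROC curve and AUC by the rank (Mann-Whitney) estimator
#'
#' The AUC equals the Mann-Whitney U statistic normalized by n1 * n0; tied
#' scores contribute half. The curve is the empirical TPR/FPR sweep over
#' score thresholds.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical or two-valued vector; `TRUE` (or the
#'   `positive_class` value) marks positives.
#' @param positive_class Value of `labels` treated as positive when
#'   `labels` is not logical.
#' @return A `roc_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(scores, labels, positive_class = "NR") {
  if (!is.logical(labels)) labels <- as.character(labels) == positive_class
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("label error: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties get half credit
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  thr <- c(Inf, unique(scores[ord]))
  tpr <- numeric(length(thr)); fpr <- numeric(length(thr))
  cum_tp <- cumsum(labels[ord]); cum_fp <- cumsum(!labels[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)
  tpr <- c(0, cum_tp[last] / n1)
  fpr <- c(0, cum_fp[last] / n0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Confusion-matrix metrics
#'
#' Positive class is NR by convention. Zero-denominator metrics are
#' returned as `NA` with `undefined` naming the affected metrics rather
#' than failing.
#'
#' @param tp,fp,tn,fn Non-negative counts (total > 0).
#' @return A `confusion_metrics` list: counts plus `accuracy`,
#'   `sensitivity`, `specificity` (fractions) and `undefined`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be >= 0 with a positive total", call. = FALSE)
  }
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- safe(tp + tn, tp + tn + fp + fn)
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  undefined <- c("sensitivity", "specificity")[c(tp + fn == 0, tn + fp == 0)]
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = acc, sensitivity = sens, specificity = spec,
                 undefined = undefined), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> tp=%d fp=%d tn=%d fn=%d | accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$tp, x$fp, x$tn, x$fn, 100 * x$accuracy, 100 * x$sensitivity,
    100 * x$specificity))
  invisible(x)
}

stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    if (length(ix) < folds) {
      stop(sprintf("fold error: class %s has %d rows, fewer than %d folds",
                   cl, length(ix), folds), call. = FALSE)
    }
    assign[sample(ix)] <- rep(seq_len(folds), length.out = length(ix))
  }
  assign
}

#' Stratified k-fold cross-validation of the PCA-LDA classifier
#'
#' Folds are stratified by class and seeded. Within each fold the full
#' PCA-LDA model — including the cumulative-variance component selection —
#' is refit on the training rows only; out-of-fold decision scores are
#' pooled across folds and feed the confusion metrics (at the common
#' 0 threshold) and the ROC curve.
#'
#' @param dataset A preprocessed [spectra_set()].
#' @param labels Class labels (default `dataset$meta$group`).
#' @param folds Number of folds (default 10); each class must have at least
#'   `folds` rows.
#' @param seed Integer seed for fold construction.
#' @param var_threshold Cumulative-variance threshold passed to the
#'   per-fold fits.
#' @param positive_class See [fit_lda()].
#' @return A `cv_result`: `metrics` ([confusion_metrics()]), `roc`
#'   ([roc_auc()]), `scores` (pooled out-of-fold), `fold` assignment,
#'   `n_components` per fold.
#' @export
cross_validate <- function(dataset, labels = dataset$meta$group,
                           folds = 10L, seed = 1L, var_threshold = 0.90,
                           positive_class = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("label error: exactly two classes required", call. = FALSE)
  }
  if (is.null(positive_class)) {
    positive_class <- if ("NR" %in% classes) "NR" else classes[2L]
  }
  set.seed(seed)
  fold <- stratified_folds(labels, folds)
  scores <- numeric(length(labels))
  ks <- integer(folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    model <- fit_pca_lda(subset_spectra(dataset, !test), labels[!test],
                         var_threshold, positive_class)
    ks[f] <- model$n_components
    scores[test] <- decision_scores(model, subset_spectra(dataset, test))
  }
  is_pos <- labels == positive_class
  pred_pos <- scores > 0
  metrics <- confusion_metrics(tp = sum(pred_pos & is_pos),
                               fp = sum(pred_pos & !is_pos),
                               tn = sum(!pred_pos & !is_pos),
                               fn = sum(!pred_pos & is_pos))
  roc <- roc_auc(scores, is_pos)
  structure(list(metrics = metrics, roc = roc, scores = scores,
                 fold = fold, n_components = ks,
                 positive_class = positive_class), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f (PCs/fold: %s)\n",
    max(x$fold), 100 * x$metrics$accuracy, 100 * x$metrics$sensitivity,
    100 * x$metrics$specificity, x$roc$auc,
    paste(x$n_components, collapse = ",")))
  invisible(x)
}

#' Label-permutation test of the cross-validated AUC
#'
#' The class labels are randomly permuted `n_permutations` times; for each
#' permutation the full PCA-LDA model is reconstructed under stratified
#' cross-validation and the pooled out-of-fold AUC recorded, building the
#' null distribution. The p-value uses the add-one formula
#' `(1 + #(null >= observed)) / (1 + n_permutations)` so it can never be
#' exactly zero.
#'
#' @param dataset A preprocessed [spectra_set()].
#' @param labels Class labels (default `dataset$meta$group`).
#' @param n_permutations Number of label permutations (default 1000).
#' @param folds,var_threshold,positive_class Passed to [cross_validate()].
#' @param seed Integer seed.
#' @return A `permutation_result`: `observed_auc`, `null_aucs`, `p_value`.
#' @export
permutation_test <- function(dataset, labels = dataset$meta$group,
                             n_permutations = 1000L, folds = 10L,
                             var_threshold = 0.90, positive_class = NULL,
                             seed = 1L) {
  if (n_permutations < 1L) {
    stop("parameter error: n_permutations must be >= 1", call. = FALSE)
  }
  labels <- as.character(labels)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_permutations + 1L)
  observed <- cross_validate(dataset, labels, folds, child_seeds[1L],
                             var_threshold, positive_class)$roc$auc
  nulls <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(child_seeds[b + 1L])
    perm <- sample(labels)
    nulls[b] <- cross_validate(dataset, perm, folds, child_seeds[b + 1L],
                               var_threshold, positive_class)$roc$auc
  }
  p <- (1 + sum(nulls >= observed)) / (1 + n_permutations)
  structure(list(observed_auc = observed, null_aucs = nulls, p_value = p),
            class = "permutation_result")
}

#' Aggregate a spectra set to one mean spectrum per patient
#'
#' Each output row is the arithmetic mean of that patient's spectra; the
#' group label is inherited. Used to avoid pseudoreplication in patient-level
#' statistics.
#'
#' @param dataset A [spectra_set()].
#' @return A [spectra_set()] with one row per patient (`sample_id` =
#'   patient id).
#' @export
patient_mean_spectra <- function(dataset) {
  stopifnot(inherits(dataset, "spectra_set"))
  pats <- unique(dataset$meta$patient_id)
  mat <- matrix(0, length(pats), ncol(dataset$matrix))
  grp <- character(length(pats))
  for (i in seq_along(pats)) {
    rows <- dataset$meta$patient_id == pats[i]
    g <- unique(dataset$meta$group[rows])
    if (length(g) != 1L) {
      stop(sprintf("metadata error: patient %s has mixed groups", pats[i]),
           call. = FALSE)
    }
    grp[i] <- g
    mat[i, ] <- colMeans(dataset$matrix[rows, , drop = FALSE])
  }
  spectra_set(dataset$wavenumbers, mat,
              data.frame(sample_id = pats, patient_id = pats, group = grp,
                         stringsAsFactors = FALSE))
}

#' Normalized per-PC contributions to the LD1 axis
#'
#' Absolute LD1 weights normalized to sum to 1; reports how the
#' discriminant loads on each retained principal component.
#'
#' @param model A `pca_lda_model`.
#' @return Named numeric vector (`PC1`, `PC2`, ...) summing to 1.
#' @export
ld1_pc_contributions <- function(model) {
  stopifnot(inherits(model, "pca_lda_model"))
  w <- abs(model$lda$weights)
  stats::setNames(w / sum(w), paste0("PC", seq_along(w)))
}
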