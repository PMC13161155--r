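test_that("PCA handles rank-1 data, symmetry, and full reconstruction", {
  # points on a line: all variance in one component
  set.seed(1)
  t <- rnorm(50)
  x <- cbind(2 * t, -t)
  p <- fit_pca(x)
  expect_equal(p$explained_variance_ratio, c(1, 0), tolerance = 1e-12)

  # isotropic gaussian: symmetric variance split
  x2 <- matrix(rnorm(20000), ncol = 2)
  p2 <- fit_pca(x2)
  expect_lt(max(abs(p2$explained_variance_ratio - 0.5)), 0.02)
  expect_equal(sum(p2$explained_variance_ratio), 1)

  # orthonormal loadings and exact reconstruction with all components
  x3 <- matrix(rnorm(200), 20, 10)
  p3 <- fit_pca(x3)
  gram <- p3$loadings %*% t(p3$loadings)
  expect_equal(gram, diag(nrow(p3$loadings)), tolerance = 1e-8)
  xc <- sweep(x3, 2, p3$mean)
  recon <- pca_scores(p3, x3) %*% p3$loadings
  expect_equal(recon, xc, tolerance = 1e-8)
  expect_true(all(diff(p3$explained_variance_ratio) <= 1e-12))
  expect_error(fit_pca(x3[1, , drop = FALSE]), "data error")
})

test_that("component selection crosses the cumulative-variance threshold", {
  expect_equal(select_n_components(c(0.5, 0.3, 0.15, 0.05), 0.9), 3)
  expect_equal(select_n_components(c(0.91, 0.05, 0.04), 0.9), 1)
  expect_equal(select_n_components(c(0.5, 0.3, 0.15, 0.05), 0.999), 4)
  expect_error(select_n_components(c(1), 1.5), "threshold")
})

test_that("Fisher LDA separates separable clouds and is label-symmetric", {
  cl <- gaussian_clusters(50, sep = 8, seed = 2)
  m <- fit_lda(cl$x, cl$labels)
  pred <- ifelse(drop(cl$x %*% m$weights) - m$threshold > 0, "NR", "CR")
  expect_equal(mean(pred == cl$labels), 1.0)
  # swapping the positive class negates the direction, same separation
  m2 <- fit_lda(cl$x, cl$labels, positive_class = "CR")
  expect_equal(m2$weights, -m$weights, tolerance = 1e-8)
  expect_error(fit_lda(cl$x, rep("CR", 100)), "label error")
})

test_that("LDA direction agrees with the classical reference implementation", {
  skip_if_not_installed("MASS")
  cl <- gaussian_clusters(60, sep = 2, seed = 3)
  w <- fit_lda(cl$x, cl$labels)$weights
  ref <- MASS::lda(cl$x, grouping = cl$labels)$scaling[, 1]
  ref <- ref / sqrt(sum(ref^2))
  expect_equal(abs(sum(w * ref)), 1, tolerance = 1e-6)
})

test_that("LDA on relabeled identical distributions sits at chance", {
  set.seed(4)
  x <- matrix(rnorm(400 * 5), ncol = 5)
  labels <- sample(rep(c("CR", "NR"), each = 200))
  m <- fit_lda(x, labels)
  pred <- ifelse(drop(x %*% m$weights) - m$threshold > 0, "NR", "CR")
  expect_lt(abs(mean(pred == labels) - 0.5), 0.1)
})

test_that("PCA-LDA end-to-end separates a strong synthetic contrast", {
  cfg <- clean_config(n_channels = 300, cells = c(CR = 60, NR = 60),
                      n_patients = 4, seed = 5,
                      profiles = default_group_profiles(contrast = 1.5))
  ds <- simulate_dataset(cfg)$dataset
  cv <- cross_validate(ds, folds = 10, seed = 9)
  expect_gt(cv$metrics$accuracy, 0.9)

  model <- fit_pca_lda(ds)
  # training accuracy at least as high as cross-validated (overfitting
  # direction)
  train_acc <- mean(predict_response(model, ds) == ds$meta$group)
  expect_gte(train_acc, cv$metrics$accuracy)
  # a looser variance threshold retains at least as many components
  k99 <- fit_pca_lda(ds, var_threshold = 0.999)$n_components
  expect_gte(k99, model$n_components)
})

test_that("decision scores split the training classes around zero", {
  cl <- gaussian_clusters(40, sep = 6, seed = 6)
  ds <- as_set(cl$x, cl$labels)
  model <- fit_pca_lda(ds)
  s <- decision_scores(model, ds)
  expect_gt(mean(s[cl$labels == "NR"]), 0)
  expect_lt(mean(s[cl$labels == "CR"]), 0)
  # duplicated sample gets an identical score
  dup <- spectra_set(ds$wavenumbers, ds$matrix[c(1, 1), ],
                     data.frame(sample_id = c("a", "b"), patient_id = "p",
                                group = "CR"))
  s2 <- decision_scores(model, dup)
  expect_equal(unname(s2[1]), unname(s2[2]))
  expect_error(decision_scores(model, crop_region(ds, 600, 602)),
               "alignment")
})

test_that("rank AUC equals the exhaustive pairwise oracle, with symmetries", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc,
               1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(7)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, pairwise_auc(scores, pos), tolerance = 1e-12)
    # label inversion mirrors the AUC
    expect_equal(roc_auc(scores, !pos)$auc, 1 - r$auc, tolerance = 1e-12)
    # curve is a monotone sweep
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "label error")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(60)
  pos <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, pos)$auc, ref, tolerance = 1e-12)
})

test_that("confusion metrics follow their defining ratios", {
  m <- confusion_metrics(tp = 93, fp = 8, tn = 92, fn = 2)
  expect_equal(m$accuracy, 185 / 195)
  expect_equal(m$sensitivity, 93 / 95)
  expect_equal(m$specificity, 92 / 100)
  perfect <- confusion_metrics(1, 0, 1, 0)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  deg <- confusion_metrics(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_true(is.na(deg$sensitivity))
  expect_equal(deg$undefined, "sensitivity")
  expect_error(confusion_metrics(-1, 0, 1, 0), ">= 0")
})

test_that("cross-validation is stratified, seeded, and honest on nulls", {
  cl <- gaussian_clusters(40, sep = 8, seed = 10)
  ds <- as_set(cl$x, cl$labels)
  cv <- cross_validate(ds, folds = 5, seed = 3)
  expect_equal(cv$metrics$accuracy, 1.0)
  expect_equal(cv$roc$auc, 1.0)
  # per-class fold counts are balanced
  expect_true(all(table(cv$fold, cl$labels) == 8))
  cv2 <- cross_validate(ds, folds = 5, seed = 3)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$scores, cv2$scores)

  # label-shuffled data: AUC near chance
  set.seed(11)
  null <- as_set(matrix(rnorm(600 * 30), ncol = 30),
                 sample(rep(c("CR", "NR"), each = 300)))
  cvn <- cross_validate(null, folds = 10, seed = 4)
  expect_lt(abs(cvn$roc$auc - 0.5), 0.08)
  expect_error(cross_validate(subset_spectra(ds, c(1:6, 41:46)), folds = 10,
                              seed = 1),
               "fold error")
})

test_that("permutation test is seeded and calibrated in both regimes", {
  cl <- gaussian_clusters(30, sep = 8, seed = 12)
  ds <- as_set(cl$x, cl$labels)
  pt <- permutation_test(ds, n_permutations = 49, folds = 5, seed = 5)
  # strong contrast: observed beats every permuted refit
  expect_equal(pt$p_value, 1 / 50)
  pt2 <- permutation_test(ds, n_permutations = 49, folds = 5, seed = 5)
  expect_identical(pt$null_aucs, pt2$null_aucs)
  expect_error(permutation_test(ds, n_permutations = 0), "parameter")

  set.seed(13)
  null <- as_set(matrix(rnorm(80 * 10), ncol = 10),
                 rep(c("CR", "NR"), each = 40))
  ptn <- permutation_test(null, n_permutations = 49, folds = 5, seed = 6)
  expect_gt(ptn$p_value, 0.05)
  expect_lt(abs(mean(ptn$null_aucs) - 0.5), 0.1)
})

test_that("patient aggregation averages rows and inherits group labels", {
  ds <- tiny_set()  # p1 has two spectra, p2 one
  agg <- patient_mean_spectra(ds)
  expect_equal(n_spectra(agg), 2)
  expect_equal(agg$matrix[1, ], unname(colMeans(ds$matrix[1:2, ])))
  expect_equal(agg$meta$group, c("CR", "NR"))
  expect_equal(agg$wavenumbers, ds$wavenumbers)
  # a patient with identical duplicate spectra keeps that spectrum
  dup <- spectra_set(ds$wavenumbers, ds$matrix[c(1, 1), ],
                     data.frame(sample_id = c("a", "b"), patient_id = "p",
                                group = "CR"))
  expect_equal(patient_mean_spectra(dup)$matrix[1, ],
               unname(ds$matrix[1, ]))
  # 18 patients in -> 18 rows out
  set.seed(14)
  big <- as_set(matrix(rnorm(36 * 8), ncol = 8),
                rep(c("CR", "NR"), each = 18),
                patients = rep(sprintf("q%02d", 1:18), each = 2))
  expect_equal(n_spectra(patient_mean_spectra(big)), 18)
  # mixed groups within a patient are an error
  bad <- tiny_set()
  bad$meta$patient_id <- "same"
  expect_error(patient_mean_spectra(spectra_set(bad$wavenumbers, bad$matrix,
                                                bad$meta)),
               "mixed groups")
})

test_that("LD1 contributions are a normalized, order-equivariant profile", {
  cl <- gaussian_clusters(40, sep = 3, seed = 15)
  ds <- as_set(cl$x, cl$labels)
  model <- fit_pca_lda(ds, var_threshold = 0.95)
  contrib <- ld1_pc_contributions(model)
  expect_equal(sum(contrib), 1)
  expect_length(contrib, model$n_components)
  # single-component model concentrates everything
  one <- fit_pca_lda(ds, var_threshold = 1e-6)
  expect_equal(unname(ld1_pc_contributions(one)), 1)
  # permuting the score columns permutes the contributions
  sc <- pca_scores(model$pca, ds$matrix, model$n_components)
  perm <- rev(seq_len(ncol(sc)))
  lda_p <- fit_lda(sc[, perm], cl$labels)
  cp <- abs(lda_p$weights) / sum(abs(lda_p$weights))
  expect_equal(unname(cp), unname(contrib[perm]), tolerance = 1e-8)
})
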