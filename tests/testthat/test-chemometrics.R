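test_that("PCA handles one-dimensional data and conserves variance", {
  m <- fit_pca(rbind(c(1, 0), c(-1, 0)))
  expect_equal(m$explained_variance_ratio, 1)
  expect_equal(abs(unname(m$loadings[1, ])), c(1, 0))

  set.seed(4)
  X <- matrix(rnorm(80), 10, 8)
  m2 <- fit_pca(X)
  total <- sum(diag(cov(X))) * (nrow(X) - 1)
  expect_equal(sum(m2$explained_variance_ratio), 1, tolerance = 1e-9)
  expect_equal(sum(m2$sdev^2) * (nrow(X) - 1), total, tolerance = 1e-9)
  # reconstruction from all components
  rec <- m2$scores %*% m2$loadings +
    matrix(m2$mean_spectrum, 10, 8, byrow = TRUE)
  expect_equal(rec, X, tolerance = 1e-9)
})

test_that("PCA loadings are orthonormal and scores uncorrelated (tall data)", {
  set.seed(5)
  X <- matrix(rnorm(15 * 40), 15, 40)   # p > n triggers the Gram route
  m <- fit_pca(X)
  G <- m$loadings %*% t(m$loadings)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-8, ignore_attr = TRUE)
  S <- crossprod(sweep(m$scores, 2, colMeans(m$scores)))
  off <- abs(S - diag(diag(S)))
  expect_lt(max(off), 1e-8 * max(diag(S)))
  # agrees with prcomp on the same data
  pr <- prcomp(X)
  k <- ncol(m$scores)
  expect_equal(abs(m$scores[, 1:3]), abs(pr$x[, 1:3]), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(fit_pca(matrix(1, 5, 4)), "zero variance")
})

test_that("t-test selection keeps separated components and flags undefined ones", {
  set.seed(6)
  n <- 30
  scores <- cbind(c(rnorm(n, 0), rnorm(n, 5)),   # 5 pooled SDs apart
                  rnorm(2 * n),
                  rep(1, 2 * n))                 # zero variance, equal means
  labels <- rep(c("intact", "damaged"), each = n)
  expect_warning(sel <- select_pcs_ttest(scores, labels), "undefined")
  expect_true(1 %in% sel$selected)
  expect_false(3 %in% sel$selected)
  # closed-form pooled-t oracle for component 1
  x1 <- scores[labels == "intact", 1]
  x0 <- scores[labels == "damaged", 1]
  sp2 <- (var(x1) * (n - 1) + var(x0) * (n - 1)) / (2 * n - 2)
  tval <- (mean(x1) - mean(x0)) / sqrt(sp2 * 2 / n)
  expect_equal(sel$statistic[1], tval, tolerance = 1e-12)
  expect_equal(sel$p_values[1], 2 * pt(-abs(tval), 2 * n - 2),
               tolerance = 1e-12)
})

test_that("a relabelled copy of one class is almost never selected", {
  set.seed(8)
  hits <- replicate(40, {
    x <- rnorm(40)
    labels <- rep(c("intact", "damaged"), each = 20)
    length(select_pcs_ttest(matrix(x, ncol = 1), labels)$selected)
  })
  expect_lte(mean(hits), 0.10)
})

test_that("LDA matches the explicit pooled-covariance solve", {
  # 1-D symmetric case: threshold at zero
  x <- matrix(c(-1.2, -0.8, -1.1, -0.9, 0.8, 1.2, 0.9, 1.1), ncol = 1)
  lab <- rep(c("intact", "damaged"), each = 4)
  m <- fit_lda(x, lab)
  expect_equal(m$threshold, 0, tolerance = 1e-12)
  pr <- predict(m, x)
  expect_equal(pr$labels, lab)

  set.seed(9)
  X <- matrix(rnorm(16), 8, 2)
  lab2 <- rep(c("damaged", "intact"), each = 4)
  m2 <- fit_lda(X, lab2)
  S <- (cov(X[1:4, ]) * 3 + cov(X[5:8, ]) * 3) / 6
  w_oracle <- solve(S, colMeans(X[1:4, ]) - colMeans(X[5:8, ]))
  expect_equal(unname(m2$w), unname(w_oracle), tolerance = 1e-10)

  # identical class means with non-degenerate spread
  pts <- matrix(c(0, 0, 1, 1, 2, 0, 3, 1), ncol = 2, byrow = TRUE)
  same <- rbind(pts, pts)
  expect_error(fit_lda(same, rep(c("intact", "damaged"), each = 4)),
               "degenerate")
})

test_that("LDA direction agrees with MASS::lda up to scale", {
  skip_if_not_installed("MASS")
  set.seed(10)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 1.5), 20, 2))
  lab <- rep(c("intact", "damaged"), each = 20)
  m <- fit_lda(X, lab)
  ref <- MASS::lda(X, grouping = lab)
  ratio <- m$w / drop(ref$scaling)
  expect_equal(abs(ratio[1]), abs(ratio[2]), tolerance = 1e-6)
})

test_that("LDA predictions use the documented tie rule and affine ordering", {
  x <- matrix(c(-1, -1.2, -0.9, -1.1, 1, 1.2, 0.9, 1.1), ncol = 1)
  lab <- rep(c("intact", "damaged"), each = 4)
  m <- fit_lda(x, lab)
  at_thr <- matrix(m$threshold / m$w, ncol = 1)
  expect_equal(predict(m, at_thr)$labels, "damaged")
  d <- predict(m, matrix(seq(-2, 2, 0.5), ncol = 1))$decision_values
  expect_true(all(diff(d) * sign(m$w) > 0))  # affine, order preserving
  expect_error(predict(m, matrix(0, 1, 2)), "features")
})

test_that("PLS-DA on a single informative column is exact", {
  y <- rep(c(0, 1), each = 10)
  lab <- ifelse(y == 1, "damaged", "intact")
  X <- matrix(y, ncol = 1)
  m <- fit_plsda(X, lab, n_lv = 1)
  pr <- predict(m, X)
  expect_equal(pr$response, y, tolerance = 1e-10)
  expect_equal(pr$labels, lab)
})

test_that("full-rank PLS equals least squares and scores are orthogonal", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rep(c(0, 1), each = 10)
  lab <- ifelse(y == 1, "damaged", "intact")
  m <- fit_plsda(X, lab, n_lv = 6)
  beta <- ols_fit(X, y)
  yhat_ols <- drop(cbind(1, X) %*% beta)
  expect_equal(predict(m, X)$response, yhat_ols, tolerance = 1e-8)
  G <- crossprod(m$x_scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8 * max(diag(G)))
  expect_error(fit_plsda(X, lab, n_lv = 25), "rank")
})

test_that("PLS-DA centering removes constant offsets and ties go positive", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  lab <- rep(c("damaged", "intact"), 10)
  m1 <- fit_plsda(X, lab, n_lv = 2)
  m2 <- fit_plsda(X + 5, lab, n_lv = 2)
  expect_equal(predict(m1, X)$response, predict(m2, X + 5)$response,
               tolerance = 1e-8)
  # response exactly at the threshold classifies as the positive class
  stub <- m1
  stub$coefficients[] <- 0
  stub$intercept <- stub$threshold
  expect_true(all(predict(stub, X)$labels == "damaged"))
})

test_that("the classifier front end predicts separable cohorts perfectly", {
  cfg <- tiny_cohort(noise_sd = 0, subject_sd = 0, severity_sd = 0,
                     discordant_frac = 0)
  coh <- generate_cohort(cfg)
  l <- coh$truth$library
  pp <- preprocess_spectra(coh$set, reference = l$sperm_reference,
                           interferents = list(glass = l$glass,
                                               agarose = l$agarose))
  for (method in c("pca-lda", "pls-da")) {
    fit <- raman_classifier(pp, method = method)
    pr <- predict(fit, pp)
    expect_equal(pr$labels, pp$meta$label)
  }
  expect_error(predict(raman_classifier(pp, method = "pls-da"),
                       pp$intensities[, 1:5]), "channels")
})
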