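lib <- reference_library(seq(600, 1800, by = 2))

test_that("least squares recovers exact superposition coefficients", {
  m <- fit_emsc(lib$sperm_reference, lib$sperm_reference,
                list(glass = lib$glass, agarose = lib$agarose),
                wavenumber = lib$wavenumber)
  expect_equal(m$b, 1, tolerance = 1e-10)
  expect_lt(max(abs(m$c)), 1e-10)
  expect_lt(max(abs(m$p)), 1e-10)

  u <- (lib$wavenumber - 600) / 600 - 1   # rescaled axis in [-1, 1]
  y <- 0.8 * lib$sperm_reference + 0.5 * lib$glass + 0.2 * lib$agarose +
    0.1 + 0.05 * u
  m2 <- fit_emsc(y, lib$sperm_reference,
                 list(glass = lib$glass, agarose = lib$agarose),
                 wavenumber = lib$wavenumber)
  expect_equal(m2$b, 0.8, tolerance = 1e-8)
  expect_equal(unname(m2$c), c(0.5, 0.2), tolerance = 1e-8)
  expect_equal(m2$p[1:2], c(0.1, 0.05), tolerance = 1e-8)
  expect_lt(max(abs(m2$p[3:5])), 1e-8)
})

test_that("rank-deficient designs fail naming the offending column", {
  expect_error(fit_emsc(lib$glass, lib$sperm_reference,
                        list(glass = lib$glass, glass2 = lib$glass),
                        wavenumber = lib$wavenumber),
               "rank deficient.*glass2")
})

test_that("correction modes subtract interference or normalize by b", {
  y <- 0.8 * lib$sperm_reference + 0.5 * lib$glass + 0.2 * lib$agarose + 0.3
  m <- fit_emsc(y, lib$sperm_reference,
                list(glass = lib$glass, agarose = lib$agarose),
                wavenumber = lib$wavenumber)
  sub <- emsc_correct(y, m, "subtract")
  expect_equal(sub, 0.8 * lib$sperm_reference, tolerance = 1e-8)
  nrm <- emsc_correct(y, m, "normalize")
  expect_equal(nrm, lib$sperm_reference, tolerance = 1e-8)
})

test_that("a pure interferent spectrum corrects to numeric zero", {
  # orthogonalize the reference against glass so the design is clean
  ref_perp <- lib$sperm_reference -
    sum(lib$sperm_reference * lib$glass) * lib$glass
  ref_perp <- ref_perp / sqrt(sum(ref_perp^2))
  y <- lib$glass
  m <- fit_emsc(y, ref_perp, list(glass = lib$glass),
                wavenumber = lib$wavenumber)
  corr <- emsc_correct(y, m, "subtract")
  # independent least-squares oracle on the same design
  B <- cbind(ref_perp, lib$glass)
  beta <- qr.coef(qr(B), y)
  expect_equal(unname(m$b), unname(beta[1]), tolerance = 1e-8)
  expect_lt(max(abs(corr - m$b * ref_perp)), 1e-6 * max(abs(y)))
})

test_that("residuals are orthogonal to the design and nested fits are monotone", {
  set.seed(21)
  y <- lib$sperm_reference + 0.4 * lib$glass + rnorm(length(lib$glass), 0, 0.01)
  m1 <- fit_emsc(y, lib$sperm_reference, list(), poly_order = 4,
                 wavenumber = lib$wavenumber)
  m2 <- fit_emsc(y, lib$sperm_reference, list(glass = lib$glass),
                 poly_order = 4, wavenumber = lib$wavenumber)
  m3 <- fit_emsc(y, lib$sperm_reference,
                 list(glass = lib$glass, agarose = lib$agarose),
                 poly_order = 4, wavenumber = lib$wavenumber)
  expect_lte(m2$residual_norm, m1$residual_norm + 1e-12)
  expect_lte(m3$residual_norm, m2$residual_norm + 1e-12)
  resid <- y - m3$fitted
  for (col in list(lib$sperm_reference, lib$glass, lib$agarose))
    expect_lt(abs(sum(resid * col)),
              1e-8 * sqrt(sum(resid^2)) * sqrt(sum(col^2)) + 1e-12)
})

test_that("batch EMSC recovers per-spectrum weights and reports bad rows", {
  cfg <- tiny_cohort(noise_sd = 0, effect_scale = 0, subject_sd = 0)
  coh <- generate_cohort(cfg)
  l <- coh$truth$library
  res <- batch_emsc(coh$set, l$sperm_reference,
                    list(glass = l$glass, agarose = l$agarose))
  expect_equal(nrow(res$failures), 0)
  expect_gt(cor(res$coefficients$c_glass, coh$truth$table$c_glass), 0.999)

  X <- coh$set$intensities[1:10, ]
  X[4, 100] <- NaN
  bad <- spectrum_set(coh$set$wavenumber, X, coh$set$meta[1:10, ],
                      allow_na = TRUE)
  res2 <- batch_emsc(bad, l$sperm_reference,
                     list(glass = l$glass, agarose = l$agarose))
  expect_equal(n_spectra(res2$corrected), 9)
  expect_equal(res2$failures$spectrum_id, coh$set$meta$spectrum_id[4])

  empty <- spectrum_set(coh$set$wavenumber,
                        matrix(0, 0, n_channels(coh$set)),
                        data.frame(spectrum_id = character(0)))
  res3 <- batch_emsc(empty, l$sperm_reference, list(glass = l$glass))
  expect_equal(n_spectra(res3$corrected), 0)
  expect_equal(nrow(res3$failures), 0)
})
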