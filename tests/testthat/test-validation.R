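meta10 <- data.frame(spectrum_id = paste0("S", 1:10),
                     cell_id = paste0("c", 1:10),
                     subject_id = rep(c("p1", "p2"), 5),
                     label = rep(c("intact", "damaged"), each = 5),
                     stringsAsFactors = FALSE)

test_that("fold plans partition the rows and never split a group", {
  plan <- make_folds(meta10, "loocv", grouping = "cell")
  expect_length(plan$folds, 10)
  expect_true(all(lengths(lapply(plan$folds, `[[`, "test")) == 1))

  kf <- make_folds(meta10, "kfold", k = 5, grouping = "cell", seed = 3)
  tests <- lapply(kf$folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  expect_true(all(lengths(tests) == 2))

  # grouped folds keep all rows of a group together (randomized metadata)
  set.seed(14)
  meta_g <- data.frame(spectrum_id = paste0("S", 1:30),
                       cell_id = paste0("c", sample(1:12, 30, replace = TRUE)),
                       label = sample(c("intact", "damaged"), 30, TRUE),
                       stringsAsFactors = FALSE)
  meta_g$cell_id <- make.unique(meta_g$cell_id)   # cells unique; group by subject
  meta_g$subject_id <- paste0("p", rep(1:5, each = 6))
  kg <- suppressWarnings(make_folds(meta_g, "kfold", k = 3,
                                    grouping = "subject", seed = 1))
  for (f in kg$folds) {
    subs_te <- unique(meta_g$subject_id[f$test])
    subs_tr <- unique(meta_g$subject_id[f$train])
    expect_length(intersect(subs_te, subs_tr), 0)
  }
})

test_that("fold plans are deterministic in the seed", {
  a <- make_folds(meta10, "kfold", k = 5, grouping = "cell", seed = 7)
  b <- make_folds(meta10, "kfold", k = 5, grouping = "cell", seed = 7)
  d <- make_folds(meta10, "kfold", k = 5, grouping = "cell", seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$folds, d$folds))
  expect_error(make_folds(meta10, "kfold", k = 11, grouping = "cell"), "k must")
  expect_warning(make_folds(meta10, "kfold", k = 2, grouping = "subject"),
                 "both class labels")
})

test_that("confusion metrics evaluate the printed formulas", {
  pred <- c(rep("damaged", 3), "intact",               # 3 TP, 1 FN
            rep("intact", 4), rep("damaged", 2))       # 4 TN, 2 FP
  truth <- c(rep("damaged", 4), rep("intact", 6))
  m <- confusion_metrics(pred, truth, "damaged")
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.7)
  expect_equal(unname(m$counts), c(3, 2, 4, 1))

  allneg <- rep("intact", 10)
  m2 <- confusion_metrics(allneg, truth, "damaged")
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_error(confusion_metrics(pred, rep("damaged", 10), "damaged"),
               "single class")
})

test_that("trapezoidal AUC equals the exhaustive pair-count statistic", {
  set.seed(15)
  for (i in 1:10) {
    n <- 20
    truth <- sample(c("damaged", "intact"), n, replace = TRUE,
                    prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) truth[1:2] <- c("damaged", "intact")
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # ties guaranteed
    roc <- roc_auc(scores, truth, "damaged")
    expect_equal(roc$auc, pair_count_auc(scores, truth), tolerance = 1e-12)
    expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
    expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
    expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]),
                 c(1, 1))
  }
})

test_that("ROC symmetry, degenerate scores, and permutation invariance", {
  truth <- rep(c("damaged", "intact"), each = 5)
  scores <- c(6:10, 1:5)
  expect_equal(roc_auc(scores, truth, "damaged")$auc, 1)
  expect_equal(roc_auc(-scores, truth, "damaged")$auc, 0)
  expect_warning(r0 <- roc_auc(rep(1, 10), truth, "damaged"), "constant")
  expect_equal(r0$auc, 0.5)
  perm <- sample(10)
  expect_equal(roc_auc(scores[perm], truth[perm], "damaged")$auc, 1)
})

test_that("cross-validation is perfect on a separable cohort and leak-free", {
  cfg <- tiny_cohort(noise_sd = 0, subject_sd = 0, severity_sd = 0,
                     discordant_frac = 0)
  coh <- generate_cohort(cfg)
  l <- coh$truth$library
  pp <- preprocess_spectra(coh$set, reference = l$sperm_reference,
                           interferents = list(glass = l$glass,
                                               agarose = l$agarose))
  plan <- make_folds(pp$meta, "loocv", grouping = "cell")
  cv <- cross_validate(pp, pipeline_config("pls-da", n_lv = 3), plan)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auc, 1)

  # leakage canary: a channel equal to the label in ONE fold's test rows
  # (noise elsewhere) must not raise that fold's accuracy, because the fold
  # is trained without those rows
  noisy <- generate_cohort(tiny_cohort(effect_scale = 0, seed = 5))
  ppn <- preprocess_spectra(noisy$set, reference = l$sperm_reference,
                            interferents = list(glass = l$glass,
                                                agarose = l$agarose))
  kf2 <- make_folds(ppn$meta, "kfold", k = 2, grouping = "cell", seed = 2)
  base_cv <- cross_validate(ppn, pipeline_config("pls-da", n_lv = 2), kf2)
  te <- kf2$folds[[1]]$test
  set.seed(33)
  canary <- rnorm(n_spectra(ppn), 0, 0.001)
  canary[te] <- ifelse(ppn$meta$label[te] == "damaged", 1, 0)
  spiked <- spectrum_set(c(ppn$wavenumber, max(ppn$wavenumber) + 1),
                         cbind(ppn$intensities, canary), ppn$meta)
  spike_cv <- cross_validate(spiked, pipeline_config("pls-da", n_lv = 2), kf2)
  fold_acc <- function(cv) {
    p <- cv$predictions[te, ]
    mean(p$predicted == p$truth)
  }
  expect_lte(fold_acc(spike_cv), fold_acc(base_cv) + 0.2)
  expect_lt(fold_acc(spike_cv), 1)
})

test_that("a training fold lacking one class raises a fold error", {
  cfg <- tiny_cohort(n_intact = 6, n_damaged = 2, n_subjects = 2)
  coh <- generate_cohort(cfg)
  meta <- coh$set$meta
  plan <- make_folds(meta, "loocv", grouping = "cell")
  # force a fold whose training rows are single-class
  dmg <- which(meta$label == "damaged")
  plan$folds[[1]]$train <- setdiff(plan$folds[[1]]$train, dmg)
  plan$folds[[1]]$test <- seq_len(nrow(meta))[-plan$folds[[1]]$train]
  expect_error(cross_validate(coh$set, pipeline_config("pls-da", n_lv = 2),
                              plan),
               "lacks one class")
})
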