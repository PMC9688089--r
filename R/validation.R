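#' Build a cross-validation fold plan
#'
#' `loocv` produces one fold per group; `kfold` shuffles the groups with the
#' given seed and deals them into `k` near-equal folds.  Grouping controls
#' the unit that is never split across train and test: `"cell"` (the
#' default; with one spectrum per cell this is leave-one-spectrum-out),
#' `"subject"`, or `"spectrum"`.  Stratified k-fold balances class counts
#' across folds where the group labels allow.
#'
#' @param meta metadata `data.frame` (needs `cell_id`/`subject_id` for those
#'   groupings, and `label` for stratification).
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k number of folds (k-fold only; default 10).
#' @param grouping `"cell"`, `"subject"` or `"spectrum"`.
#' @param seed integer seed for the shuffle (mandatory for k-fold
#'   reproducibility).
#' @param stratified balance class counts per fold (k-fold only; default
#'   `TRUE`).
#' @return an object of class `fold_plan`; `$folds` is a list of
#'   `list(train, test)` row-index vectors.
#' @export
make_folds <- function(meta, scheme = c("loocv", "kfold"), k = 10L,
                       grouping = c("cell", "subject", "spectrum"),
                       seed = 1L, stratified = TRUE) {
  scheme <- match.arg(scheme)
  grouping <- match.arg(grouping)
  n <- nrow(meta)
  gid <- switch(grouping,
                spectrum = as.character(seq_len(n)),
                cell = {
                  if (is.null(meta$cell_id)) stop("grouping = cell needs a cell_id column")
                  as.character(meta$cell_id)
                },
                subject = {
                  if (is.null(meta$subject_id)) stop("grouping = subject needs a subject_id column")
                  as.character(meta$subject_id)
                })
  groups <- unique(gid)
  ng <- length(groups)
  glabel <- NULL
  if (!is.null(meta$label)) {
    mixed <- character(0)
    glabel <- vapply(groups, function(g) {
      labs <- unique(meta$label[gid == g])
      if (length(labs) > 1L) {
        mixed <<- c(mixed, g)
        labs <- names(which.max(table(meta$label[gid == g])))
      }
      labs
    }, character(1))
    if (length(mixed))
      warning(length(mixed), " group(s) contain both class labels under ",
              "grouping = ", grouping, " (e.g. ", mixed[1L],
              "); folds remain valid", call. = FALSE)
  }
  if (scheme == "loocv") {
    folds <- lapply(groups, function(g) {
      te <- which(gid == g)
      list(train = setdiff(seq_len(n), te), test = te)
    })
  } else {
    k <- as.integer(k)
    if (k < 2L || k > ng)
      stop("k must satisfy 2 <= k <= number of groups (", ng, ")")
    fold_of_group <- with_preserved_rng(seed, {
      fog <- integer(ng)
      names(fog) <- groups
      if (stratified && !is.null(glabel)) {
        offset <- 0L
        for (cl in unique(glabel)) {
          gs <- sample(groups[glabel == cl])
          fog[gs] <- ((offset + seq_along(gs) - 1L) %% k) + 1L
          offset <- offset + length(gs)
        }
      } else {
        fog[sample(groups)] <- rep_len(seq_len(k), ng)
      }
      fog
    })
    folds <- lapply(seq_len(k), function(f) {
      te <- which(gid %in% names(fold_of_group)[fold_of_group == f])
      list(train = setdiff(seq_len(n), te), test = te)
    })
  }
  structure(list(scheme = scheme, k = if (scheme == "kfold") k else NA_integer_,
                 grouping = grouping, seed = seed,
                 stratified = stratified && scheme == "kfold",
                 folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", x$scheme,
      if (x$scheme == "kfold") paste0(" (k = ", x$k, ")"),
      ", grouping = ", x$grouping, ", ", length(x$folds), " folds\n", sep = "")
  invisible(x)
}

#' Pipeline configuration for cross-validation
#'
#' Bundles the classifier and preprocessing choices used by
#' [cross_validate()].  Preprocessing steps act per spectrum (no parameters
#' are learned across spectra), so they are applied once before the folds;
#' everything trainable (PCA, t-test selection, LDA / PLS) is refit inside
#' every fold.
#'
#' @param method `"pca-lda"` or `"pls-da"`.
#' @param alpha,n_pcs,priors,n_lv,positive_class see [raman_classifier()].
#' @param threshold PLS-DA decision cut; the pipeline default is
#'   `"midpoint"` (class-mean midpoint), the imbalance-robust counterpart
#'   of the equal-prior LDA rule; pass `0.5` for the raw textbook cut.
#' @param preprocess logical: apply [preprocess_spectra()] first
#'   (default `FALSE`, i.e. the input is already preprocessed).
#' @param ... further arguments stored for [preprocess_spectra()] or
#'   [fit_plsda()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("pca-lda", "pls-da"), alpha = 0.05,
                            n_pcs = 20L, priors = "equal", n_lv = "auto",
                            positive_class = "damaged", preprocess = FALSE,
                            threshold = "midpoint", ...) {
  structure(list(method = match.arg(method), alpha = alpha, n_pcs = n_pcs,
                 priors = priors, n_lv = n_lv,
                 positive_class = positive_class, preprocess = preprocess,
                 extra = c(list(threshold = threshold), list(...))),
            class = "pipeline_config")
}

#' Cross-validate a classification pipeline
#'
#' For each fold the entire trainable chain (PCA, t-test component
#' selection, LDA or PLS-DA including the `"auto"` latent-variable search)
#' is refit on the training rows only; out-of-fold predictions are pooled
#' and the confusion metrics and ROC/AUC are computed once over the pooled
#' predictions (stable under the default cohort's heavy class imbalance).
#'
#' @param set a preprocessed [spectrum_set] with a two-class `label` column
#'   (or set `preprocess = TRUE` in the config and pass preprocessing
#'   arguments there).
#' @param config a [pipeline_config()].
#' @param plan a [make_folds()] plan on the same rows.
#' @return an object of class `cv_result`: `predictions` (per-spectrum
#'   out-of-fold label and score), `counts` (TP/FP/TN/FN),
#'   `sensitivity`, `specificity`, `accuracy`, `roc`, `auc`,
#'   `fold_diagnostics`.
#' @export
cross_validate <- function(set, config, plan) {
  stopifnot(inherits(set, "spectrum_set"), inherits(config, "pipeline_config"),
            inherits(plan, "fold_plan"))
  if (isTRUE(config$preprocess)) {
    pp_args <- config$extra[names(config$extra) %in%
                              names(formals(preprocess_spectra))]
    set <- do.call(preprocess_spectra, c(list(set), pp_args))
  }
  labels <- set$meta$label
  if (is.null(labels)) stop("metadata lacks a label column")
  n <- n_spectra(set)
  pred <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  fold_id <- rep(NA_integer_, n)
  diag_list <- vector("list", length(plan$folds))
  fit_args <- config$extra[names(config$extra) %in%
                             c("max_lv", "inner_folds", "inner_metric",
                               "cv_seed", "threshold", "ridge")]
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    te <- plan$folds[[f]]$test
    if (length(unique(labels[tr])) < 2L)
      stop("fold ", f, " training set lacks one class")
    model <- do.call(raman_classifier,
                     c(list(set$intensities[tr, , drop = FALSE],
                            labels = labels[tr],
                            method = config$method, alpha = config$alpha,
                            n_pcs = config$n_pcs, priors = config$priors,
                            n_lv = config$n_lv,
                            positive_class = config$positive_class),
                       fit_args))
    pr <- predict(model, set$intensities[te, , drop = FALSE])
    pred[te] <- pr$labels
    score[te] <- pr$score
    fold_id[te] <- f
    diag_list[[f]] <- data.frame(
      fold = f, n_train = length(tr), n_test = length(te),
      n_lv = if (config$method == "pls-da") model$plsda$n_lv else NA_integer_,
      n_pcs_selected = if (config$method == "pca-lda")
        length(model$components) else NA_integer_)
  }
  cm <- confusion_metrics(pred, labels, config$positive_class)
  roc <- roc_auc(score, labels, config$positive_class)
  structure(list(predictions = data.frame(
                   spectrum_id = set$meta$spectrum_id,
                   truth = labels, predicted = pred, score = score,
                   fold = fold_id, stringsAsFactors = FALSE),
                 counts = cm$counts,
                 sensitivity = cm$sensitivity,
                 specificity = cm$specificity,
                 accuracy = cm$accuracy,
                 roc = roc,
                 auc = roc$auc,
                 fold_diagnostics = do.call(rbind, diag_list),
                 config = config, plan_scheme = plan$scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$config$method, ", ", x$plan_scheme, " (",
      max(x$predictions$fold), " folds)\n", sep = "")
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  AUC %.3f\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              x$auc))
  cat("  counts: TP", x$counts["TP"], "FP", x$counts["FP"],
      "TN", x$counts["TN"], "FN", x$counts["FN"], "\n")
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("  per-fold diagnostics:\n")
  print(utils::head(object$fold_diagnostics, 10L))
  invisible(object)
}

#' Confusion-matrix metrics for a two-class prediction
#'
#' Sensitivity = TP/(TP+FN) (true-positive rate among the positive class),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n.
#'
#' @param pred predicted labels.
#' @param truth true labels (must contain both classes).
#' @param positive_class the diagnostic positive label.
#' @return a list: `counts` (named TP/FP/TN/FN), `sensitivity`,
#'   `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(pred, truth, positive_class = "damaged") {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  if (length(unique(truth)) < 2L)
    stop("truth contains a single class; sensitivity or specificity undefined")
  if (!positive_class %in% truth)
    stop("positive_class ", sQuote(positive_class), " absent from truth")
  tp <- sum(pred == positive_class & truth == positive_class)
  fp <- sum(pred == positive_class & truth != positive_class)
  fn <- sum(pred != positive_class & truth == positive_class)
  tn <- sum(pred != positive_class & truth != positive_class)
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(truth))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores in descending order;
#' tied scores step simultaneously, which makes the trapezoidal area equal
#' to the Mann-Whitney statistic (concordant pairs + half the ties over
#' n_pos * n_neg).
#'
#' @param scores continuous classifier scores (higher = more positive).
#' @param truth true labels (both classes present).
#' @param positive_class the diagnostic positive label.
#' @return an object of class `roc_curve`: `thresholds`, `tpr`, `fpr`,
#'   `auc`.  Constant scores give a degenerate curve with AUC 0.5 and a
#'   warning.
#' @export
roc_auc <- function(scores, truth, positive_class = "damaged") {
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(truth)) < 2L)
    stop("truth contains a single class")
  pos <- truth == positive_class
  np <- sum(pos)
  nn <- sum(!pos)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- pos[o]
  # collapse tied scores into simultaneous steps
  last <- rev(!duplicated(rev(s)))       # TRUE at the last index of each tie run
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  thresholds <- s[last]
  tpr <- c(0, tp / np)
  fpr <- c(0, fp / nn)
  if (length(unique(s)) == 1L)
    warning("constant scores: degenerate ROC curve, AUC = 0.5")
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", length(x$thresholds), " thresholds, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l",
                 xlab = "False-positive rate (1 - specificity)",
                 ylab = "True-positive rate (sensitivity)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}
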