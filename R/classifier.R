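#' Fit a sperm DNA-integrity classifier on preprocessed spectra
#'
#' The package's central fitting function.  Two methods are available:
#' \describe{
#'   \item{`"pca-lda"`}{PCA of the spectral matrix, selection of the
#'     components whose scores separate the classes (two-sample t-test,
#'     `p < alpha`), then two-class Fisher LDA on the selected scores.}
#'   \item{`"pls-da"`}{PLS regression of a 0/1 class coding on the full
#'     spectra, thresholded at 0.5.}
#' }
#' Input spectra are expected to be preprocessed (baseline-corrected,
#' EMSC-corrected, vector-normalized); see [preprocess_spectra()].
#'
#' If the t-test selects no component at level `alpha` (as happens on null
#' data inside cross-validation folds), the single component with the
#' smallest p-value is used so that a model can always be fitted.
#'
#' @param x a [spectrum_set] with a two-class `label` column, or a numeric
#'   matrix plus `labels`.
#' @param labels class labels (taken from `x$meta$label` when omitted).
#' @param method `"pca-lda"` or `"pls-da"`.
#' @param alpha t-test level for PC selection (default 0.05).
#' @param n_pcs number of leading PCs made available for selection
#'   (default 20).
#' @param priors LDA priors, `"equal"` (default) or `"empirical"`.
#' @param n_lv PLS latent variables (integer or `"auto"`, the default).
#' @param positive_class the diagnostic positive label (default `"damaged"`).
#' @param ... passed on to [fit_plsda()] (e.g. `max_lv`, `cv_seed`).
#' @return an object of class `raman_classifier`.
#' @export
raman_classifier <- function(x, labels = NULL,
                             method = c("pca-lda", "pls-da"),
                             alpha = 0.05, n_pcs = 20L,
                             priors = "equal", n_lv = "auto",
                             positive_class = "damaged", ...) {
  method <- match.arg(method)
  X <- spectra_matrix(x)
  if (is.null(labels)) {
    if (!inherits(x, "spectrum_set") || is.null(x$meta$label))
      stop("labels must be given (or present in the metadata)")
    labels <- x$meta$label
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("length(labels) != number of spectra")
  fit <- list(method = method, positive_class = positive_class,
              n_channels = ncol(X),
              classes = unique(labels))
  if (method == "pca-lda") {
    pca <- fit_pca(X, n_components = n_pcs)
    sel <- select_pcs_ttest(pca$scores, labels, alpha = alpha)
    comps <- sel$selected
    if (!length(comps)) comps <- which.min(sel$p_values)
    lda <- fit_lda(pca$scores[, comps, drop = FALSE], labels,
                   priors = priors, positive_class = positive_class)
    fit$pca <- pca
    fit$selection <- sel
    fit$components <- comps
    fit$lda <- lda
  } else {
    fit$plsda <- fit_plsda(X, labels, n_lv = n_lv,
                           positive_class = positive_class, ...)
  }
  class(fit) <- "raman_classifier"
  fit
}

#' @export
print.raman_classifier <- function(x, ...) {
  cat("<raman_classifier> method =", x$method, "\n")
  if (x$method == "pca-lda") {
    cat("  selected PCs:", paste0("PC", x$components, collapse = ", "),
        sprintf("(%.1f%% of variance)\n",
                100 * sum(x$pca$explained_variance_ratio[x$components])))
  } else {
    cat("  latent variables:", x$plsda$n_lv, "\n")
  }
  cat("  positive class:", x$positive_class, "\n")
  invisible(x)
}

#' @export
summary.raman_classifier <- function(object, ...) {
  print(object)
  if (object$method == "pca-lda") {
    k <- length(object$selection$p_values)
    cat("  t-test p-values (first ", min(k, 10L), "): ",
        paste(sprintf("%.3g", object$selection$p_values[seq_len(min(k, 10L))]),
              collapse = ", "), "\n", sep = "")
    cat("  LDA priors:", paste(names(object$lda$priors),
                               sprintf("%.3f", object$lda$priors),
                               sep = ":", collapse = ", "), "\n")
  } else {
    cat("  PLS intercept:", format(object$plsda$intercept, digits = 4),
        "; threshold:", object$plsda$threshold, "\n")
  }
  invisible(object)
}

#' @export
coef.raman_classifier <- function(object, ...) {
  if (object$method == "pca-lda") {
    # discriminant direction mapped back to spectral space
    w_pc <- object$lda$w
    drop(t(object$pca$loadings[object$components, , drop = FALSE]) %*% w_pc)
  } else {
    object$plsda$coefficients
  }
}

#' Predict class labels and continuous scores for new spectra
#'
#' @param object a [raman_classifier()] fit.
#' @param newdata [spectrum_set] or matrix on the training grid.
#' @param ... unused.
#' @return a list: `labels` and `score` (LDA decision value or PLS response).
#' @export
predict.raman_classifier <- function(object, newdata, ...) {
  X <- spectra_matrix(newdata)
  if (ncol(X) != object$n_channels)
    stop("newdata has ", ncol(X), " channels; model expects ",
         object$n_channels)
  if (object$method == "pca-lda") {
    sc <- project_pca(object$pca, X)[, object$components, drop = FALSE]
    pr <- predict(object$lda, sc)
    list(labels = pr$labels, score = pr$decision_values)
  } else {
    pr <- predict(object$plsda, X)
    list(labels = pr$labels, score = pr$response)
  }
}

#' Default preprocessing chain for raw sperm-on-glass spectra
#'
#' Applies, in order: closed-interval crop, Vancouver-style baseline removal,
#' Savitzky-Golay smoothing, EMSC interference subtraction against the given
#' reference library, and vector normalization.  Every step acts per
#' spectrum with no information shared across spectra, so the chain can be
#' applied once before cross-validation without leaking class information.
#'
#' @param set a raw [spectrum_set].
#' @param reference,interferents EMSC ingredients (see [fit_emsc()]); when
#'   `reference` is `NULL` the EMSC step is skipped.
#' @param crop_range length-2 numeric or `NULL` to skip cropping.
#' @param baseline_order,baseline_tol Vancouver baseline parameters
#'   (`NULL` order skips the step).
#' @param window,polyorder smoothing parameters (`NULL` window skips).
#' @param emsc_poly_order,emsc_mode EMSC parameters.
#' @param normalize apply final vector normalization (default `TRUE`).
#' @return the preprocessed `spectrum_set`.
#' @export
preprocess_spectra <- function(set, reference = NULL, interferents = list(),
                               crop_range = NULL,
                               baseline_order = 5L, baseline_tol = 1e-4,
                               window = 7L, polyorder = 3L,
                               emsc_poly_order = 4L, emsc_mode = "subtract",
                               normalize = TRUE) {
  stopifnot(inherits(set, "spectrum_set"))
  out <- set
  if (!is.null(crop_range))
    out <- crop(out, crop_range[1L], crop_range[2L])
  ref <- reference
  ints <- interferents
  if (!is.null(ref)) {
    fit_grid <- function(v) {
      v <- spec_vector(v)
      if (length(v) != n_channels(out))
        stop("EMSC reference/interferent not on the (cropped) grid")
      v
    }
    ref <- fit_grid(ref)
    ints <- lapply(ints, fit_grid)
  }
  if (!is.null(baseline_order))
    out <- vancouver_baseline(out, order = baseline_order,
                              tol = baseline_tol)$corrected
  if (!is.null(window))
    out <- smooth_spectra(out, window = window, polyorder = polyorder)
  if (!is.null(ref)) {
    res <- batch_emsc(out, ref, ints, poly_order = emsc_poly_order,
                      mode = emsc_mode)
    if (nrow(res$failures))
      warning("EMSC failed for ", nrow(res$failures), " spectra; dropped")
    out <- res$corrected
  }
  if (normalize)
    out <- vector_normalize(out)
  out
}
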