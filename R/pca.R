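#' Principal component analysis of a spectral matrix
#'
#' Mean-centered singular value decomposition.  When there are more channels
#' than spectra the decomposition is computed from the `n x n` Gram matrix,
#' which is exact and much faster for typical Raman data
#' (hundreds of spectra, >1000 channels).
#'
#' @param x a [spectrum_set] or a numeric matrix (spectra in rows).
#' @param n_components number of components to retain (default: all
#'   `min(n - 1, p)` non-trivial components).
#' @return an object of class `pca_model`: `mean_spectrum`, `loadings`
#'   (components in rows, orthonormal), `explained_variance_ratio`
#'   (fractions of total variance), `scores` (`n x k`), `sdev`.
#' @export
fit_pca <- function(x, n_components = NULL) {
  X <- spectra_matrix(x)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2L) stop("PCA requires at least 2 spectra")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  total <- sum(Xc^2)
  if (total == 0) stop("data have zero variance; PCA is undefined")
  kmax <- min(n - 1L, p)
  k <- if (is.null(n_components)) kmax else min(as.integer(n_components), kmax)
  if (p > n) {
    G <- tcrossprod(Xc)                      # n x n
    eg <- eigen(G, symmetric = TRUE)
    keep <- seq_len(k)
    d2 <- pmax(eg$values[keep], 0)
    d <- sqrt(d2)
    U <- eg$vectors[, keep, drop = FALSE]
    nz <- d > max(d) * 1e-12
    V <- matrix(0, p, k)
    V[, nz] <- crossprod(Xc, U[, nz, drop = FALSE]) %*%
      diag(1 / d[nz], sum(nz))
    scores <- U %*% diag(d, k)
  } else {
    sv <- svd(Xc, nu = k, nv = k)
    d <- sv$d[seq_len(k)]
    d2 <- d^2
    V <- sv$v
    scores <- sv$u %*% diag(d, k)
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- t(V)
  rownames(loadings) <- colnames(scores)
  structure(list(mean_spectrum = mu,
                 loadings = loadings,
                 explained_variance_ratio = d2 / total,
                 scores = scores,
                 sdev = d / sqrt(n - 1)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5L, nrow(x$loadings))
  cat("<pca_model> ", nrow(x$scores), " spectra, ",
      nrow(x$loadings), " components\n", sep = "")
  cat("  explained variance (first ", k, "): ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio[seq_len(k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project new spectra onto a fitted PCA basis
#' @param model a `pca_model`.
#' @param x matrix or [spectrum_set] on the training grid.
#' @return score matrix (`n x k`).
#' @export
project_pca <- function(model, x) {
  X <- spectra_matrix(x)
  if (ncol(X) != length(model$mean_spectrum))
    stop("channel count does not match the PCA model")
  sweep(X, 2L, model$mean_spectrum) %*% t(model$loadings)
}

#' Select principal components by two-sample t-test of their scores
#'
#' Rather than keeping the largest-variance components, components whose
#' scores differ between the two classes (two-sided two-sample t-test,
#' pooled variance by default) at level `alpha` are retained, in their
#' original PC order.  No multiple-testing correction is applied.
#'
#' @param scores score matrix (`n x k`), e.g. from [fit_pca()].
#' @param labels two-class label vector of length `n`.
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance Student t (default `TRUE`); `FALSE` uses
#'   the Welch test.
#' @return an object of class `pc_selection`: `alpha`, `p_values`,
#'   `statistic`, `selected` (1-based component indices).
#' @export
select_pcs_ttest <- function(scores, labels, alpha = 0.05, var_equal = TRUE) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("need exactly two classes, got: ", paste(cls, collapse = ", "))
  i1 <- labels == cls[1L]
  n1 <- sum(i1)
  n0 <- sum(!i1)
  if (n1 < 2L || n0 < 2L) stop("each class needs at least 2 spectra")
  k <- ncol(scores)
  pv <- tstat <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    x1 <- scores[i1, j]
    x0 <- scores[!i1, j]
    if (var_equal) {
      sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
      dm <- mean(x1) - mean(x0)
      if (se == 0) {
        if (dm == 0) next  # undefined: no variance, no difference
        tstat[j] <- sign(dm) * Inf
        pv[j] <- 0
      } else {
        tstat[j] <- dm / se
        pv[j] <- 2 * stats::pt(-abs(tstat[j]), df = n1 + n0 - 2)
      }
    } else {
      tt <- tryCatch(stats::t.test(x1, x0, var.equal = FALSE),
                     error = function(e) NULL)
      if (!is.null(tt)) {
        tstat[j] <- unname(tt$statistic)
        pv[j] <- tt$p.value
      }
    }
  }
  if (anyNA(pv))
    warning("component(s) ", paste(which(is.na(pv)), collapse = ", "),
            " have undefined t-tests (zero variance, equal means); excluded")
  selected <- which(!is.na(pv) & pv < alpha)
  structure(list(alpha = alpha, p_values = pv, statistic = tstat,
                 selected = selected),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat("<pc_selection> alpha =", x$alpha, "; selected:",
      if (length(x$selected)) paste0("PC", x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

spectra_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) return(x$intensities)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  X
}
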