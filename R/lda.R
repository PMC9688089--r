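#' Two-class Fisher linear discriminant analysis
#'
#' Fits the classical two-class LDA in (typically PC-score) space: the
#' discriminant direction is \eqn{w = \Sigma^{-1}(\mu_{pos} - \mu_{neg})}
#' with \eqn{\Sigma} the pooled within-class covariance.  The decision
#' threshold on the discriminant axis is the midpoint of the projected class
#' means, shifted by the log prior ratio.
#'
#' With the default cohort's 361/65 class imbalance the prior choice is
#' consequential: `"equal"` priors (the default) weight both error types
#' equally, `"empirical"` priors favor the majority (intact) class.
#'
#' @param x numeric matrix of features (`n x d`), e.g. selected PC scores.
#' @param labels two-class label vector of length `n`.
#' @param priors `"equal"` (default) or `"empirical"` (class frequencies).
#' @param positive_class label treated as the diagnostic positive (default
#'   `"damaged"`).
#' @param ridge relative ridge (`ridge * trace/d`) added to the pooled
#'   covariance when it is numerically singular.
#' @return an object of class `lda_model` with `class_means`,
#'   `pooled_covariance`, `w`, `threshold`, `priors`, `positive_class`.
#' @export
fit_lda <- function(x, labels, priors = c("equal", "empirical"),
                    positive_class = "damaged", ridge = 1e-8) {
  priors <- match.arg(priors)
  X <- as.matrix(x)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("LDA requires exactly two classes, got: ", paste(cls, collapse = ", "))
  if (!positive_class %in% cls)
    stop("positive_class ", sQuote(positive_class), " absent from labels")
  neg <- setdiff(cls, positive_class)
  ip <- labels == positive_class
  np <- sum(ip)
  nn <- sum(!ip)
  if (np < 2L || nn < 2L) stop("each class needs at least 2 spectra")
  Xp <- X[ip, , drop = FALSE]
  Xn <- X[!ip, , drop = FALSE]
  mup <- colMeans(Xp)
  mun <- colMeans(Xn)
  S <- ((np - 1) * stats::cov(Xp) + (nn - 1) * stats::cov(Xn)) / (np + nn - 2)
  S <- as.matrix(S)
  if (rcond_safe(S) < 1e-12)
    S <- S + diag(ridge * sum(diag(S)) / ncol(S), ncol(S))
  w <- tryCatch(solve(S, mup - mun),
                error = function(e)
                  stop("pooled covariance is singular even after ",
                       "regularization", call. = FALSE))
  if (sqrt(sum(w^2)) == 0)
    stop("identical class means: degenerate LDA model (||w|| = 0)")
  pr <- if (priors == "equal") c(0.5, 0.5) else c(np, nn) / (np + nn)
  names(pr) <- c(positive_class, neg)
  threshold <- sum(w * (mup + mun)) / 2 - log(pr[1L] / pr[2L])
  structure(list(class_means = rbind(positive = mup, negative = mun),
                 pooled_covariance = S,
                 w = w,
                 threshold = unname(threshold),
                 priors = pr,
                 positive_class = positive_class,
                 negative_class = neg),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> ", length(x$w), "-dimensional discriminant; positive = ",
      x$positive_class, "; priors = ",
      paste(names(x$priors), sprintf("%.3f", x$priors), sep = ":",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Predict with a fitted LDA model
#'
#' The decision value is \eqn{d(x) = w^T x}; a spectrum is assigned the
#' positive class iff \eqn{d(x) \ge} threshold (ties classify as positive,
#' a deterministic rule).
#'
#' @param object an `lda_model`.
#' @param newdata feature matrix with the training dimensionality.
#' @param ... unused.
#' @return a list: `labels` (character) and `decision_values` (numeric, for
#'   ROC analysis).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$w))
    stop("newdata has ", ncol(X), " features; model expects ",
         length(object$w))
  d <- unname(drop(X %*% object$w))
  list(labels = ifelse(d >= object$threshold, object$positive_class,
                       object$negative_class),
       decision_values = d)
}

rcond_safe <- function(S) {
  if (nrow(S) == 1L) return(if (S[1L] > 0) 1 else 0)
  tryCatch(rcond(S), error = function(e) 0)
}
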