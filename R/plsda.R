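#' Partial least squares discriminant analysis (PLS1, two classes)
#'
#' Codes the classes as a 0/1 response (positive class -> 1) and fits
#' univariate-response partial least squares by the NIPALS deflation scheme:
#' each latent variable's weight vector maximizes covariance between the
#' X-scores and the response, X is deflated by the fitted loading after each
#' step, and the regression coefficients over channels are assembled from all
#' latent variables.  Successive X-score vectors are mutually orthogonal.
#'
#' `n_lv = "auto"` picks the number of latent variables in
#' `1..max_lv` by stratified inner k-fold cross-validation on the training
#' data, maximizing balanced accuracy (the mean of sensitivity and
#' specificity; plain accuracy is insensitive to the minority class under
#' heavy imbalance), with ties resolved toward fewer LVs.
#'
#' @param x a [spectrum_set] or numeric matrix (`n x p`).
#' @param labels two-class label vector.
#' @param n_lv number of latent variables, or `"auto"`.
#' @param positive_class label coded as 1 (default `"damaged"`).
#' @param threshold decision cut on the predicted response: a number
#'   (default 0.5, the textbook cut halfway between the 0/1 codes) or
#'   `"midpoint"`, the midpoint of the two class-mean training responses.
#'   With heavily unbalanced classes the fitted responses of the minority
#'   class are shrunk toward the grand mean and the raw 0.5 cut is
#'   miscalibrated; the class-midpoint rule is the standard remedy.
#' @param max_lv upper bound for the `"auto"` search (default 15).
#' @param inner_folds folds of the inner CV for `"auto"` (default 5).
#' @param inner_metric criterion the `"auto"` search maximizes:
#'   `"balanced_accuracy"` (default; robust to class imbalance) or plain
#'   `"accuracy"` (majority-dominated under imbalance, which makes the
#'   selection conservative on weak signals).
#' @param cv_seed seed for the inner CV split (default 1), so that the
#'   selection is deterministic.
#' @return an object of class `plsda_model`: `n_lv`, `x_weights`,
#'   `x_loadings`, `y_loadings`, `x_scores`, `coefficients`, `intercept`,
#'   `threshold`, `class_coding`, plus the centering vectors.
#' @export
fit_plsda <- function(x, labels, n_lv = "auto", positive_class = "damaged",
                      threshold = 0.5, max_lv = 15L, inner_folds = 5L,
                      inner_metric = c("balanced_accuracy", "accuracy"),
                      cv_seed = 1L) {
  inner_metric <- match.arg(inner_metric)
  X <- spectra_matrix(x)
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L)
    stop("PLS-DA requires exactly two classes, got: ",
         paste(cls, collapse = ", "))
  if (!positive_class %in% cls)
    stop("positive_class ", sQuote(positive_class), " absent from labels")
  neg <- setdiff(cls, positive_class)
  y <- as.numeric(labels == positive_class)
  midpoint <- identical(threshold, "midpoint")
  if (!midpoint && !is.numeric(threshold))
    stop("threshold must be numeric or \"midpoint\"")
  auto <- identical(n_lv, "auto")
  kmax <- if (auto) min(max_lv, nrow(X) - 1L, ncol(X)) else as.integer(n_lv)
  core_full <- pls1_path(X, y, kmax)
  if (!auto && core_full$k < kmax)
    stop("n_lv = ", kmax, " exceeds the rank of the centered data (",
         core_full$k, ")")
  k_use <- core_full$k
  if (auto && k_use > 1L) {
    acc <- pls_inner_cv(X, y, labels, kmax = k_use, folds = inner_folds,
                        threshold = threshold, metric = inner_metric,
                        seed = cv_seed)
    k_use <- which.max(acc)  # which.max takes the first (fewest LVs) on ties
  }
  B <- core_full$B[, k_use]
  intercept <- core_full$ym - sum(core_full$xm * B)
  if (midpoint) {
    resp <- drop(X %*% B) + intercept
    threshold <- (mean(resp[y == 1]) + mean(resp[y == 0])) / 2
  }
  structure(list(n_lv = k_use,
                 x_weights = core_full$W[, seq_len(k_use), drop = FALSE],
                 x_loadings = core_full$P[, seq_len(k_use), drop = FALSE],
                 y_loadings = core_full$q[seq_len(k_use)],
                 x_scores = core_full$Tm[, seq_len(k_use), drop = FALSE],
                 coefficients = B,
                 intercept = intercept,
                 threshold = threshold,
                 class_coding = stats::setNames(c(1, 0), c(positive_class, neg)),
                 positive_class = positive_class,
                 negative_class = neg,
                 x_mean = core_full$xm,
                 y_mean = core_full$ym,
                 inner_cv_accuracy = if (auto && exists("acc", inherits = FALSE))
                   acc else NULL),
            class = "plsda_model")
}

# NIPALS PLS1 with X (and y) deflation; returns weight/loading matrices and
# the coefficient path B[, k] for every number of LVs up to the achieved rank.
pls1_path <- function(X, y, kmax) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  scale0 <- sum(Xc^2)
  tol <- max(scale0, .Machine$double.eps) * 1e-12
  W <- P <- matrix(0, p, kmax)
  Tm <- matrix(0, n, kmax)
  qv <- numeric(kmax)
  k <- 0L
  for (a in seq_len(kmax)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 < tol * 1e-6) break
    w <- w / nw
    tt <- drop(Xc %*% w)
    t2 <- sum(tt^2)
    if (t2 < tol) break
    pvec <- drop(crossprod(Xc, tt)) / t2
    qk <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, pvec)
    yc <- yc - qk * tt
    k <- a
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- tt
    qv[a] <- qk
  }
  if (k == 0L) stop("centered data have no variance; PLS is undefined")
  # coefficient path: B_k = W_k (P_k' W_k)^{-1} q_k
  B <- matrix(0, p, k)
  PtW <- crossprod(P[, seq_len(k), drop = FALSE], W[, seq_len(k), drop = FALSE])
  for (a in seq_len(k)) {
    sol <- solve(PtW[seq_len(a), seq_len(a), drop = FALSE], qv[seq_len(a)])
    B[, a] <- W[, seq_len(a), drop = FALSE] %*% sol
  }
  list(W = W[, seq_len(k), drop = FALSE],
       P = P[, seq_len(k), drop = FALSE],
       Tm = Tm[, seq_len(k), drop = FALSE],
       q = qv[seq_len(k)], B = B, xm = xm, ym = ym, k = k)
}

# Stratified inner k-fold CV criterion for each number of LVs 1..kmax.
pls_inner_cv <- function(X, y, labels, kmax, folds, threshold, metric,
                         seed) {
  midpoint <- identical(threshold, "midpoint")
  n <- nrow(X)
  fold_of <- integer(n)
  with_preserved_rng(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  tp <- tn <- matrix(0, folds, kmax)
  npos <- nneg <- numeric(folds)
  counted <- logical(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    te <- !tr
    if (!any(te) || length(unique(labels[tr])) < 2L) next
    core <- pls1_path(X[tr, , drop = FALSE], y[tr], kmax)
    ks <- seq_len(core$k)
    Yhat <- sweep(X[te, , drop = FALSE], 2L, core$xm) %*%
      core$B[, ks, drop = FALSE] + core$ym
    thr <- if (midpoint) {
      Ytr <- sweep(X[tr, , drop = FALSE], 2L, core$xm) %*%
        core$B[, ks, drop = FALSE] + core$ym
      (colMeans(Ytr[y[tr] == 1, , drop = FALSE]) +
         colMeans(Ytr[y[tr] == 0, , drop = FALSE])) / 2
    } else rep(threshold, length(ks))
    pred_pos <- Yhat >= matrix(thr, nrow(Yhat), length(ks), byrow = TRUE)
    truth_pos <- y[te] == 1
    pad <- function(v) {         # carry the last achieved-LV value forward
      out <- numeric(kmax)
      out[ks] <- v
      if (core$k < kmax) out[(core$k + 1L):kmax] <- v[core$k]
      out
    }
    tp[f, ] <- pad(colSums(pred_pos & truth_pos))
    tn[f, ] <- pad(colSums(!pred_pos & !truth_pos))
    npos[f] <- sum(truth_pos)
    nneg[f] <- sum(!truth_pos)
    counted[f] <- TRUE
  }
  if (!any(counted))
    stop("inner cross-validation failed: no fold had both classes in training")
  if (metric == "accuracy")
    return((colSums(tp[counted, , drop = FALSE]) +
              colSums(tn[counted, , drop = FALSE])) /
             (sum(npos[counted]) + sum(nneg[counted])))
  sens <- colSums(tp[counted, , drop = FALSE]) / sum(npos[counted])
  spec <- colSums(tn[counted, , drop = FALSE]) / sum(nneg[counted])
  (sens + spec) / 2
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", x$n_lv, " latent variable(s), ",
      length(x$coefficients), " channels; positive = ", x$positive_class,
      " (coded 1), threshold = ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict with a fitted PLS-DA model
#'
#' The continuous response is \eqn{\hat y = b_0 + x^T B}; a spectrum is
#' assigned the positive class iff \eqn{\hat y \ge} threshold (ties classify
#' as positive).
#'
#' @param object a `plsda_model`.
#' @param newdata [spectrum_set] or matrix on the training grid.
#' @param ... unused.
#' @return a list: `labels` and `response` (continuous, for ROC analysis).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  X <- spectra_matrix(newdata)
  if (ncol(X) != length(object$coefficients))
    stop("newdata has ", ncol(X), " channels; model expects ",
         length(object$coefficients))
  yhat <- unname(drop(X %*% object$coefficients)) + object$intercept
  list(labels = ifelse(yhat >= object$threshold, object$positive_class,
                       object$negative_class),
       response = yhat)
}
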