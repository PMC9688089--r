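#' Construct a set of spectra on a shared wavenumber grid
#'
#' A `spectrum_set` is the pipeline's universal currency: an
#' `n_spectra x n_channels` intensity matrix whose columns live on one
#' strictly increasing wavenumber grid (cm^-1), plus a per-row metadata
#' table.  Metadata columns beyond the known schema
#' (`spectrum_id`, `cell_id`, `subject_id`, `label`, `x_um`, `y_um`)
#' are carried through untouched.
#'
#' @param wavenumber numeric vector of Raman shifts (cm^-1), strictly
#'   increasing and finite.
#' @param intensities numeric matrix (`n_spectra x n_channels`) or a single
#'   numeric vector (interpreted as one spectrum).  All values must be finite.
#' @param meta optional `data.frame` with one row per spectrum.  A
#'   `spectrum_id` column is generated when absent; `label`, when present,
#'   must be one of `"intact"`, `"damaged"`, `"unknown"`.
#' @param allow_na if `TRUE`, non-finite intensities are tolerated (e.g. to
#'   carry corrupt instrument rows into [batch_emsc()], which reports them as
#'   per-row failures).  Default `FALSE`: intensities must be finite.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumber, intensities, meta = NULL,
                         allow_na = FALSE) {
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) < 1L || anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop("wavenumber grid must be finite and non-empty")
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("wavenumber grid must be strictly increasing")
  if (is.null(dim(intensities)))
    intensities <- matrix(as.numeric(intensities), nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(wavenumber))
    stop("intensity matrix has ", ncol(intensities),
         " channels but grid has ", length(wavenumber))
  if (!allow_na && nrow(intensities) > 0L && any(!is.finite(intensities)))
    stop("intensities must be finite")
  n <- nrow(intensities)
  if (is.null(meta)) {
    meta <- data.frame(spectrum_id = if (n > 0L) paste0("S", seq_len(n)) else character(0),
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n)
    stop("metadata has ", nrow(meta), " rows but there are ", n, " spectra")
  if (is.null(meta$spectrum_id))
    meta$spectrum_id <- if (n > 0L) paste0("S", seq_len(n)) else character(0)
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id))
    stop("spectrum_id values must be unique")
  if (!is.null(meta$label)) {
    meta$label <- as.character(meta$label)
    bad <- setdiff(unique(meta$label), c("intact", "damaged", "unknown"))
    if (length(bad))
      stop("label values must be intact/damaged/unknown; found: ",
           paste(bad, collapse = ", "))
  }
  if (!is.null(meta$cell_id) && n > 0L) {
    cid <- meta$cell_id[!is.na(meta$cell_id)]
    if (anyDuplicated(cid))
      stop("cell_id must be unique per row when present")
  }
  rownames(intensities) <- meta$spectrum_id
  structure(list(wavenumber = wavenumber,
                 intensities = intensities,
                 meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$intensities), " spectra x ",
      length(x$wavenumber), " channels (",
      format(min(x$wavenumber)), "-", format(max(x$wavenumber)),
      " cm-1)\n", sep = "")
  if (!is.null(x$meta$label)) {
    tab <- table(x$meta$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra / channels in a spectrum_set
#' @param set a `spectrum_set`.
#' @return integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @rdname n_spectra
#' @export
n_channels <- function(set) length(set$wavenumber)

#' Crop a spectrum set to a closed wavenumber interval
#'
#' Keeps exactly the channels with `lo <= wavenumber <= hi` (both endpoints
#' included).  Metadata is unchanged; the operation is idempotent.
#'
#' @param set a `spectrum_set`.
#' @param lo,hi interval bounds in cm^-1, `lo < hi`.
#' @return the cropped `spectrum_set`.
#' @export
crop <- function(set, lo, hi) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!(lo < hi)) stop("crop requires lo < hi")
  keep <- set$wavenumber >= lo & set$wavenumber <= hi
  if (!any(keep))
    stop("crop(", lo, ", ", hi, ") leaves no channels")
  spectrum_set(set$wavenumber[keep],
               set$intensities[, keep, drop = FALSE],
               set$meta)
}

#' Resample a spectrum set onto a target wavenumber grid
#'
#' Linear interpolation per spectrum.  Extrapolation is refused: every target
#' point must lie within the source grid's range.
#'
#' @param set a `spectrum_set`.
#' @param target numeric vector of target wavenumbers (strictly increasing).
#' @return a `spectrum_set` on the target grid.
#' @export
resample_to_grid <- function(set, target) {
  stopifnot(inherits(set, "spectrum_set"))
  target <- as.numeric(target)
  if (is.unsorted(target, strictly = TRUE))
    stop("target grid must be strictly increasing")
  rng <- range(set$wavenumber)
  if (any(target < rng[1] | target > rng[2]))
    stop("target grid extends outside the source range [",
         rng[1], ", ", rng[2], "]; extrapolation is not performed")
  out <- matrix(0, nrow(set$intensities), length(target))
  for (i in seq_len(nrow(out)))
    out[i, ] <- stats::approx(set$wavenumber, set$intensities[i, ],
                              xout = target, method = "linear")$y
  spectrum_set(target, out, set$meta)
}

#' Row-subset a spectrum set
#' @param set a `spectrum_set`.
#' @param i integer or logical row index.
#' @return a `spectrum_set` with the selected spectra.
#' @export
subset_spectra <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"))
  spectrum_set(set$wavenumber,
               set$intensities[i, , drop = FALSE],
               set$meta[i, , drop = FALSE])
}
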