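#' Assemble gridded point spectra into a hyperspectral Raman map
#'
#' Spectra carrying `x_um`/`y_um` coordinates are snapped (tolerance 1e-6
#' micrometres) onto the regular lattice inferred from the unique sorted
#' coordinates, filling an `ny x nx x n_channels` cube.  Missing lattice
#' points are masked; duplicate or off-lattice coordinates are errors.
#' Image convention: row 1 = smallest y, column 1 = smallest x.
#'
#' @param set a [spectrum_set] whose metadata has numeric `x_um`, `y_um`.
#' @param tol coordinate snap tolerance in micrometres (default 1e-6).
#' @return an object of class `raman_map`: `nx`, `ny`, `step_um`
#'   (x and y spacing), `wavenumber`, `cube`, `mask` (TRUE = filled),
#'   `origin`.
#' @export
assemble_map <- function(set, tol = 1e-6) {
  stopifnot(inherits(set, "spectrum_set"))
  x <- set$meta$x_um
  y <- set$meta$y_um
  if (is.null(x) || is.null(y))
    stop("metadata must contain x_um and y_um coordinates")
  xs <- snap_axis(x, tol, "x")
  ys <- snap_axis(y, tol, "y")
  nx <- length(xs$values)
  ny <- length(ys$values)
  key <- (ys$index - 1L) * nx + xs$index
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate coordinate (", x[d], ", ", y[d], ")")
  }
  cube <- array(NA_real_, dim = c(ny, nx, n_channels(set)))
  mask <- matrix(FALSE, ny, nx)
  for (i in seq_len(n_spectra(set))) {
    cube[ys$index[i], xs$index[i], ] <- set$intensities[i, ]
    mask[ys$index[i], xs$index[i]] <- TRUE
  }
  structure(list(nx = nx, ny = ny,
                 step_um = c(x = xs$step, y = ys$step),
                 wavenumber = set$wavenumber,
                 cube = cube, mask = mask,
                 origin = c(x0_um = xs$values[1L], y0_um = ys$values[1L])),
            class = "raman_map")
}

snap_axis <- function(v, tol, name) {
  u <- sort(unique(v))
  u <- u[c(TRUE, diff(u) > tol)]            # merge values within tolerance
  idx <- vapply(v, function(z) which.min(abs(u - z)), integer(1))
  off <- abs(v - u[idx])
  if (any(off > tol))
    stop(name, " coordinates do not lie on a regular grid (off-lattice by ",
         format(max(off)), " um)")
  d <- diff(u)
  if (length(d) && (max(d) - min(d)) > tol)
    stop(name, " coordinates are irregularly spaced (steps ",
         format(min(d)), " to ", format(max(d)), " um)")
  list(values = u, index = idx,
       step = if (length(d)) mean(d) else NA_real_)
}

#' @export
print.raman_map <- function(x, ...) {
  cat("<raman_map> ", x$ny, " x ", x$nx, " pixels (",
      sum(x$mask), " filled, ", sum(!x$mask), " masked), ",
      length(x$wavenumber), " channels\n", sep = "")
  invisible(x)
}

#' Flatten a Raman map back into a spectrum set
#'
#' Inverse of [assemble_map()] on the filled pixels.
#'
#' @param map a `raman_map`.
#' @return a [spectrum_set] with `x_um`/`y_um` metadata.
#' @export
flatten_map <- function(map) {
  stopifnot(inherits(map, "raman_map"))
  filled <- which(map$mask, arr.ind = TRUE)
  n <- nrow(filled)
  X <- matrix(0, n, length(map$wavenumber))
  for (i in seq_len(n))
    X[i, ] <- map$cube[filled[i, 1L], filled[i, 2L], ]
  xs <- map$origin["x0_um"] + (seq_len(map$nx) - 1L) *
    (if (is.na(map$step_um["x"])) 0 else map$step_um["x"])
  ys <- map$origin["y0_um"] + (seq_len(map$ny) - 1L) *
    (if (is.na(map$step_um["y"])) 0 else map$step_um["y"])
  spectrum_set(map$wavenumber, X,
               data.frame(spectrum_id = paste0("px", seq_len(n)),
                          x_um = xs[filled[, 2L]],
                          y_um = ys[filled[, 1L]],
                          stringsAsFactors = FALSE))
}

#' Band-intensity image from a Raman map
#'
#' `height` is the maximum intensity within the band window
#' `[center - halfwidth, center + halfwidth]`; `area` is the trapezoidal
#' integral over the window after subtracting the linear chord between the
#' window endpoints (which annihilates any linear background).
#'
#' @param map a `raman_map`.
#' @param center band center (cm^-1), e.g. 1089 for the DNA PO2- backbone.
#' @param halfwidth band half-width (cm^-1, default 8 - a typical biological
#'   Raman half-width at ~1 cm^-1 resolution).
#' @param mode `"height"` or `"area"`.
#' @return an `ny x nx` numeric matrix (`NA` at masked pixels) with
#'   attributes `center`, `halfwidth`, `mode`.
#' @export
band_image <- function(map, center, halfwidth = 8, mode = c("height", "area")) {
  stopifnot(inherits(map, "raman_map"))
  mode <- match.arg(mode)
  w <- map$wavenumber
  if (center - halfwidth < min(w) || center + halfwidth > max(w))
    stop("band window [", center - halfwidth, ", ", center + halfwidth,
         "] extends outside the map's grid")
  idx <- which(w >= center - halfwidth & w <= center + halfwidth)
  if (mode == "height" && length(idx) < 1L)
    stop("band window contains no grid channel")
  if (mode == "area" && length(idx) < 2L)
    stop("area mode needs at least 2 channels in the window")
  img <- matrix(NA_real_, map$ny, map$nx)
  wi <- w[idx]
  for (r in seq_len(map$ny)) for (cc in seq_len(map$nx)) {
    if (!map$mask[r, cc]) next
    yv <- map$cube[r, cc, idx]
    img[r, cc] <- if (mode == "height") max(yv) else {
      chord <- yv[1L] + (yv[length(yv)] - yv[1L]) *
        (wi - wi[1L]) / (wi[length(wi)] - wi[1L])
      trapz(wi, yv - chord)
    }
  }
  attr(img, "center") <- center
  attr(img, "halfwidth") <- halfwidth
  attr(img, "mode") <- mode
  img
}

#' Write a band image as a CSV matrix
#' @param img a [band_image()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_band_image <- function(img, path) {
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
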