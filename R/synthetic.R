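#' Default sperm Raman band table
#'
#' Gaussian peak parameters of the synthetic sperm biochemical profile.
#' Centers follow the band assignments commonly reported for human sperm
#' heads (DNA backbone and base vibrations, phenylalanine, CH deformations,
#' amide I).  `class_effect` is the signed relative height change of a band
#' in DNA-damaged cells versus intact cells: negative at the bands that are
#' higher in the intact group (782, 920, 1001, 1089, 1460, 1580,
#' 1673 cm^-1), positive at the bands that increase with damage (1208,
#' 1258, 1319, 1367 cm^-1).  The magnitudes were calibrated once by
#' simulation so that the default cohort yields cross-validated performance
#' in the 70-85% sensitivity/specificity regime, and then frozen.
#'
#' @return a `data.frame` with columns `center`, `width` (Gaussian sigma,
#'   cm^-1), `base_height` (a.u.), `class_effect`, `assignment`.
#' @export
sperm_band_table <- function() {
  data.frame(
    center = c(782, 896, 920, 1001, 1089, 1208, 1258, 1319, 1367, 1460,
               1580, 1673),
    width = c(8, 9, 8, 5, 9, 9, 10, 9, 9, 10, 10, 12),
    base_height = c(1.00, 0.45, 0.50, 0.90, 0.85, 0.45, 0.60, 0.70, 0.50,
                    0.80, 0.65, 0.90),
    class_effect = c(-0.26, -0.10, -0.19, -0.16, -0.26, 0.22, 0.22, 0.26,
                     0.22, -0.19, -0.19, -0.16),
    assignment = c(
      "T/U/C ring breathing + DNA backbone",
      "deoxyribose",
      "C-C stretch, ribose-phosphate",
      "phenylalanine ring breathing",
      "PO2- symmetric stretch, DNA backbone",
      "C-C6H5, tryptophan/phenylalanine",
      "adenine, cytosine",
      "guanine",
      "CH deformation, nucleic acids",
      "CH2/CH3 deformation (thymine)",
      "ring stretch, A/G",
      "amide I"),
    stringsAsFactors = FALSE)
}

gaussian_peaks <- function(wavenumber, centers, widths, heights) {
  out <- numeric(length(wavenumber))
  for (i in seq_along(centers))
    out <- out + heights[i] * exp(-(wavenumber - centers[i])^2 /
                                    (2 * widths[i]^2))
  out
}

#' Default wavenumber grid (600-1800 cm^-1 at 1 cm^-1)
#' @return numeric vector.
#' @export
default_grid <- function() seq(600, 1800, by = 1)

#' Synthetic reference library: sperm profile, glass, agarose
#'
#' The sperm reference is the sum of the [sperm_band_table()] Gaussians;
#' glass is a single broad Gaussian centered at 1100 cm^-1 (sigma
#' 120 cm^-1), emulating the prominent background that glass slides
#' contribute between ~1050 and 1150 cm^-1; agarose is a small set of
#' broad bands distinct from the sperm peaks.  All three are
#' vector-normalized.  The library is deterministic; `seed` is accepted for
#' interface symmetry with the other generators.
#'
#' @param wavenumber wavenumber grid (default [default_grid()]).
#' @param seed unused (the library is deterministic).
#' @return a list: `wavenumber`, `sperm_reference`, `glass`, `agarose`
#'   (numeric vectors of unit Euclidean norm).
#' @export
reference_library <- function(wavenumber = default_grid(), seed = 1L) {
  bands <- sperm_band_table()
  sperm <- gaussian_peaks(wavenumber, bands$center, bands$width,
                          bands$base_height)
  glass <- gaussian_peaks(wavenumber, 1100, 120, 1)
  agarose <- gaussian_peaks(wavenumber,
                            c(845, 930, 1078, 1370, 1465),
                            c(22, 18, 28, 30, 25),
                            c(0.8, 0.6, 0.5, 0.4, 0.3))
  list(wavenumber = wavenumber,
       sperm_reference = vector_normalize(sperm),
       glass = vector_normalize(glass),
       agarose = vector_normalize(agarose))
}

#' Configuration of a synthetic sperm-on-glass cohort
#'
#' Defaults emulate a realistic clinical cohort: 361 DNA-intact and 65 DNA-damaged
#' cells from 10 subjects on a 600-1800 cm^-1 grid at 1 cm^-1 spacing.
#'
#' @param n_intact,n_damaged class counts (defaults 361 / 65).
#' @param n_subjects number of subjects cells are drawn from (default 10).
#' @param subject_sd sd of the log-normal subject-by-band height multiplier.
#' @param effect_scale multiplier on all band `class_effect`s (1 = the
#'   calibrated defaults; 0 = null cohort).
#' @param severity_sd sd of the continuous per-cell DNA-damage severity
#'   around its class mean (0 for intact, 1 for damaged cells).  The halo
#'   assay thresholds a continuous fragmentation index, so cells near the
#'   decision boundary carry intermediate spectral damage.
#' @param discordant_frac fraction of cells whose spectral severity is drawn
#'   from the opposite class's distribution, emulating label-versus-spectrum
#'   discordance of the halo assay (staining noise, subjective halo scoring,
#'   chemically atypical damage).  Either a single value or
#'   `c(intact = , damaged = )`; the intact-side fraction must stay well
#'   below the class-imbalance ratio or flipped intact cells outnumber the
#'   damaged class in spectral space.  This, not the channel noise, is what
#'   bounds the attainable classification accuracy, as it does in real
#'   stained cohorts.
#' @param glass_weight_range,agarose_weight_range per-cell uniform ranges of
#'   the interferent weights.
#' @param baseline_coeff_ranges list of `c(lo, hi)` ranges, one per Legendre
#'   degree 0..k, for the smooth additive baseline.
#' @param b_range per-cell uniform range of the overall sperm-signal scale.
#' @param noise_sd sd of the additive Gaussian channel noise (a.u.).
#' @param noise_model `"gaussian"` (default) or `"poisson"`-like
#'   (intensity-scaled shot noise).
#' @param wavenumber wavenumber grid.
#' @param seed integer seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_intact = 361L, n_damaged = 65L, n_subjects = 10L,
                          subject_sd = 0.08, effect_scale = 1,
                          severity_sd = 0.15,
                          discordant_frac = c(intact = 0.12, damaged = 0.13),
                          glass_weight_range = c(0.5, 2),
                          agarose_weight_range = c(0.1, 0.5),
                          baseline_coeff_ranges = list(c(0.5, 2.0),
                                                       c(-0.4, 0.1),
                                                       c(-0.1, 0.25),
                                                       c(-0.1, 0.1)),
                          b_range = c(0.8, 1.2),
                          noise_sd = 0.004,
                          noise_model = c("gaussian", "poisson"),
                          wavenumber = default_grid(), seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_intact >= 0, n_damaged >= 0, n_subjects >= 1,
            subject_sd >= 0, severity_sd >= 0,
            all(discordant_frac >= 0), all(discordant_frac < 1),
            length(discordant_frac) %in% 1:2, noise_sd >= 0,
            diff(glass_weight_range) >= 0, diff(agarose_weight_range) >= 0,
            diff(b_range) >= 0)
  for (r in baseline_coeff_ranges) stopifnot(length(r) == 2L, r[1] <= r[2])
  structure(list(n_intact = as.integer(n_intact),
                 n_damaged = as.integer(n_damaged),
                 n_subjects = as.integer(n_subjects),
                 subject_sd = subject_sd, effect_scale = effect_scale,
                 severity_sd = severity_sd,
                 discordant_frac = discordant_frac,
                 glass_weight_range = glass_weight_range,
                 agarose_weight_range = agarose_weight_range,
                 baseline_coeff_ranges = baseline_coeff_ranges,
                 b_range = b_range, noise_sd = noise_sd,
                 noise_model = noise_model,
                 wavenumber = wavenumber, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic sperm-on-glass Raman cohort
#'
#' Each cell's spectrum is
#' `b * profile(subject, cell) + c_g * glass + c_a * agarose + baseline + noise`.
#' The profile scales every band height by
#' `(1 + class_effect * effect_scale * severity)`, where the cell's
#' continuous damage severity is drawn around 1 for damaged and around 0 for
#' intact cells (`sd = severity_sd`), and by a log-normal subject-by-band
#' multiplier (`sd = subject_sd`); the profile is then vector-normalized so
#' that `b` is the interpretable overall signal scale.
#' The baseline is a random Legendre polynomial (degree = number of
#' coefficient ranges - 1).  The truth table records every coefficient.
#'
#' @param config a [cohort_config()].
#' @return a list: `set` (a [spectrum_set] with `spectrum_id`, `cell_id`,
#'   `subject_id`, `label` metadata), `truth` (a list with `table` - one row
#'   per cell with all generating coefficients -, `profiles` (noise-free
#'   normalized cell profiles), `class_mean_profiles`, and the reference
#'   `library`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_intact + config$n_damaged
  if (config$n_subjects > n && n > 0L)
    stop("more subjects (", config$n_subjects, ") than cells (", n, ")")
  lib <- reference_library(config$wavenumber)
  bands <- sperm_band_table()
  nb <- nrow(bands)
  w <- config$wavenumber
  deg <- length(config$baseline_coeff_ranges) - 1L
  B <- legendre_basis(rescale_unit(w), deg)
  out <- with_preserved_rng(config$seed, {
    labels <- c(rep("intact", config$n_intact),
                rep("damaged", config$n_damaged))
    subject <- if (n > 0L)
      sample(rep_len(seq_len(config$n_subjects), n)) else integer(0)
    M <- matrix(exp(stats::rnorm(config$n_subjects * nb, 0,
                                 config$subject_sd)),
                config$n_subjects, nb)
    b <- stats::runif(n, config$b_range[1], config$b_range[2])
    cg <- stats::runif(n, config$glass_weight_range[1],
                       config$glass_weight_range[2])
    ca <- stats::runif(n, config$agarose_weight_range[1],
                       config$agarose_weight_range[2])
    P <- matrix(0, n, deg + 1L)
    for (j in seq_len(deg + 1L)) {
      r <- config$baseline_coeff_ranges[[j]]
      P[, j] <- stats::runif(n, r[1], r[2])
    }
    f <- rep_len(config$discordant_frac, 2L)  # (intact, damaged)
    spectral_class <- labels == "damaged"
    discordant <- stats::runif(n) < ifelse(spectral_class, f[2L], f[1L])
    spectral_class[discordant] <- !spectral_class[discordant]
    severity <- spectral_class + stats::rnorm(n, 0, config$severity_sd)
    X <- matrix(0, n, length(w))
    profiles <- matrix(0, n, length(w))
    for (i in seq_len(n)) {
      h <- bands$base_height * M[subject[i], ] *
        (1 + bands$class_effect * config$effect_scale * severity[i])
      prof <- vector_normalize(gaussian_peaks(w, bands$center, bands$width, h))
      profiles[i, ] <- prof
      clean <- b[i] * prof + cg[i] * lib$glass + ca[i] * lib$agarose +
        drop(B %*% P[i, ])
      noise <- if (config$noise_sd == 0) 0
        else if (config$noise_model == "gaussian")
          stats::rnorm(length(w), 0, config$noise_sd)
        else
          stats::rnorm(length(w), 0, config$noise_sd *
                         sqrt(pmax(clean, 0) / max(mean(clean), 1e-12)))
      X[i, ] <- clean + noise
    }
    list(labels = labels, subject = subject, b = b, cg = cg, ca = ca,
         P = P, X = X, profiles = profiles, severity = severity,
         discordant = discordant)
  })
  meta <- data.frame(spectrum_id = if (n > 0L) sprintf("sp%03d", seq_len(n))
                                   else character(0),
                     cell_id = if (n > 0L) sprintf("cell%03d", seq_len(n))
                               else character(0),
                     subject_id = if (n > 0L) sprintf("subj%02d", out$subject)
                                  else character(0),
                     label = out$labels,
                     stringsAsFactors = FALSE)
  truth_table <- data.frame(meta,
                            severity = out$severity,
                            discordant = out$discordant,
                            b = out$b, c_glass = out$cg, c_agarose = out$ca,
                            stringsAsFactors = FALSE)
  if (n > 0L) {
    Pmat <- as.data.frame(out$P)
    names(Pmat) <- paste0("p_", 0:deg)
    truth_table <- cbind(truth_table, Pmat)
  }
  cmp <- list(
    intact = if (config$n_intact > 0L)
      colMeans(out$profiles[out$labels == "intact", , drop = FALSE]) else NULL,
    damaged = if (config$n_damaged > 0L)
      colMeans(out$profiles[out$labels == "damaged", , drop = FALSE]) else NULL)
  list(set = spectrum_set(w, out$X, meta),
       truth = list(table = truth_table,
                    profiles = out$profiles,
                    class_mean_profiles = cmp,
                    library = lib,
                    bands = bands,
                    config = config))
}

#' Generate a synthetic Raman mapping phantom of a sperm head
#'
#' Pixels inside an elliptical "head" mask contain the sperm reference plus
#' glass background and noise; pixels outside contain glass and noise only.
#'
#' @param nx,ny raster dimensions in points (defaults 38 x 43, i.e. 1634
#'   pixels).
#' @param step_um raster step (default 1).
#' @param mask ellipse parameters, a list with `cx`, `cy` (center, um),
#'   `rx`, `ry` (radii, um); `NULL` centers an ellipse covering ~half the
#'   field.  The ellipse must fit inside the field.
#' @param glass_weight,sperm_weight intensity scales of the two components.
#' @param noise_sd additive Gaussian noise sd.
#' @param wavenumber wavenumber grid.
#' @param seed integer seed.
#' @return a list: `set` (a [spectrum_set] with `x_um`/`y_um` metadata) and
#'   `mask` (an `ny x nx` logical matrix, `TRUE` inside the head).
#' @export
generate_map_phantom <- function(nx = 38L, ny = 43L, step_um = 1,
                                 mask = NULL, glass_weight = 0.8,
                                 sperm_weight = 1, noise_sd = 0.003,
                                 wavenumber = default_grid(), seed = 1L) {
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  xs <- (seq_len(nx) - 1L) * step_um
  ys <- (seq_len(ny) - 1L) * step_um
  if (is.null(mask))
    mask <- list(cx = mean(range(xs)), cy = mean(range(ys)),
                 rx = diff(range(xs)) * 0.3, ry = diff(range(ys)) * 0.3)
  if (mask$rx <= 0 || mask$ry <= 0 ||
      mask$cx - mask$rx < min(xs) - step_um / 2 ||
      mask$cx + mask$rx > max(xs) + step_um / 2 ||
      mask$cy - mask$ry < min(ys) - step_um / 2 ||
      mask$cy + mask$ry > max(ys) + step_um / 2)
    stop("ellipse mask does not fit inside the mapped field")
  lib <- reference_library(wavenumber)
  grid_xy <- expand.grid(x_um = xs, y_um = ys)
  inside <- ((grid_xy$x_um - mask$cx) / mask$rx)^2 +
    ((grid_xy$y_um - mask$cy) / mask$ry)^2 <= 1
  n <- nrow(grid_xy)
  X <- with_preserved_rng(seed, {
    base <- outer(rep(glass_weight, n), lib$glass)
    base[inside, ] <- base[inside, , drop = FALSE] +
      outer(rep(sperm_weight, sum(inside)), lib$sperm_reference)
    base + matrix(stats::rnorm(n * length(wavenumber), 0, noise_sd),
                  n, length(wavenumber))
  })
  meta <- data.frame(spectrum_id = sprintf("px%04d", seq_len(n)),
                     x_um = grid_xy$x_um, y_um = grid_xy$y_um,
                     stringsAsFactors = FALSE)
  truth <- matrix(inside, ny, nx, byrow = TRUE)
  list(set = spectrum_set(wavenumber, X, meta), mask = truth)
}
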