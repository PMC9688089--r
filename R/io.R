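#' Read point spectra from a delimited text table
#'
#' Two dialects are supported.  `wide`: first column is the wavenumber axis
#' (header `wavenumber_cm-1` by convention), every remaining column one
#' spectrum named by its `spectrum_id`.  `long`: columns
#' `spectrum_id`, `wavenumber_cm-1` (or `wavenumber`), `intensity`.
#' The delimiter is auto-detected among comma, tab and semicolon; the decimal
#' separator is the point.  The wavenumber axis is normalized to ascending
#' order on read regardless of file order.
#'
#' @param path path to the spectra table.
#' @param dialect `"wide"` or `"long"`.
#' @param metadata optional path to a sidecar metadata CSV keyed by
#'   `spectrum_id` (columns `cell_id`, `subject_id`, `label`, `x_um`, `y_um`;
#'   extra columns are carried through).
#' @return a [spectrum_set].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delimiter(path)
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE,
                      comment.char = "", quote = "\""),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  set <- if (dialect == "wide") parse_wide(raw, path) else parse_long(raw, path)
  if (!is.null(metadata)) {
    md <- read_spectra_metadata(metadata)
    set <- attach_metadata(set, md)
  }
  set
}

#' Read a spectra metadata table
#'
#' @param path CSV/TSV with a `spectrum_id` column.
#' @return a `data.frame`.
#' @export
read_spectra_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  sep <- detect_delimiter(path)
  md <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (is.null(md$spectrum_id))
    stop("metadata table ", path, " lacks a spectrum_id column")
  md$spectrum_id <- as.character(md$spectrum_id)
  md
}

attach_metadata <- function(set, md) {
  i <- match(set$meta$spectrum_id, md$spectrum_id)
  if (anyNA(i))
    stop("metadata is missing spectrum_id: ",
         paste(set$meta$spectrum_id[is.na(i)], collapse = ", "))
  extra <- md[i, setdiff(names(md), "spectrum_id"), drop = FALSE]
  meta <- cbind(set$meta, extra)
  rownames(meta) <- NULL
  spectrum_set(set$wavenumber, set$intensities, meta)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

# Convert a character column to numeric, reporting the offending cell.
numeric_column <- function(x, col_name, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "" &
                 toupper(trimws(x)) != "NA")
  if (length(bad))
    stop("non-numeric value ", sQuote(x[bad[1]]), " in column ",
         sQuote(col_name), ", data row ", bad[1], " of ", path)
  if (anyNA(v))
    stop("missing value in column ", sQuote(col_name), " of ", path)
  v
}

parse_wide <- function(raw, path) {
  if (ncol(raw) < 1L) stop("empty table in ", path)
  w <- numeric_column(raw[[1L]], names(raw)[1L], path)
  if (anyDuplicated(w))
    stop("duplicate wavenumber ", w[which(duplicated(w))[1L]], " in ", path)
  ids <- names(raw)[-1L]
  n <- length(ids)
  X <- matrix(0, n, length(w))
  for (j in seq_len(n))
    X[j, ] <- numeric_column(raw[[j + 1L]], ids[j], path)
  o <- order(w)
  spectrum_set(w[o], X[, o, drop = FALSE],
               data.frame(spectrum_id = ids, stringsAsFactors = FALSE))
}

parse_long <- function(raw, path) {
  need <- c("spectrum_id", "intensity")
  wn_col <- intersect(c("wavenumber_cm-1", "wavenumber"), names(raw))[1]
  if (is.na(wn_col) || !all(need %in% names(raw)))
    stop("long dialect requires columns spectrum_id, wavenumber_cm-1 (or ",
         "wavenumber), intensity; ", path, " has: ",
         paste(names(raw), collapse = ", "))
  id <- as.character(raw$spectrum_id)
  w <- numeric_column(raw[[wn_col]], wn_col, path)
  y <- numeric_column(raw$intensity, "intensity", path)
  ids <- unique(id)
  grids <- split(w, factor(id, levels = ids))
  vals <- split(y, factor(id, levels = ids))
  sorted <- lapply(grids, sort)
  ref <- sorted[[1L]]
  if (anyDuplicated(ref))
    stop("duplicate wavenumber ", ref[which(duplicated(ref))[1L]],
         " for spectrum ", ids[1L], " in ", path)
  for (k in seq_along(ids)) {
    if (length(sorted[[k]]) != length(ref) || any(sorted[[k]] != ref))
      stop("spectra in ", path, " are not on a common wavenumber grid ",
           "(first mismatch: ", ids[k], "); read them separately and use ",
           "resample_to_grid()")
  }
  X <- matrix(0, length(ids), length(ref))
  for (k in seq_along(ids)) {
    o <- order(grids[[k]])
    X[k, ] <- vals[[k]][o]
  }
  spectrum_set(ref, X, data.frame(spectrum_id = ids, stringsAsFactors = FALSE))
}

#' Write a spectrum set as a delimited text table
#'
#' Values are printed with 15 significant digits so that a write/read round
#' trip reproduces intensities to better than 1e-9 relative.
#'
#' @param set a [spectrum_set].
#' @param path output file path.
#' @param dialect `"wide"` or `"long"`.
#' @param sep field delimiter (default comma).
#' @param metadata_path optional path for a sidecar metadata CSV; when given,
#'   the full metadata table is written there keyed by `spectrum_id`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path, dialect = c("wide", "long"), sep = ",",
                          metadata_path = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  dialect <- match.arg(dialect)
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open ", path, " for writing: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (dialect == "wide") {
    writeLines(paste(c("wavenumber_cm-1", set$meta$spectrum_id), collapse = sep), con)
    body <- matrix(fmt(set$wavenumber), ncol = 1L)
    if (n_spectra(set) > 0L)
      body <- cbind(body, matrix(fmt(t(set$intensities)),
                                 nrow = n_channels(set)))
    writeLines(apply(body, 1L, paste, collapse = sep), con)
  } else {
    writeLines(paste(c("spectrum_id", "wavenumber_cm-1", "intensity"),
                     collapse = sep), con)
    for (i in seq_len(n_spectra(set))) {
      writeLines(paste(set$meta$spectrum_id[i], fmt(set$wavenumber),
                       fmt(set$intensities[i, ]), sep = sep), con)
    }
  }
  if (!is.null(metadata_path))
    utils::write.csv(set$meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
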