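#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` couples a strictly increasing wavenumber grid (Raman
#' shift, cm^-1) with one intensity vector of the same length, representing a
#' single-cell (or reference) measurement.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing.
#' @param intensities Numeric vector of intensities, same length as
#'   `wavenumbers`, all finite.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers` and `intensities`.
#' @export
#' @examples
#' s <- raman_spectrum(seq(600, 1800, by = 2), rep(1, 601))
raman_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 channels", call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("grid error: wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must all be finite", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

valid_groups <- c("CR", "NR", "UNKNOWN")

#' Construct a set of aligned spectra with per-cell metadata
#'
#' A `spectra_set` is the universal currency between pipeline stages: a
#' samples x channels intensity matrix on one shared wavenumber grid, plus a
#' metadata data frame with one row per spectrum (`sample_id`, `patient_id`,
#' `group`). Groups are the two induction-therapy response classes, complete
#' remission (`CR`) and non-remission (`NR`), with `UNKNOWN` for unlabeled
#' rows.
#'
#' @param wavenumbers Shared wavenumber grid (strictly increasing, cm^-1).
#' @param matrix Numeric matrix, rows = cells/samples, columns = channels.
#' @param meta Data frame with columns `sample_id` (unique), `patient_id`,
#'   `group` (one of `"CR"`, `"NR"`, `"UNKNOWN"`); one row per matrix row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, matrix, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (any(diff(wavenumbers) <= 0)) {
    stop("grid error: wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (ncol(matrix) != length(wavenumbers)) {
    stop(sprintf("matrix has %d columns but grid has %d channels",
                 ncol(matrix), length(wavenumbers)), call. = FALSE)
  }
  required <- c("sample_id", "patient_id", "group")
  if (!all(required %in% names(meta))) {
    stop("meta must have columns sample_id, patient_id, group", call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$patient_id <- as.character(meta$patient_id)
  meta$group <- as.character(meta$group)
  if (nrow(meta) != nrow(matrix)) {
    stop(sprintf("matrix has %d rows but meta has %d", nrow(matrix), nrow(meta)),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("sample_id values must be unique within a spectra_set", call. = FALSE)
  }
  if (!all(meta$group %in% valid_groups)) {
    stop("group must be one of CR, NR, UNKNOWN", call. = FALSE)
  }
  rownames(matrix) <- meta$sample_id
  rownames(meta) <- NULL
  structure(list(wavenumbers = wavenumbers, matrix = matrix, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  grp <- table(factor(x$meta$group, levels = valid_groups))
  cat(sprintf(
    "<spectra_set> %d spectra x %d channels (%.1f-%.1f cm^-1); CR=%d NR=%d UNKNOWN=%d; %d patients\n",
    nrow(x$matrix), ncol(x$matrix), min(x$wavenumbers), max(x$wavenumbers),
    grp[["CR"]], grp[["NR"]], grp[["UNKNOWN"]],
    length(unique(x$meta$patient_id))))
  invisible(x)
}

#' Number of spectra in a spectra_set
#' @param x A `spectra_set`.
#' @return Integer count of rows.
#' @export
n_spectra <- function(x) nrow(x$matrix)

#' Extract one row of a spectra_set as a raman_spectrum
#' @param x A `spectra_set`.
#' @param i Row index or sample_id.
#' @return A `raman_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  raman_spectrum(x$wavenumbers, x$matrix[i, ])
}

#' Subset a spectra_set by row
#' @param x A `spectra_set`.
#' @param rows Integer or logical index over rows.
#' @return A `spectra_set` with the selected rows.
#' @export
subset_spectra <- function(x, rows) {
  spectra_set(x$wavenumbers, x$matrix[rows, , drop = FALSE],
              x$meta[rows, , drop = FALSE])
}

#' Interpolate a spectrum onto a target wavenumber grid
#'
#' Linear interpolation of intensities onto `grid`. The target grid must lie
#' within the span of the spectrum's own grid; extrapolation is refused
#' because Raman intensities outside the measured window are undefined.
#'
#' @param spectrum A `raman_spectrum`.
#' @param grid Target wavenumber vector (strictly increasing).
#' @return A `raman_spectrum` on `grid`.
#' @export
align_to_grid <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  grid <- as.numeric(grid)
  wn <- spectrum$wavenumbers
  if (min(grid) < min(wn) || max(grid) > max(wn)) {
    stop(sprintf(
      "extrapolation error: target grid [%.6g, %.6g] extends outside spectrum span [%.6g, %.6g]",
      min(grid), max(grid), min(wn), max(wn)), call. = FALSE)
  }
  y <- stats::approx(wn, spectrum$intensities, xout = grid, method = "linear")$y
  raman_spectrum(grid, y)
}
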