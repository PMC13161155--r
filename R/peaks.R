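# Characteristic-peak analysis: group mean +/- SD spectra, the CR - NR
# difference spectrum, windowed peak-intensity extraction, the
# normality-driven two-group test-selection rule, and per-peak ROC at the
# patient level (cells from one patient are not independent observations;
# patient means avoid pseudoreplication).

#' Channelwise mean and standard deviation spectrum of a group
#'
#' @param dataset A [spectra_set()].
#' @param group Group label to select (`"CR"` or `"NR"`), or `NULL` for all
#'   rows.
#' @return List with `mean` and `sd`, both [raman_spectrum()]s (`sd` is the
#'   sample standard deviation; 0 with a single row).
#' @export
mean_sd_spectrum <- function(dataset, group = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  rows <- if (is.null(group)) rep(TRUE, n_spectra(dataset)) else
    dataset$meta$group == group
  if (!any(rows)) {
    stop(sprintf("selection error: no spectra in group %s", group),
         call. = FALSE)
  }
  m <- dataset$matrix[rows, , drop = FALSE]
  mu <- colMeans(m)
  sdv <- if (nrow(m) > 1L) apply(m, 2L, stats::sd) else numeric(ncol(m))
  list(mean = raman_spectrum(dataset$wavenumbers, mu),
       sd = raman_spectrum(dataset$wavenumbers, sdv))
}

#' Signed difference of two mean spectra
#'
#' @param mean_a,mean_b [raman_spectrum()]s on the same grid.
#' @return A [raman_spectrum()] with intensities `mean_a - mean_b`.
#' @export
difference_spectrum <- function(mean_a, mean_b) {
  stopifnot(inherits(mean_a, "raman_spectrum"),
            inherits(mean_b, "raman_spectrum"))
  if (!isTRUE(all.equal(mean_a$wavenumbers, mean_b$wavenumbers))) {
    stop("alignment error: spectra are on different grids", call. = FALSE)
  }
  raman_spectrum(mean_a$wavenumbers, mean_a$intensities - mean_b$intensities)
}

#' Extract a characteristic-peak intensity
#'
#' The maximum intensity within `center +/- halfwidth` — a windowed maximum
#' is robust to small wavenumber calibration shifts.
#'
#' @param spectrum A [raman_spectrum()].
#' @param center Peak center in cm^-1.
#' @param halfwidth Window half-width in cm^-1 (default 5; 0 takes the
#'   nearest channel).
#' @return Scalar intensity.
#' @export
extract_peak_intensity <- function(spectrum, center, halfwidth = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  wn <- spectrum$wavenumbers
  keep <- wn >= center - halfwidth & wn <= center + halfwidth
  if (!any(keep)) {
    if (center >= min(wn) && center <= max(wn)) {
      keep <- seq_along(wn) == which.min(abs(wn - center))
    } else {
      stop(sprintf("range error: window around %g cm^-1 misses the grid",
                   center), call. = FALSE)
    }
  }
  max(spectrum$intensities[keep])
}

#' Two-group comparison with normality-driven test selection
#'
#' Shapiro-Wilk normality is checked on each group and variance homogeneity
#' with an F ratio, all at alpha = 0.05; when all three pass, a two-sided
#' unpaired Student's t test is used, otherwise a two-sided Mann-Whitney U
#' test with tie correction.
#'
#' @param values_a,values_b Numeric vectors, each with n >= 3.
#' @param alpha Significance level of the assumption checks.
#' @return List: `p_value`, `test_used` (`"t"` or `"mann_whitney"`), and the
#'   assumption p-values (`shapiro_a`, `shapiro_b`, `var_f`).
#' @export
group_compare <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("sample-size error: each group needs n >= 3", call. = FALSE)
  }
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # degenerate: clearly non-gaussian
    stats::shapiro.test(v)$p.value
  }
  sa <- shapiro_p(values_a)
  sb <- shapiro_p(values_b)
  vf <- if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) 0 else
    stats::var.test(values_a, values_b)$p.value
  if (sa > alpha && sb > alpha && vf > alpha) {
    p <- stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)$p.value)
    test <- "mann_whitney"
  }
  list(p_value = p, test_used = test, shapiro_a = sa, shapiro_b = sb,
       var_f = vf)
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001, `ns`
#' otherwise.
#'
#' @param p P-value.
#' @return Character annotation.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**" else
    if (p < 0.05) "*" else "ns"
}

#' Per-peak ROC with orientation
#'
#' Delegates to [roc_auc()] with the score direction chosen so the reported
#' AUC is >= 0.5; `direction` records whether higher intensities indicate
#' the positive (NR) class (`"higher"`) or were flipped (`"lower"`).
#'
#' @param peak_values Numeric peak intensities.
#' @param labels Group labels (positive class NR) or logical.
#' @param positive_class Passed to [roc_auc()].
#' @return A `roc_curve` with an extra `direction` element.
#' @export
per_peak_roc <- function(peak_values, labels, positive_class = "NR") {
  roc <- roc_auc(peak_values, labels, positive_class)
  direction <- "higher"
  if (roc$auc < 0.5) {
    roc <- roc_auc(-peak_values, labels, positive_class)
    direction <- "lower"
  }
  roc$direction <- direction
  roc
}

#' The default characteristic-peak list
#'
#' The canonical fingerprint-region bands for AML single cells with their
#' biomolecular assignments (glutathione, DNA/RNA ring-breathing modes,
#' phenylalanine, amide bands, lipid acyl-chain modes, ...).
#'
#' @return Data frame with columns `center` (cm^-1), `assignment`, `class`.
#' @export
default_peak_list <- function() {
  data.frame(
    center = c(662, 682, 747, 785, 943, 1003, 1095, 1175, 1235, 1298,
               1382, 1441, 1671),
    assignment = c(
      "Glutathione S-S stretch",
      "G ring breathing (DNA)",
      "T ring breathing (DNA/RNA)",
      "U/T/C ring breathing, O-P-O backbone",
      "Skeletal modes (polysaccharides)",
      "Phenylalanine ring breathing",
      "PO2- phosphodioxy / lipid",
      "Cytosine, guanine",
      "Amide III",
      "Palmitic acid / acyl chains",
      "CH3 band",
      "C-H deformation",
      "Amide I / cholesterol"),
    class = c("protein", "nucleic_acid", "nucleic_acid", "nucleic_acid",
              "carbohydrate", "protein", "nucleic_acid", "nucleic_acid",
              "protein", "lipid", "lipid", "protein_lipid", "protein_lipid"),
    stringsAsFactors = FALSE)
}

#' Build the per-peak statistics table
#'
#' For each configured peak: per-sample windowed intensities, group means
#' and SDs, the [group_compare()] p-value with its selected test and star
#' annotation, and the oriented per-peak ROC AUC. Intended for
#' patient-level datasets (see [patient_mean_spectra()]); cell-level input
#' triggers a pseudoreplication warning.
#'
#' @param dataset A [spectra_set()], normally one row per patient.
#' @param peak_list Data frame with columns `center` and (optionally)
#'   `assignment`; default [default_peak_list()].
#' @param halfwidth Extraction window half-width in cm^-1.
#' @return A `peak_table` data frame: one row per peak with group
#'   statistics, `p_value`, `test_used`, `stars`, `auc`, `direction`.
#' @export
build_peak_table <- function(dataset, peak_list = default_peak_list(),
                             halfwidth = 5) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (anyDuplicated(dataset$meta$patient_id)) {
    warning(paste("multiple rows per patient: cell-level peak statistics",
                  "are subject to pseudoreplication"), call. = FALSE)
  }
  if (is.null(peak_list$assignment)) peak_list$assignment <- NA_character_
  groups <- dataset$meta$group
  rows <- lapply(seq_len(nrow(peak_list)), function(i) {
    center <- peak_list$center[i]
    vals <- vapply(seq_len(n_spectra(dataset)), function(r) {
      extract_peak_intensity(get_spectrum(dataset, r), center, halfwidth)
    }, numeric(1L))
    a <- vals[groups == "CR"]
    b <- vals[groups == "NR"]
    cmp <- group_compare(a, b)
    roc <- per_peak_roc(vals, groups)
    data.frame(center = center, assignment = peak_list$assignment[i],
               mean_CR = mean(a), sd_CR = stats::sd(a),
               mean_NR = mean(b), sd_NR = stats::sd(b),
               p_value = cmp$p_value, test_used = cmp$test_used,
               stars = significance_stars(cmp$p_value),
               auc = roc$auc, direction = roc$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_table", class(out))
  out
}
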