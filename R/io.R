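# Plain-text storage of spectra matrices and metadata manifests.
# Dialect: TSV, UTF-8, "." decimal, one header row of wavenumbers in the
# matrix file; metadata in a separate file so the matrix stays numeric.
# Lines starting with "#" are treated as comments (used for provenance
# headers written by run_pipeline).

#' Read a spectra matrix and metadata manifest from TSV files
#'
#' The matrix file holds one header row of wavenumbers, then one row per
#' spectrum: the sample id followed by its intensities. The metadata manifest
#' maps `sample_id` to `patient_id` and `group`. Samples missing from the
#' manifest are kept with group `UNKNOWN` and a warning.
#'
#' @param path_matrix Path to the spectra matrix TSV.
#' @param path_meta Path to the metadata manifest TSV (columns `sample_id`,
#'   `patient_id`, `group`).
#' @return A validated [spectra_set()].
#' @export
read_spectra_table <- function(path_matrix, path_meta) {
  lines <- readLines(path_matrix, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("format error: empty matrix file", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  wn <- suppressWarnings(as.numeric(header))
  if (anyNA(wn)) {
    stop("format error: header row must contain numeric wavenumbers",
         call. = FALSE)
  }
  if (any(diff(wn) <= 0)) {
    stop("grid error: wavenumber header must be strictly increasing",
         call. = FALSE)
  }
  p <- length(wn)
  n <- length(lines) - 1L
  mat <- matrix(NA_real_, nrow = n, ncol = p)
  ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != p + 1L) {
      stop(sprintf(
        "format error: data row %d has %d values, expected %d (sample id + %d channels)",
        i, length(fields), p + 1L, p), call. = FALSE)
    }
    ids[i] <- fields[[1L]]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) {
      stop(sprintf("format error: non-numeric intensity in data row %d", i),
           call. = FALSE)
    }
    mat[i, ] <- vals
  }
  manifest <- utils::read.delim(path_meta, colClasses = "character",
                                comment.char = "#")
  if (!all(c("sample_id", "patient_id", "group") %in% names(manifest))) {
    stop("format error: manifest needs columns sample_id, patient_id, group",
         call. = FALSE)
  }
  idx <- match(ids, manifest$sample_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sprintf("%d sample(s) missing from manifest; assigned group UNKNOWN (e.g. %s)",
                    sum(missing), ids[which(missing)[1L]]), call. = FALSE)
  }
  meta <- data.frame(
    sample_id = ids,
    patient_id = ifelse(missing, "unknown", manifest$patient_id[idx]),
    group = ifelse(missing, "UNKNOWN", manifest$group[idx]),
    stringsAsFactors = FALSE)
  spectra_set(wn, mat, meta)
}

#' Write a spectra_set to a matrix TSV and metadata manifest TSV
#'
#' Inverse of [read_spectra_table()]: the round trip reproduces the dataset to
#' full printed precision (15 significant digits).
#'
#' @param dataset A `spectra_set`.
#' @param path_matrix Output path for the matrix TSV.
#' @param path_meta Output path for the metadata manifest TSV.
#' @param digits Significant digits used when printing intensities.
#' @param header Optional character vector of comment lines (without the
#'   leading `#`) prepended to both files.
#' @return Invisibly, `dataset`.
#' @export
write_spectra_table <- function(dataset, path_matrix, path_meta,
                                digits = 15L, header = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  lines <- paste(fmt(dataset$wavenumbers), collapse = "\t")
  if (n_spectra(dataset) > 0L) {
    body <- vapply(seq_len(n_spectra(dataset)), function(i) {
      paste(c(dataset$meta$sample_id[i], fmt(dataset$matrix[i, ])),
            collapse = "\t")
    }, character(1L))
    lines <- c(lines, body)
  }
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  tryCatch(writeLines(lines, path_matrix, useBytes = TRUE),
           error = function(e) stop("I/O error writing ", path_matrix, ": ",
                                    conditionMessage(e), call. = FALSE))
  meta_lines <- c(
    if (!is.null(header)) paste0("# ", header),
    "sample_id\tpatient_id\tgroup",
    if (n_spectra(dataset) > 0L)
      paste(dataset$meta$sample_id, dataset$meta$patient_id,
            dataset$meta$group, sep = "\t"))
  tryCatch(writeLines(meta_lines, path_meta, useBytes = TRUE),
           error = function(e) stop("I/O error writing ", path_meta, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(dataset)
}

#' Write a numeric matrix with a self-describing header as TSV
#'
#' Used for model outputs (scores, loadings, resolved component spectra,
#' metrics tables).
#'
#' @param x Matrix or data frame.
#' @param path Output path.
#' @param header Optional comment lines (without leading `#`).
#' @return Invisibly, `path`.
#' @export
write_tsv_output <- function(x, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
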