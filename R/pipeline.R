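# End-to-end pipeline driver: simulate -> preprocess -> crossval ->
# permutation test -> MCR -> peak table, with a shared config, one global
# seed fanned out into stable per-stage child seeds, and provenance
# headers (config hash + seed) on every artifact.

#' Build a run configuration
#'
#' Defaults follow the documented reproduction settings: cumulative
#' variance threshold 0.90, ten folds, 1000 permutations, MCR with k = 4,
#' at most 50 iterations, 0.1% convergence tolerance and 10% SIMPLISMA
#' noise.
#'
#' @param synthetic A [synthetic_config()] (used by the simulate stage).
#' @param preprocess A [preprocess_config()].
#' @param var_threshold,folds,n_permutations Classifier settings.
#' @param mcr_k,mcr_max_iter,mcr_tol,mcr_noise_percent MCR settings.
#' @param peak_list Peak table for the peaks stage.
#' @param peak_halfwidth Extraction half-width, cm^-1.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       preprocess = preprocess_config(),
                       var_threshold = 0.90, folds = 10L,
                       n_permutations = 1000L,
                       mcr_k = 4L, mcr_max_iter = 50L, mcr_tol = 0.001,
                       mcr_noise_percent = 10,
                       peak_list = default_peak_list(),
                       peak_halfwidth = 5,
                       seed = 1L) {
  structure(list(synthetic = synthetic, preprocess = preprocess,
                 var_threshold = var_threshold, folds = as.integer(folds),
                 n_permutations = as.integer(n_permutations),
                 mcr_k = as.integer(mcr_k),
                 mcr_max_iter = as.integer(mcr_max_iter),
                 mcr_tol = mcr_tol, mcr_noise_percent = mcr_noise_percent,
                 peak_list = peak_list, peak_halfwidth = peak_halfwidth,
                 seed = as.integer(seed)), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments; nested
#' `synthetic` and `preprocess` maps are passed to their constructors.
#' Unspecified fields keep their defaults. A `seed` entry is required so
#' every run is reproducible from its config alone.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) {
    stop("config error: a seed entry is required", call. = FALSE)
  }
  syn <- do.call(synthetic_config,
                 c(raw$synthetic, if (is.null(raw$synthetic$seed))
                   list(seed = raw$seed)))
  pre <- do.call(preprocess_config, if (is.null(raw$preprocess)) list()
                 else raw$preprocess)
  keep <- intersect(names(raw),
                    c("var_threshold", "folds", "n_permutations", "mcr_k",
                      "mcr_max_iter", "mcr_tol", "mcr_noise_percent",
                      "peak_halfwidth", "seed"))
  do.call(run_config, c(list(synthetic = syn, preprocess = pre), raw[keep]))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

# one global seed fans out into stable per-stage child seeds
stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, 5L),
                  c("simulate", "crossval", "permtest", "mcr", "peaks"))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `preprocess`,
#' `crossval`, `permtest`, `mcr`, `peaks`), writing each stage's artifacts
#' as TSV files with a provenance header (config hash, global seed) into
#' `outdir`. A stage failure raises an error naming the stage. Identical
#' config and seed give byte-identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("ramanaml_"),
                         stages = c("simulate", "preprocess", "crossval",
                                    "permtest", "mcr", "peaks"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (config$folds > min(config$synthetic$cells_per_group)) {
    stop("validation error: folds exceed the smallest class size",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("config_hash: %s", config_hash(config)),
           sprintf("seed: %d", config$seed))
  seeds <- stage_seeds(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  results <- list()
  run_stage <- function(name, expr) {
    say("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dataset <- NULL
  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", {
      cfg <- config$synthetic
      cfg$seed <- seeds[["simulate"]]
      simulate_dataset(cfg)
    })
    results$simulate <- sim
    dataset <- sim$dataset
    write_spectra_table(dataset, file.path(outdir, "raw_matrix.tsv"),
                        file.path(outdir, "raw_meta.tsv"), header = hdr)
    truth_c <- cbind(sim$truth$meta["sample_id"],
                     as.data.frame(sim$truth$concentrations))
    write_tsv_output(truth_c, file.path(outdir, "truth_concentrations.tsv"),
                     header = hdr)
    write_tsv_output(
      cbind(data.frame(component = rownames(sim$truth$pure_spectra)),
            as.data.frame(sim$truth$pure_spectra)),
      file.path(outdir, "truth_pure_spectra.tsv"), header = hdr)
  }
  glass_ref <- render_glass_reference(
    if (is.null(dataset)) config$synthetic$grid else dataset$wavenumbers)

  if ("preprocess" %in% stages) {
    if (is.null(dataset)) stop("preprocess stage needs the simulate stage",
                               call. = FALSE)
    pp <- run_stage("preprocess",
                    preprocess_pipeline(dataset, glass_ref, config$preprocess))
    results$preprocess <- pp
    dataset <- pp$dataset
    write_spectra_table(dataset, file.path(outdir, "processed_matrix.tsv"),
                        file.path(outdir, "processed_meta.tsv"), header = hdr)
    write_tsv_output(pp$report, file.path(outdir, "preprocess_report.tsv"),
                     header = hdr)
  }

  if ("crossval" %in% stages) {
    cv <- run_stage("crossval",
                    cross_validate(dataset, folds = config$folds,
                                   seed = seeds[["crossval"]],
                                   var_threshold = config$var_threshold))
    results$crossval <- cv
    m <- cv$metrics
    write_tsv_output(
      data.frame(metric = c("accuracy", "sensitivity", "specificity", "auc"),
                 value = c(m$accuracy, m$sensitivity, m$specificity,
                           cv$roc$auc)),
      file.path(outdir, "crossval_metrics.tsv"), header = hdr)
  }

  if ("permtest" %in% stages) {
    pt <- run_stage("permtest",
                    permutation_test(dataset,
                                     n_permutations = config$n_permutations,
                                     folds = config$folds,
                                     var_threshold = config$var_threshold,
                                     seed = seeds[["permtest"]]))
    results$permtest <- pt
    write_tsv_output(
      data.frame(observed_auc = pt$observed_auc, p_value = pt$p_value,
                 n_permutations = length(pt$null_aucs),
                 null_mean_auc = mean(pt$null_aucs)),
      file.path(outdir, "permutation_test.tsv"), header = hdr)
  }

  if ("mcr" %in% stages) {
    mcr <- run_stage("mcr", {
      init <- simplisma(dataset$matrix, config$mcr_k,
                        config$mcr_noise_percent)
      mcr_als_fit(dataset$matrix, init, config$mcr_max_iter, config$mcr_tol)
    })
    results$mcr <- mcr
    write_tsv_output(cbind(dataset$meta["sample_id"], as.data.frame(mcr$C)),
                     file.path(outdir, "mcr_concentrations.tsv"), header = hdr)
    write_tsv_output(as.data.frame(mcr$S),
                     file.path(outdir, "mcr_pure_spectra.tsv"), header = hdr)
    abund <- run_stage("mcr", compare_component_scores(mcr, dataset$meta))
    results$mcr_groups <- abund
    write_tsv_output(abund, file.path(outdir, "mcr_group_comparison.tsv"),
                     header = hdr)
  }

  if ("peaks" %in% stages) {
    pk <- run_stage("peaks", {
      pat <- patient_mean_spectra(dataset)
      build_peak_table(pat, config$peak_list, config$peak_halfwidth)
    })
    results$peaks <- pk
    write_tsv_output(pk, file.path(outdir, "peak_table.tsv"), header = hdr)
  }

  say("done: %s", outdir)
  invisible(c(results, list(outdir = outdir)))
}
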