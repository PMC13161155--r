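# Shared fixtures, built in code at test time.

# tiny 3-sample, 5-channel set with simple metadata
tiny_set <- function() {
  spectra_set(
    wavenumbers = c(600, 700, 800, 900, 1000),
    matrix = rbind(c(1, 2, 3, 4, 5),
                   c(5, 4, 3, 2, 1),
                   c(2, 2, 2, 2, 3)),
    meta = data.frame(sample_id = c("s1", "s2", "s3"),
                      patient_id = c("p1", "p1", "p2"),
                      group = c("CR", "CR", "NR")))
}

fingerprint_grid <- function(n = 400) seq(600, 1800, length.out = n)

# small three-component library for fast recovery tests
small_library <- function() {
  lib <- default_component_library()
  structure(lib[c("protein", "lipid_carbohydrate", "nucleic_acid")],
            class = "component_library")
}

# noiseless bilinear config: no baseline, no glass, no channel noise
clean_config <- function(n_channels = 400, cells = c(CR = 30, NR = 30),
                         n_patients = 3, seed = 1,
                         library = small_library(),
                         profiles = default_group_profiles()) {
  synthetic_config(
    n_channels = n_channels, n_patients = n_patients,
    cells_per_group = cells, library = library, profiles = profiles,
    baseline_params = list(amplitude = 0, decay_range = c(0.5, 1.5),
                           offset_range = c(0.2, 1)),
    glass_params = list(amplitude = 0, cv = 0), noise_sd = 0, seed = seed)
}

# gaussian cluster pair for classifier tests: two classes separated along
# the first coordinate by `sep` standard deviations
gaussian_clusters <- function(n_per_class, dim = 5, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * dim), ncol = dim),
             matrix(rnorm(n_per_class * dim), ncol = dim))
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + sep
  labels <- rep(c("CR", "NR"), each = n_per_class)
  list(x = x, labels = labels)
}

# wrap a plain matrix as a spectra_set on an arbitrary increasing grid
as_set <- function(x, labels, patients = NULL) {
  n <- nrow(x)
  if (is.null(patients)) patients <- paste0("p", seq_len(n))
  spectra_set(seq_len(ncol(x)) + 599, x,
              data.frame(sample_id = paste0("s", seq_len(n)),
                         patient_id = patients, group = labels))
}

# brute-force AUC: exhaustive pairwise comparisons with half credit on ties
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
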