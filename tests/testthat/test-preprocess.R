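test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  grid <- fingerprint_grid(600)
  t <- (grid - 600) / 1200
  cubic <- 5 + 2 * t - 7 * t^2 + 3 * t^3
  sm <- sg_denoise(raman_spectrum(grid, cubic), window = 25, order = 3)
  expect_equal(sm$intensities, cubic, tolerance = 1e-10)
  const <- sg_denoise(raman_spectrum(grid, rep(4, 600)), 25, 3)
  expect_equal(const$intensities, rep(4, 600), tolerance = 1e-12)
  expect_error(sg_denoise(raman_spectrum(grid, cubic), window = 24), "odd")
  expect_error(sg_denoise(raman_spectrum(grid, cubic), window = 3,
                          order = 3), "order")
})

test_that("S-G noise attenuation matches the filter-coefficient closed form", {
  # variance of filtered white noise = sum of squared filter coefficients
  h <- signal::sgolay(p = 3, n = 25)[13, ]  # central (steady-state) row
  predicted <- sum(h^2)
  set.seed(1)
  n <- 20000
  noise <- rnorm(n)
  sm <- sg_denoise(raman_spectrum(seq_len(n), noise), 25, 3)
  interior <- 13:(n - 12)
  ratio <- var(sm$intensities[interior]) / var(noise[interior])
  expect_lt(abs(ratio - predicted) / predicted, 0.1)
  expect_lt(ratio, 1)
})

test_that("RMSE window selection picks the sweet spot between under- and over-smoothing", {
  grid <- fingerprint_grid(800)
  clean <- render_pure_spectrum(list(peak_def(1000, width = 20),
                                     peak_def(1400, width = 25)), grid)
  set.seed(7)
  noisy <- raman_spectrum(grid, clean$intensities + rnorm(800, sd = 0.08))
  expect_equal(select_sg_window(noisy, clean, c(5, 25, 101)), 25)
  # no noise: any smoothing only distorts, smallest window wins
  expect_equal(select_sg_window(clean, clean, c(5, 25, 101)), 5)
  expect_equal(select_sg_window(noisy, clean, 25), 25)
  expect_error(select_sg_window(noisy, clean, integer(0)), "candidate")
})

test_that("a pure-substrate spectrum yields its exact glass scale", {
  grid <- fingerprint_grid(700)
  glass <- render_glass_reference(grid)
  cell <- raman_spectrum(grid, 0.7 * glass$intensities)
  out <- remove_glass_background(cell, glass)
  expect_equal(out$scale, 0.7, tolerance = 1e-6)
  expect_lt(max(abs(out$spectrum$intensities)), 1e-9)
})

test_that("a glass-free peak spectrum is left nearly untouched", {
  grid <- fingerprint_grid(700)
  glass <- render_glass_reference(grid)
  peaks <- render_pure_spectrum(
    list(peak_def(700, width = 10, shape = "gaussian"),
         peak_def(1050, width = 10, shape = "gaussian"),
         peak_def(1430, width = 10, shape = "gaussian")), grid)
  out <- remove_glass_background(peaks, glass)
  expect_lt(out$scale, 0.1)
  expect_lt(max(abs(out$spectrum$intensities - peaks$intensities)), 0.1)
})

test_that("glass scale is recovered within 10% on bilinear fixtures", {
  grid <- fingerprint_grid(600)
  glass <- render_glass_reference(grid)
  # gaussian lineshapes: their light tails keep the fixture's coarse-band
  # energy small, which is what bounds the achievable recovery accuracy
  lib <- lapply(small_library(), function(pk) {
    lapply(pk, function(p) peak_def(p$center, p$width, p$amplitude,
                                    "gaussian"))
  })
  pure <- t(vapply(lib, function(p) render_pure_spectrum(p, grid)$intensities,
                   numeric(600)))
  for (seed in 1:20) {
    set.seed(seed)
    conc <- runif(3, 0.5, 1.5)
    truth <- drop(conc %*% pure)
    # the coarse-band fit is accurate to ~0.03 in absolute scale units, so
    # substantial (>= 0.4) substrate contributions are recovered within 10%
    gscale <- runif(1, 0.4, 0.8)
    cell <- raman_spectrum(grid, truth + gscale * glass$intensities)
    out <- remove_glass_background(cell, glass)
    expect_lt(abs(out$scale - gscale) / gscale, 0.10)
    rmse <- function(v) sqrt(mean((v - truth)^2))
    expect_lt(rmse(out$spectrum$intensities), rmse(cell$intensities))
  }
  expect_error(
    remove_glass_background(raman_spectrum(grid, rep(1, 600)),
                            render_glass_reference(fingerprint_grid(300))),
    "alignment")
  expect_error(remove_glass_background(get_spectrum(tiny_set(), 1),
                                       render_glass_reference(
                                         tiny_set()$wavenumbers),
                                       dwt_levels = 6),
               "parameter")
})

test_that("baseline correction flattens a pure hump and preserves pure peaks", {
  grid <- fingerprint_grid(900)
  t <- (grid - 600) / 1200
  hump <- 2 * exp(-(t - 0.4)^2 / 0.18)
  out <- correct_baseline_spline(raman_spectrum(grid, hump),
                                 interval_init = 120)
  expect_lt(max(out$spectrum$intensities), 0.02 * max(hump))

  peaks <- render_pure_spectrum(list(peak_def(800, width = 12),
                                     peak_def(1100, width = 12),
                                     peak_def(1500, width = 12)), grid)
  out2 <- correct_baseline_spline(peaks, interval_init = 120)
  expect_true(all(out2$spectrum$intensities >= 0))
  for (ctr in c(800, 1100, 1500)) {
    h0 <- extract_peak_intensity(peaks, ctr)
    h1 <- extract_peak_intensity(out2$spectrum, ctr)
    expect_lt(abs(h1 - h0) / h0, 0.05)
  }
  expect_error(correct_baseline_spline(peaks, interval_init = 2), ">= 4")
  expect_error(correct_baseline_spline(peaks, interval_init = 2000), "wider")
})

test_that("baseline correction moves contaminated spectra toward the truth", {
  grid <- fingerprint_grid(700)
  lib <- small_library()
  pure <- t(vapply(lib, function(p) render_pure_spectrum(p, grid)$intensities,
                   numeric(700)))
  params <- list(amplitude = 0.5, decay_range = c(0.5, 1.5),
                 offset_range = c(0.2, 1))
  improved <- 0
  n_trials <- 100
  for (seed in seq_len(n_trials)) {
    set.seed(seed)
    truth <- drop(runif(3, 0.5, 1.5) %*% pure)
    base <- render_fluorescence_baseline(grid, params)$intensities
    contaminated <- raman_spectrum(grid, truth + base)
    out <- correct_baseline_spline(contaminated, interval_init = 100)
    rmse <- function(v) sqrt(mean((v - truth)^2))
    if (rmse(out$spectrum$intensities) < rmse(contaminated$intensities)) {
      improved <- improved + 1
    }
  }
  expect_gte(improved / n_trials, 0.95)
})

test_that("min-max normalization maps onto [0, 1] and is idempotent there", {
  s <- raman_spectrum(c(600, 700, 800), c(2, 4, 6))
  expect_equal(minmax_normalize(s)$intensities, c(0, 0.5, 1))
  norm <- minmax_normalize(s)
  expect_equal(minmax_normalize(norm), norm)
  expect_error(minmax_normalize(raman_spectrum(c(600, 700, 800), c(5, 5, 5))),
               "degenerate")
})

test_that("crop_region keeps the closed interval and rejects empty overlap", {
  ds <- tiny_set()
  cropped <- crop_region(ds, 700, 900)
  expect_equal(cropped$wavenumbers, c(700, 800, 900))
  expect_equal(crop_region(ds, 600, 1000)$matrix, ds$matrix)
  expect_error(crop_region(ds, 2000, 2200), "range error")
  expect_error(crop_region(ds, 900, 700), "range error")
})

test_that("the full pipeline yields unit-range fingerprint spectra closer to truth", {
  cfg <- synthetic_config(
    n_channels = 500, n_patients = 2, cells_per_group = c(CR = 6, NR = 6),
    library = small_library(), seed = 21)
  sim <- simulate_dataset(cfg)
  glass <- render_glass_reference(sim$dataset$wavenumbers)
  out <- preprocess_pipeline(sim$dataset, glass,
                             preprocess_config(spline_interval = 60))
  expect_equal(unname(apply(out$dataset$matrix, 1, min)), rep(0, 12))
  expect_equal(unname(apply(out$dataset$matrix, 1, max)), rep(1, 12))
  expect_true(all(out$dataset$wavenumbers >= 600 &
                    out$dataset$wavenumbers <= 1800))
  expect_equal(nrow(out$report), 12)
  expect_true(all(out$report$glass_scale >= 0))

  # corrected spectra should resemble the interference-free truth more than
  # the raw spectra do (cosine similarity, mean over cells)
  clean <- sim$truth$concentrations %*% sim$truth$pure_spectra
  cos_to_truth <- function(m) {
    mean(vapply(seq_len(nrow(m)), function(i) {
      a <- m[i, ]; b <- clean[i, ]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1)))
  }
  expect_gt(cos_to_truth(out$dataset$matrix), cos_to_truth(sim$dataset$matrix))
})

test_that("pipeline errors name the failing stage", {
  ds <- tiny_set()
  glass <- render_glass_reference(ds$wavenumbers)
  expect_error(preprocess_pipeline(ds, glass, preprocess_config()),
               "sg_denoise")
})
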