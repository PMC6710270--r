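test_that("phantoms are valid, reproducible and reject bad layouts", {
  ph <- make_phantom(64, 64, "gut-bands", seed = 1)
  expect_equal(sort(unique(as.vector(ph$labels))), 1:6)
  expect_equal(ph$region_names[1], "lumen")
  ph2 <- make_phantom(64, 64, "gut-bands", seed = 1)
  expect_identical(ph$labels, ph2$labels)
  expect_false(identical(ph$labels,
                         make_phantom(64, 64, "gut-bands", seed = 2)$labels))
  # minimal phantom
  mini <- make_phantom(2, 2, "blocks", n_regions = 2)
  expect_equal(dim(mini$labels), c(2L, 2L))
  expect_equal(sort(unique(as.vector(mini$labels))), 1:2)
  expect_error(make_phantom(64, 64, "x"), "arg")
  expect_error(make_phantom(1, 2), "4 pixels")
})

test_that("fixed seed gives a bitwise-identical dataset", {
  ph <- make_phantom(6, 6, "blocks", n_regions = 2, seed = 1)
  spikes <- default_spikes(50, regions = "region_1")
  a <- simulate_dataset(ph, spikes = spikes, mz_range = c(200, 550), seed = 5)
  b <- simulate_dataset(ph, spikes = spikes, mz_range = c(200, 550), seed = 5)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  c <- simulate_dataset(ph, spikes = spikes, mz_range = c(200, 550), seed = 6)
  expect_false(identical(a$dataset$intensities, c$dataset$intensities))
})

test_that("a noiseless lumen spike reproduces the exact Br doublet everywhere in the lumen", {
  ph <- make_phantom(8, 8, "gut-bands", seed = 2)
  silent <- noise_model(baseline_amp = 0, wobble_amp = 0, noise_sd = 0,
                        drift_ppm = 0)
  spike <- spike_spec("C8H4BrNO2", "[M-H]+", "lumen", 100, sigma = 0)
  sim <- simulate_dataset(ph, spikes = list(spike), lipids = NULL,
                          noise = silent, mz_range = c(200, 300), seed = 1)
  pat <- isotope_distribution("C8H4BrNO2", "[M-H]+")
  lumen <- which(sim$truth$labels == 1L)
  expect_gt(length(lumen), 0)
  # the two Br isotopologue peaks are rows 1 and 3 of the envelope (row 2 is
  # the 13C satellite of the 79Br peak)
  br_mz <- pat$mz[c(1L, 3L)]
  for (i in lumen) {
    pk <- pick_peaks(get_spectrum(sim$dataset, i), snr_min = 3)
    hit <- vapply(br_mz, function(m) which.min(abs(pk$mz - m)), integer(1))
    expect_equal(pk$mz[hit], br_mz, tolerance = 0.05)  # within one grid bin
    expect_equal(pk$intensity[hit[2L]] / pk$intensity[hit[1L]],
                 0.4931 / 0.5069, tolerance = 0.01)
  }
  # non-lumen pixels carry no signal at all
  outside <- which(sim$truth$labels != 1L)
  expect_equal(sum(sim$dataset$intensities[outside, ]), 0)
})

test_that("no spikes, no noise, no lipids gives all-zero spectra", {
  ph <- make_phantom(4, 4, "blocks", n_regions = 2)
  silent <- noise_model(baseline_amp = 0, wobble_amp = 0, noise_sd = 0)
  sim <- simulate_dataset(ph, spikes = list(), lipids = NULL, noise = silent,
                          mz_range = c(100, 200), seed = 1)
  expect_equal(sum(sim$dataset$intensities), 0)
})

test_that("the default configuration yields >3000 informative spectra", {
  # statistical scale of one section's acquisition: >3,000 spectra
  ph <- make_phantom(64, 64, "gut-bands", seed = 3)
  expect_gte(prod(dim(ph$labels)), 3000)
  # verified on a subsampled simulation: every pixel has positive TIC
  ph_small <- make_phantom(10, 10, "gut-bands", seed = 3)
  sim <- simulate_dataset(ph_small, spikes = default_spikes(50), seed = 3)
  expect_true(all(tic(sim$dataset) > 0))
})

test_that("the lipid background contains flagged di-Br decoy pairs in range", {
  lip <- default_lipid_background()
  expect_gte(nrow(lip), 35)
  expect_true(all(lip$mz >= 400 & lip$mz <= 1100))
  decoys <- lip[lip$decoy, ]
  expect_gte(nrow(decoys), 2)
  for (pr in unique(decoys$decoy_pair)) {
    pair <- decoys[decoys$decoy_pair == pr, ]
    expect_equal(nrow(pair), 2L)
    expect_lt(abs(diff(pair$mz) - 1.998), 0.05)
  }
  # non-decoy species never fall within screening distance of the spiked
  # brominated compounds
  spikes <- vapply(default_spikes(), function(s) s$pattern$mz[1L], numeric(1))
  expect_true(all(outer(lip$mz[!lip$decoy], spikes, function(a, b)
    abs(a - b)) > 0.5))
})

test_that("simulation rejects spikes outside the range or in unknown regions", {
  ph <- make_phantom(4, 4, "blocks", n_regions = 2)
  sp <- spike_spec("C8H4BrNO2", "[M-H]+", "region_1", 10)
  expect_error(simulate_dataset(ph, spikes = list(sp), lipids = NULL,
                                mz_range = c(300, 400)),
               "excludes isotopologues.*C8H4BrNO2")
  bad <- spike_spec("C8H4BrNO2", "[M-H]+", "lumen", 10)
  expect_error(simulate_dataset(ph, spikes = list(bad), lipids = NULL,
                                mz_range = c(200, 300)),
               "unknown region")
})

test_that("ground truth JSON and label-map PGM are written", {
  ph <- make_phantom(4, 4, "blocks", n_regions = 2)
  sim <- simulate_dataset(ph, spikes = default_spikes(10, "region_1"),
                          lipids = NULL, mz_range = c(200, 550), seed = 1)
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "gt.json"); pp <- file.path(dir, "gt.pgm")
  write_ground_truth(sim$truth, jp, pp)
  gt <- jsonlite::read_json(jp)
  expect_equal(length(gt$spikes), nrow(sim$truth$spikes))
  expect_equal(readLines(pp)[1], "P2")
})
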