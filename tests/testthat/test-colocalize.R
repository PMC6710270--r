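test_that("ion images integrate windows, respect masks and are additive", {
  ph <- make_phantom(8, 8, "gut-bands", seed = 2)
  silent <- noise_model(baseline_amp = 0, wobble_amp = 0, noise_sd = 0,
                        drift_ppm = 0)
  sim <- simulate_dataset(ph, spikes = list(
    spike_spec("C8H4BrNO2", "[M-H]+", "lumen", 100)),
    lipids = NULL, noise = silent, mz_range = c(200, 300), seed = 4)
  ds <- sim$dataset
  img <- ion_image(ds, 223.934, 0.3)
  lumen_mask <- pixel_image(ds, sim$truth$labels == 1L)
  expect_true(all((img > 0) == lumen_mask))
  # empty window
  expect_equal(sum(ion_image(ds, 280, 0.5)), 0)
  # additivity over disjoint windows whose union is a single window
  a2 <- ion_image(ds, 223.5, 0.5)    # bins 223.00-224.00
  b2 <- ion_image(ds, 224.55, 0.5)   # bins 224.05-225.05
  u <- ion_image(ds, 224.025, 1.025) # bins 223.00-225.05
  expect_equal(a2 + b2, u, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(ion_image(ds, 500, 0.1), "outside")
  expect_error(ion_image(ds, 250, 0), "tol")
})

test_that("spatial correlation is symmetric, bounded, exact on self and inverse", {
  set.seed(5)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, -a + 3), -1)
  expect_equal(spatial_correlation(a, b), spatial_correlation(b, a))
  expect_true(abs(spatial_correlation(a, b)) <= 1)
  expect_error(spatial_correlation(a, matrix(0, 8, 8)), "zero-variance")
  expect_error(spatial_correlation(a, matrix(1, 4, 4)), "shape")
})

test_that("images sharing a mask with independent noise stay highly correlated", {
  set.seed(12)
  mask <- matrix(0, 16, 16); mask[5:12, 5:12] <- 100
  a <- mask * (1 + 0.1 * matrix(rnorm(256), 16))
  b <- mask * (1 + 0.1 * matrix(rnorm(256), 16))
  expect_gte(spatial_correlation(a, b), 0.9)
})

test_that("co-localisation groups follow the phantom design and ignore input order", {
  ph <- make_phantom(12, 12, "gut-bands", seed = 3)
  silent <- noise_model(baseline_amp = 0, wobble_amp = 0, noise_sd = 0,
                        drift_ppm = 0)
  # two lumen compounds, one mucosa compound (the lymphoid-tissue layout)
  sim <- simulate_dataset(ph, spikes = list(
    spike_spec("C8H4BrNO2", "[M-H]+", "lumen", 100),
    spike_spec("C9H6BrNOS", "[M+H]+", "lumen", 80),
    spike_spec("C12H18BrN2O2", "[M]+", "mucosa", 90)),
    lipids = NULL, noise = silent, mz_range = c(200, 320), seed = 5)
  ds <- sim$dataset
  cand <- rbind(
    find_halogen_signatures(pick_peaks(roi_summed_spectrum(
      ds, sim$truth$labels, 1L), snr_min = 3)),
    find_halogen_signatures(pick_peaks(roi_summed_spectrum(
      ds, sim$truth$labels, 3L), snr_min = 3)))
  # keep the main envelopes; noiseless ROI sums also expose the weak 13C
  # satellite doublets of each compound one mass unit up
  expected <- c(ion_mz("C8H4BrNO2", "[M-H]+"), ion_mz("C9H6BrNOS", "[M+H]+"),
                ion_mz("C12H18BrN2O2", "[M]+"))
  cand <- cand[vapply(expected, function(m) which.min(abs(cand$mono_mz - m)),
                      integer(1)), , drop = FALSE]
  expect_true(all(abs(cand$mono_mz - expected) < 0.05))
  g <- colocalization_groups(cand, ds, r_min = 0.7)
  expect_equal(length(unique(g)), 2L)
  # the two lumen compounds share a group
  lum <- which(abs(cand$mono_mz - 223.934) < 0.05 |
                 abs(cand$mono_mz - 255.943) < 0.05)
  expect_equal(length(unique(g[lum])), 1L)
  # permuted input gives the same grouping after renumbering
  perm <- c(3L, 1L, 2L)
  g2 <- colocalization_groups(cand[perm, ], ds, r_min = 0.7)
  expect_equal(g2, g[perm], ignore_attr = TRUE)
  # singleton
  g3 <- colocalization_groups(cand[1L, ], ds)
  expect_equal(g3, structure(1L, r = diag(1)), ignore_attr = TRUE)
})

test_that("annotation matches library ions, keeps isobars, names the rest M-series", {
  cand <- find_halogen_signatures(peak_list_for_test(
    c(223.9342, 225.9322), c(0.5069, 0.4931)))
  ann <- annotate_candidates(cand, tol_ppm = 10)
  expect_equal(ann$name, "6-bromoisatin (6Br)")
  expect_equal(ann$adduct, "[M-H]+")
  expect_lt(abs(ann$ppm), 10)

  # dibromo dimer: TP and DBI are isobaric -- both must be listed
  tpl2 <- halogen_template(2L)
  mz0 <- ion_mz("C16H8Br2N2O2", "[M+H]+")
  cand2 <- find_halogen_signatures(peak_list_for_test(
    mz0 + tpl2$spacings, tpl2$abundances))
  ann2 <- annotate_candidates(cand2, tol_ppm = 10)
  expect_equal(ann2$n_matches, 2L)
  expect_match(ann2$ambiguous, "dibromoindigo")
  expect_match(ann2$ambiguous, "dibromoindirubin")

  # unknown mass gets an M-series placeholder
  cand3 <- find_halogen_signatures(peak_list_for_test(
    c(500.000, 501.998), c(0.51, 0.49)))
  ann3 <- annotate_candidates(cand3, tol_ppm = 5)
  expect_equal(ann3$name, "M24")  # continues the library M-series
  expect_equal(ann3$n_matches, 0L)
})

test_that("mass-only library entries participate in annotation", {
  lib <- read_compound_library()
  m17 <- lib[grepl("M17", lib$name), ]
  expect_true(is.na(m17$formula))
  cand <- find_halogen_signatures(peak_list_for_test(
    c(432.963, 434.961), c(0.51, 0.49)))
  ann <- annotate_candidates(cand, tol_ppm = 10)
  expect_match(ann$name, "M17")
})

test_that("region fold change recovers designed ratios and flags degenerate input", {
  mz <- seq(200, 260, by = 0.05)
  doublet_mz <- c(223.9342, 225.9322)
  doublet_ab <- c(0.5069, 0.4931)
  shape <- function(area) {
    x <- numeric(length(mz))
    x[mz < 220] <- 5                 # matrix TIC floor away from the signal
    for (j in 1:2) {
      x <- x + area * doublet_ab[j] * dnorm(mz, doublet_mz[j], 0.05) * 0.05
    }
    msi_spectrum(mz, x)
  }
  cand <- find_halogen_signatures(peak_list_for_test(doublet_mz, doublet_ab))
  a <- shape(100); b <- shape(200)
  expect_equal(region_fold_change(a, a, cand[1L, ], tol = 0.3), 1.0)
  fc <- region_fold_change(a, b, cand[1L, ], tol = 0.3)
  expect_equal(fc, 2.0, tolerance = 0.05)
  empty <- msi_spectrum(mz, numeric(length(mz)))
  expect_error(region_fold_change(empty, empty, cand[1L, ]), "absent")
})
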