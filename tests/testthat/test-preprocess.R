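test_that("TopHat equals the naive sliding-window opening oracle exactly", {
  set.seed(7)
  mz <- seq(100, 150, by = 0.05)
  n <- length(mz)
  cases <- list(
    flat = rep(3.2, n),
    ramp = seq(0, 10, length.out = n),
    noisy = pmax(0, 2 + 0.05 * seq_len(n) %% 13 + rnorm(n)),
    spiky = {
      x <- numeric(n); x[c(100, 300, 700)] <- c(50, 80, 20); x
    }
  )
  for (x in cases) {
    got <- tophat_baseline(msi_spectrum(mz, pmax(x, 0)), window = 2)
    w <- 41L  # 2 Da / 0.05 rounded to odd
    oracle <- pmax(x, 0) - naive_opening(pmax(x, 0), w)
    expect_equal(got$intensity, oracle, tolerance = 0)
    expect_true(all(got$intensity >= 0))
    expect_true(all(got$intensity <= pmax(x, 0) + 1e-12))
  }
})

test_that("TopHat removes a constant, preserves narrow peaks on a ramp, is idempotent", {
  mz <- seq(200, 220, by = 0.05)
  flat <- tophat_baseline(msi_spectrum(mz, rep(5, length(mz))), 5)
  expect_true(all(flat$intensity == 0))
  # narrow Gaussian on a linear ramp: ramp removed, peak height kept within 1%
  ramp <- 2 + 0.3 * (mz - 200)
  peak <- 40 * exp(-(mz - 210)^2 / (2 * 0.06^2))
  th <- tophat_baseline(msi_spectrum(mz, ramp + peak), 5)
  apex <- which.max(th$intensity)
  expect_equal(mz[apex], 210, tolerance = 0.05)
  expect_equal(max(th$intensity), max(peak), tolerance = 0.01)
  expect_lt(max(th$intensity[abs(mz - 210) > 2]), 0.35 * 5 + 1e-9)
  # opening is idempotent: TopHat of its own output changes nothing
  th2 <- tophat_baseline(th, 5)
  expect_equal(th2$intensity, th$intensity, tolerance = 1e-12)
  expect_error(tophat_baseline(th, 0.01), "grid spacing")
})

test_that("TIC-preserving resampling conserves total and local mass", {
  mz <- seq(100, 200, by = 0.05)
  set.seed(11)
  sp <- msi_spectrum(mz, rexp(length(mz)))
  # identity axis
  same <- resample_tic_preserving(sp, mz)
  expect_equal(same$intensity, sp$intensity, tolerance = 1e-12)
  # coarser, finer and irregular axes conserve TIC to 1e-9 relative
  for (axis in list(seq(99, 201, by = 0.1),
                    seq(99, 201, by = 0.017),
                    sort(c(99, 201, runif(500, 99, 201))))) {
    r <- resample_tic_preserving(sp, axis)
    expect_lt(abs(sum(r$intensity) - sum(sp$intensity)) / sum(sp$intensity),
              1e-9)
    expect_true(all(r$intensity >= 0))
  }
  expect_error(resample_tic_preserving(sp, c(1, 1, 2)), "increasing")
})

test_that("peak picking finds noiseless doublets, ignores pure noise, scales invariantly", {
  # noiseless 6Br doublet (the two Br isotopologues) on the acquisition grid
  mz <- seq(200, 260, by = 0.05)
  doublet_mz <- c(223.9342, 225.9322)
  doublet_ab <- c(0.5069, 0.4931)
  x <- numeric(length(mz))
  for (j in 1:2) {
    x <- x + 100 * doublet_ab[j] * dnorm(mz, doublet_mz[j], 0.055) * 0.05
  }
  pk <- pick_peaks(msi_spectrum(mz, x), snr_min = 3)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$mz, doublet_mz, tolerance = 0.05)
  # uniform intensity scaling leaves detection and SNR unchanged
  pk2 <- pick_peaks(msi_spectrum(mz, 1000 * x), snr_min = 3)
  expect_equal(pk2$mz, pk$mz, tolerance = 1e-9)
  expect_equal(pk2$snr, pk$snr, tolerance = 1e-9)
  # all-zero spectrum
  expect_equal(nrow(pick_peaks(msi_spectrum(mz, numeric(length(mz))))), 0L)
  # pure noise at snr_min = 10: expected false positives well below 1
  fp <- vapply(1:10, function(s) {
    set.seed(s)
    ax <- seq(20, 1500, by = 0.05)
    noise <- pmax(0, rnorm(length(ax), 2, 0.5))
    nrow(pick_peaks(msi_spectrum(ax, noise), snr_min = 10))
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("quadratic calibration recovers identity and synthetic distortions", {
  ref <- csi_reference_masses()
  expect_equal(round(ref, 5),
               c(132.90490, 392.71483, 652.52475, 912.33468, 1172.14460,
                 1431.95453))
  ident <- fit_quadratic_calibration(ref, ref)
  expect_equal(unname(ident$coefficients), c(0, 1, 0), tolerance = 1e-12)
  # synthetic quadratic distortion: observed = inverse-distorted references
  a <- 4e-7; b <- 0.99985; c0 <- 0.05
  observed <- (-b + sqrt(b^2 - 4 * a * (c0 - ref))) / (2 * a)  # invert cal
  cal <- fit_quadratic_calibration(observed, ref)
  expect_equal(unname(cal$coefficients), c(c0, b, a), tolerance = 1e-6)
  expect_lt(max(abs(predict(cal, observed) - ref)), 1e-9)
  # calibrating already calibrated data is the identity
  cal2 <- fit_quadratic_calibration(predict(cal, observed), ref)
  expect_equal(unname(cal2$coefficients), c(0, 1, 0), tolerance = 1e-8)
  expect_error(fit_quadratic_calibration(ref[1:2], ref[1:2]), "at least 3")
  # nearest-peak matching within 0.5 Da against a cluttered peak list
  peaks <- sort(c(ref + rnorm(6, 0, 0.01), runif(30, 100, 1500)))
  cal3 <- fit_quadratic_calibration(peaks, ref)
  expect_equal(length(cal3$residuals), 6L)
  expect_lt(cal3$rms, 0.02)
})
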