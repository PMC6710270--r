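make_block_cube <- function(n_per_block = 20L, m_per_block = 15L, seed = 3L) {
  # two pixel blocks with disjoint peak sets
  set.seed(seed)
  V <- matrix(0, 2L * n_per_block, 2L * m_per_block)
  V[1:n_per_block, 1:m_per_block] <-
    matrix(rpois(n_per_block * m_per_block, 40), n_per_block)
  V[(n_per_block + 1L):(2L * n_per_block),
    (m_per_block + 1L):(2L * m_per_block)] <-
    matrix(rpois(n_per_block * m_per_block, 40), n_per_block)
  V
}

test_that("k = 1 recovers the closed-form multinomial optimum", {
  set.seed(1)
  V <- matrix(rpois(60, 10), 6, 10)
  fit <- plsa_fit(V, k = 1, seed = 1, n_restarts = 2)
  # analytic optimum: phi = column sums normalised; loglik = sum V log phi_w
  phi_opt <- colSums(V) / sum(V)
  expect_equal(as.vector(fit$phi), phi_opt, tolerance = 1e-6)
  ll_opt <- sum(V * log(matrix(phi_opt, 6, 10, byrow = TRUE))[V > 0])
  expect_equal(fit$loglik[length(fit$loglik)], ll_opt, tolerance = 1e-8)
  expect_true(all(label_pixels(fit) == 0L))
})

test_that("two disjoint blocks are perfectly separated at k = 2", {
  V <- make_block_cube()
  fit <- plsa_fit(V, k = 2, seed = 7)
  lab <- label_pixels(fit)
  expect_equal(length(unique(lab[1:20])), 1L)
  expect_equal(length(unique(lab[21:40])), 1L)
  expect_false(lab[1] == lab[21])
})

test_that("EM log-likelihood is non-decreasing for every seed", {
  V <- make_block_cube(10L, 8L)
  for (s in 1:20) {
    fit <- plsa_fit(V, k = 3, seed = s, n_restarts = 1, max_iter = 60)
    d <- diff(fit$loglik)
    expect_true(all(d >= -1e-9 * abs(fit$loglik[-length(fit$loglik)])),
                info = paste("seed", s))
  }
})

test_that("model normalisation invariants hold after fitting", {
  V <- make_block_cube(8L, 6L)
  fit <- plsa_fit(V, k = 4, seed = 2)
  expect_equal(rowSums(fit$theta), rep(1, nrow(V)), tolerance = 1e-9)
  expect_equal(rowSums(fit$phi), rep(1, 4L), tolerance = 1e-9)
})

test_that("permuting pixel order permutes labels identically", {
  V <- make_block_cube(8L, 6L)
  perm <- sample(nrow(V))
  fit1 <- plsa_fit(V, k = 2, seed = 5)
  fit2 <- plsa_fit(V[perm, ], k = 2, seed = 5)
  lab1 <- label_pixels(fit1)
  lab2 <- label_pixels(fit2)
  # same partition up to topic relabelling
  expect_equal(length(unique(paste(lab1[perm], lab2))),
               length(unique(lab2)))
})

test_that("zero-TIC pixels are dropped and labelled -1; ties go to topic 0", {
  V <- make_block_cube(6L, 5L)
  V[3L, ] <- 0
  fit <- plsa_fit(V, k = 2, seed = 1)
  expect_equal(fit$dropped, 3L)
  expect_equal(label_pixels(fit)[3L], -1L)
  # tie rule: uniform topic distribution labels as topic 0
  fake <- fit
  fake$theta[1L, ] <- 0.5
  expect_equal(label_pixels(fake)[1L], 0L)
  expect_error(plsa_fit(V, k = 0), "k must be")
  expect_error(plsa_fit(V, k = 100), "k must be")
})

test_that("data cube binning aggregates peaks into the right columns", {
  ds <- tiny_dataset(n = 4L)
  pls <- list(
    peak_list_for_test(c(100.01, 100.04), c(5, 7)),   # same 0.1 bin
    peak_list_for_test(c(100.17), c(2)),
    peak_list_for_test(numeric(0), numeric(0)),
    peak_list_for_test(c(104.99), c(9))
  )
  cube <- build_datacube(ds, pls, bin_width = 0.1)
  expect_equal(ncol(cube$matrix), 3L)
  expect_equal(cube$matrix[1L, 1L], 12)   # two peaks summed in one bin
  expect_equal(cube$matrix[2L, 2L], 2)
  expect_equal(sum(cube$matrix[3L, ]), 0)
  expect_error(build_datacube(ds, pls, bin_width = 0), "bin_width")
})

test_that("ROI summed spectra conserve totals and reject empty regions", {
  ds <- tiny_dataset()
  labels <- c(0L, 0L, 1L, 1L)
  r0 <- roi_summed_spectrum(ds, labels, 0L)
  r1 <- roi_summed_spectrum(ds, labels, 1L)
  expect_equal(sum(r0$intensity) + sum(r1$intensity), sum(ds$intensities),
               tolerance = 1e-12)
  single <- roi_summed_spectrum(ds, c(2L, 0L, 0L, 0L), 2L)
  expect_equal(single$intensity, ds$intensities[1L, ])
  whole <- roi_summed_spectrum(ds, rep(0L, 4L), 0L)
  expect_equal(sum(whole$intensity), sum(ds$intensities))
  expect_error(roi_summed_spectrum(ds, labels, 9L), "no pixels")
})
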