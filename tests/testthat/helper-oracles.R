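# Independent brute-force oracles used against the package implementations.

# Enumerate all isotope combinations of n_br bromine atoms explicitly and
# collapse equal-mass states: the oracle for the di-Br triplet.
brute_force_br_pattern <- function(n_br) {
  tab <- isotope_table("Br")
  idx <- expand.grid(rep(list(1:2), n_br))
  mass <- rowSums(matrix(tab$mass[as.matrix(idx)], ncol = n_br))
  ab <- apply(matrix(tab$abundance[as.matrix(idx)], ncol = n_br), 1, prod)
  agg <- tapply(ab, round(mass, 6), sum)
  list(mz = as.numeric(names(agg)), abundance = as.vector(agg))
}

# Naive O(n*w) sliding min/max with edge replication: oracle for the
# morphological opening used by TopHat.
naive_running <- function(x, w, fun) {
  n <- length(x)
  r <- w %/% 2
  vapply(seq_len(n), function(i) {
    fun(x[max(1, i - r):min(n, i + r)])
  }, numeric(1))
}

naive_opening <- function(x, w) {
  naive_running(naive_running(x, w, min), w, max)
}

# hand-summed IUPAC monoisotopic masses (typed independently of the package
# table) for the formulas exercised in tests
HAND_MASSES <- c(
  H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.99491461956,
  S = 31.97207100, Br = 78.9183376, K = 38.96370668, Na = 22.9897692809,
  Cs = 132.905451933, I = 126.904473)
hand_mass <- function(counts) {
  sum(HAND_MASSES[names(counts)] * counts)
}

ibd_of <- function(path) sub("\\.imzML$", ".ibd", path)

peak_list_for_test <- function(mz, intensity) {
  data.frame(mz = mz, intensity = intensity, snr = rep(Inf, length(mz)))
}

# small flat-phantom dataset used by several io/segmentation tests
tiny_dataset <- function(n = 4L, nbins = 200L, seed = 42L) {
  set.seed(seed)
  coords <- cbind(x = rep(0:(n %/% 2 - 1), each = 2), y = rep(0:1, n %/% 2))
  mz <- seq(100, 100 + (nbins - 1) * 0.05, by = 0.05)
  ints <- matrix(runif(n * nbins), nrow = n)
  msi_dataset(coords, mz, ints, pitch_um = 60)
}

# fast screening phantom: small grid, narrow m/z range around the spikes
screen_phantom_run <- function(seed, spike_intensity = 40, rows = 24,
                               cols = 24, noise_sd = 0.5) {
  ph <- make_phantom(rows, cols, "gut-bands", seed = seed)
  sim <- simulate_dataset(
    ph, spikes = default_spikes(spike_intensity),
    noise = noise_model(noise_sd = noise_sd),
    seed = seed)
  sim
}
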