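#' Acquisition noise model for the synthetic generator
#'
#' Emulates TOF acquisition: a slowly varying chemical baseline (exponential
#' decay plus a slow sinusoid), additive Gaussian detector noise, optional
#' signal-dependent shot noise, Gaussian peak shapes whose FWHM grows with
#' sqrt(m/z), and a per-pixel linear mass-error drift in ppm across columns
#' (which the quadratic external calibration is there to absorb).
#'
#' @param baseline_amp Baseline amplitude at the low-m/z end (counts).
#' @param baseline_scale Exponential decay scale in Da.
#' @param wobble_amp,wobble_period Sinusoidal baseline component (counts, Da).
#' @param noise_sd Additive Gaussian noise SD (counts).
#' @param shot Signal-proportional variance factor (0 disables shot noise).
#' @param peak_fwhm Peak FWHM in Da at `fwhm_ref_mz`.
#' @param fwhm_ref_mz Reference m/z for the FWHM model.
#' @param drift_ppm Mass-error drift amplitude: ppm shift runs linearly from
#'   `-drift_ppm` to `+drift_ppm` across pixel columns.
#' @return A `noise_model` list.
#' @export
noise_model <- function(baseline_amp = 20, baseline_scale = 300,
                        wobble_amp = 4, wobble_period = 400,
                        noise_sd = 0.5, shot = 0,
                        peak_fwhm = 0.12, fwhm_ref_mz = 200,
                        drift_ppm = 20) {
  vals <- c(baseline_amp, baseline_scale, wobble_amp, wobble_period,
            noise_sd, shot, peak_fwhm, fwhm_ref_mz)
  if (any(vals < 0)) stop("noise model scales must be >= 0", call. = FALSE)
  structure(list(baseline_amp = baseline_amp, baseline_scale = baseline_scale,
                 wobble_amp = wobble_amp, wobble_period = wobble_period,
                 noise_sd = noise_sd, shot = shot, peak_fwhm = peak_fwhm,
                 fwhm_ref_mz = fwhm_ref_mz, drift_ppm = drift_ppm),
            class = "noise_model")
}

#' Specification of a spiked compound
#'
#' @param formula Molecular formula of the neutral compound, or `NULL` if an
#'   explicit `pattern` is given.
#' @param adduct Adduct label.
#' @param regions Character vector of phantom region names the compound
#'   occupies.
#' @param intensity Mean total area (counts) deposited per pixel; split over
#'   the isotope envelope.
#' @param sigma Log-normal sigma of the per-pixel abundance distribution.
#' @param name Compound name for ground truth.
#' @param pattern Optional explicit [isotope_pattern] overriding `formula`.
#' @return A `spike_spec`.
#' @export
spike_spec <- function(formula, adduct, regions, intensity, sigma = 0.3,
                       name = NULL, pattern = NULL) {
  if (intensity <= 0) stop("spike intensity must be > 0", call. = FALSE)
  if (is.null(pattern)) pattern <- isotope_distribution(formula, adduct)
  if (is.null(name)) name <- paste0(format_formula(parse_formula(formula)),
                                    " ", adduct)
  structure(list(formula = if (is.null(formula)) NA_character_ else formula,
                 adduct = adduct, regions = regions, intensity = intensity,
                 sigma = sigma, name = name, pattern = pattern),
            class = "spike_spec")
}

#' Default spike panel: the brominated indoles of the compound library
#'
#' Five mono- and di-brominated indole species confined to the lumen, the
#' distribution observed for brominated metabolites in the stomach.
#'
#' @param intensity Mean per-pixel area per compound.
#' @param regions Target regions (default `"lumen"`).
#' @return List of [spike_spec]s.
#' @export
default_spikes <- function(intensity = 400, regions = "lumen") {
  list(
    spike_spec("C8H4BrNO2", "[M-H]+", regions, intensity,
               name = "6-bromoisatin [M-H]+"),
    spike_spec("C8H4BrNO2", "[M+K]+", regions, intensity * 0.5,
               name = "6-bromoisatin [M+K]+"),
    spike_spec("C9H6BrNOS", "[M+H]+", regions, intensity * 0.8,
               name = "tyrindoleninone [M+H]+"),
    spike_spec("C16H8Br2N2O2", "[M+H]+", regions, intensity * 0.7,
               name = "dibromoindigo/indirubin [M+H]+"),
    spike_spec("C12H18BrN2O2", "[M]+", regions, intensity * 0.6,
               name = "M3 [M]+")
  )
}

# deposit a Gaussian peak of given area onto the uniform axis; index
# arithmetic exploits the uniform grid (findInterval would re-scan the axis)
.add_gauss <- function(vec, axis, mu, area, sd, dx) {
  lo <- max(1L, as.integer(ceiling((mu - 4 * sd - axis[1L]) / dx)) + 1L)
  hi <- min(length(vec), as.integer(floor((mu + 4 * sd - axis[1L]) / dx)) + 1L)
  if (hi < lo) return(vec)
  idx <- lo:hi
  vec[idx] <- vec[idx] + area * stats::dnorm(axis[idx], mu, sd) * dx
  vec
}

#' Simulate a phantom MSI dataset with ground truth
#'
#' Every pixel's profile is baseline + region-specific lipid background +
#' spiked compound envelopes + noise. Each phantom region is given its own
#' lipid composition (a shared base plus a region-specific boosted subset),
#' which is the statistical structure pLSA segmentation exploits. Ground
#' truth records every spiked isotopologue's theoretical m/z, target regions
#' and mean intensity, plus the lipid table with decoy flags and the label
#' map.
#'
#' @param phantom An [make_phantom] phantom.
#' @param spikes List of [spike_spec]s (default [default_spikes]).
#' @param lipids Lipid table (default [default_lipid_background]); `NULL`
#'   disables the lipid background.
#' @param noise A [noise_model].
#' @param mz_range Acquisition range in Da (default 20-1500).
#' @param pitch_um Pixel pitch (default 60).
#' @param bin Axis bin width in Da (default 0.05, ten samples per Da near the
#'   1.998 Da Br spacing at m/z 225).
#' @param lipid_intensity Mean area per unit composition weight.
#' @param seed Integer seed; a fixed seed gives a bitwise-identical dataset.
#' @return List with `dataset` ([msi_dataset]) and `truth`
#'   (`msi_ground_truth`).
#' @export
simulate_dataset <- function(phantom, spikes = default_spikes(),
                             lipids = default_lipid_background(),
                             noise = noise_model(), mz_range = c(20, 1500),
                             pitch_um = 60, bin = 0.05,
                             lipid_intensity = 30, seed = 1L) {
  stopifnot(inherits(phantom, "msi_phantom"), inherits(noise, "noise_model"))
  region_names <- phantom$region_names
  for (sp in spikes) {
    bad <- setdiff(sp$regions, region_names)
    if (length(bad)) {
      stop("spike '", sp$name, "' targets unknown region '", bad[1L], "'",
           call. = FALSE)
    }
    if (any(sp$pattern$mz < mz_range[1L] | sp$pattern$mz > mz_range[2L])) {
      stop("acquisition range excludes isotopologues of spike '", sp$name,
           "'", call. = FALSE)
    }
  }
  set.seed(seed)
  axis <- seq(mz_range[1L], mz_range[2L], by = bin)
  nbins <- length(axis)
  rows <- nrow(phantom$labels); cols <- ncol(phantom$labels)
  np <- rows * cols
  # pixel order: row-major over the grid, x = column, y = row (0-based)
  coords <- cbind(x = rep(seq_len(cols) - 1L, each = rows),
                  y = rep(seq_len(rows) - 1L, times = cols))
  labels <- phantom$labels[cbind(coords[, "y"] + 1L, coords[, "x"] + 1L)]

  nreg <- length(region_names)
  # region-specific lipid composition: shared base + boosted subset
  if (!is.null(lipids) && nrow(lipids)) {
    ns <- nrow(lipids)
    comp <- matrix(0.3, nrow = nreg, ncol = ns)
    assign_reg <- ((seq_len(ns) - 1L) %% nreg) + 1L
    comp[cbind(assign_reg, seq_len(ns))] <- 5
    # decoy pair members co-located in one region with equal weight
    for (pr in unique(stats::na.omit(lipids$decoy_pair))) {
      idx <- which(lipids$decoy_pair %in% pr)
      reg <- assign_reg[idx[1L]]
      comp[, idx] <- 0
      comp[reg, idx] <- 5
    }
    envs <- lapply(seq_len(ns), function(i) .species_envelope(lipids[i, ]))
  } else {
    ns <- 0L
    comp <- NULL
    envs <- list()
  }

  sdev <- function(mu) {
    noise$peak_fwhm * sqrt(mu / noise$fwhm_ref_mz) / (2 * sqrt(2 * log(2)))
  }
  base_curve <- if (noise$baseline_amp > 0 || noise$wobble_amp > 0) {
    noise$baseline_amp * exp(-(axis - axis[1L]) / noise$baseline_scale) +
      noise$wobble_amp * (1 + sin(2 * pi * (axis - axis[1L]) /
                                    noise$wobble_period)) / 2
  } else NULL

  ppm_of_col <- function(x0) {
    if (cols == 1L) 0 else noise$drift_ppm * (2 * x0 / (cols - 1L) - 1)
  }

  ints <- matrix(0, nrow = np, ncol = nbins)
  for (i in seq_len(np)) {
    v <- numeric(nbins)
    reg <- labels[i]
    drift <- 1 + ppm_of_col(coords[i, "x"]) * 1e-6
    if (ns > 0L) {
      amps <- lipid_intensity * comp[reg, ] *
        stats::rlnorm(ns, -0.3^2 / 2, 0.3)
      for (s in seq_len(ns)) {
        if (comp[reg, s] <= 0) next
        env <- envs[[s]]
        for (j in seq_len(nrow(env))) {
          mu <- env$mz[j] * drift
          v <- .add_gauss(v, axis, mu, amps[s] * env$abundance[j],
                          sdev(mu), bin)
        }
      }
    }
    for (sp in spikes) {
      if (!region_names[reg] %in% sp$regions) next
      amp <- sp$intensity * stats::rlnorm(1, -sp$sigma^2 / 2, sp$sigma)
      for (j in seq_len(nrow(sp$pattern))) {
        mu <- sp$pattern$mz[j] * drift
        v <- .add_gauss(v, axis, mu, amp * sp$pattern$abundance[j],
                        sdev(mu), bin)
      }
    }
    if (!is.null(base_curve)) {
      v <- v + base_curve * stats::rlnorm(1, 0, 0.1)
    }
    if (noise$noise_sd > 0 || noise$shot > 0) {
      sd_i <- sqrt(noise$noise_sd^2 + noise$shot * v)
      v <- pmax(0, v + stats::rnorm(nbins) * sd_i)
    }
    ints[i, ] <- v
  }

  dataset <- msi_dataset(coords, axis, ints, pitch_um = pitch_um,
                         metadata = list(mz_range = mz_range,
                                         polarity = "positive"))
  spike_truth <- do.call(rbind, lapply(spikes, function(sp) {
    data.frame(compound = sp$name,
               formula = sp$formula,
               adduct = sp$adduct,
               mz = sp$pattern$mz,
               abundance = sp$pattern$abundance,
               regions = paste(sp$regions, collapse = ","),
               intensity = sp$intensity * sp$pattern$abundance)
  }))
  truth <- structure(list(spikes = spike_truth, lipids = lipids,
                          labels = labels, label_map = phantom$labels,
                          region_names = region_names,
                          params = list(seed = seed, bin = bin,
                                        mz_range = mz_range, noise = noise)),
                     class = "msi_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Write ground truth to JSON and the label map to plain-text PGM
#'
#' @param truth An `msi_ground_truth`.
#' @param json_path Output JSON path.
#' @param pgm_path Optional output path for the label-map PGM.
#' @return `json_path`, invisibly.
#' @export
write_ground_truth <- function(truth, json_path, pgm_path = NULL) {
  obj <- list(spikes = truth$spikes, lipids = truth$lipids,
              region_names = truth$region_names,
              params = list(seed = truth$params$seed, bin = truth$params$bin,
                            mz_range = truth$params$mz_range))
  jsonlite::write_json(obj, json_path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(pgm_path)) write_pgm(truth$label_map, pgm_path)
  invisible(json_path)
}
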