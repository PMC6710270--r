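#' Run the full screening pipeline
#'
#' Simulates (or accepts) a dataset, preprocesses it, segments it with pLSA,
#' screens each segmented region's summed spectrum for Br isotope
#' signatures, de-replicates lipid look-alikes, groups co-localised
#' candidates, annotates against the compound library and (optionally)
#' writes the report.
#'
#' @param dataset An [msi_dataset], or `NULL` to simulate one from the
#'   config.
#' @param config Configuration list (default [default_config]).
#' @param lipids Lipid mass list used for de-replication (default
#'   [default_lipid_background]).
#' @param library Compound library for annotation.
#' @param report_dir If non-NULL, [write_report] output directory.
#' @return List with `dataset`, `truth` (when simulated), `model` (pLSA),
#'   `labels`, `candidates`, `groups`, `annotations`.
#' @export
run_pipeline <- function(dataset = NULL, config = default_config(),
                         lipids = default_lipid_background(),
                         library = read_compound_library(),
                         report_dir = NULL) {
  truth <- NULL
  if (is.null(dataset)) {
    sim <- config$simulate
    ph <- make_phantom(sim$rows, sim$cols, sim$layout,
                       n_regions = sim$n_regions, seed = config$seed)
    out <- simulate_dataset(ph, spikes = default_spikes(sim$spike_intensity),
                            lipids = lipids, mz_range = sim$mz_range,
                            pitch_um = sim$pitch_um, bin = sim$bin,
                            lipid_intensity = sim$lipid_intensity,
                            seed = config$seed)
    dataset <- out$dataset
    truth <- out$truth
  }
  pp <- preprocess_dataset(dataset,
                           tophat_window = config$preprocess$tophat_window,
                           snr_min = config$preprocess$snr_min,
                           noise_window = config$preprocess$noise_window)
  cube <- build_datacube(pp$dataset, pp$peaks,
                         bin_width = config$segment$bin_width)
  model <- plsa_fit(cube, k = config$segment$k, seed = config$seed,
                    max_iter = config$segment$max_iter,
                    tol = config$segment$tol,
                    n_restarts = config$segment$n_restarts)
  labels <- label_pixels(model)

  cands <- list()
  for (r in sort(unique(labels[labels >= 0L]))) {
    roi_spec <- roi_summed_spectrum(pp$dataset, labels, r)
    pk <- pick_peaks(roi_spec, snr_min = config$screen$roi_snr_min,
                     noise_window = config$preprocess$noise_window)
    cands[[length(cands) + 1L]] <-
      find_halogen_signatures(pk, tol_mz = config$screen$tol_mz,
                              score_min = config$screen$score_min,
                              roi = as.character(r))
  }
  candidates <- do.call(rbind, c(cands, list(empty_br_candidates())))
  candidates <- dereplicate_lipids(candidates, lipids,
                                   tol_mz = config$screen$dereplicate_tol)
  groups <- if (nrow(candidates)) {
    colocalization_groups(candidates, pp$dataset,
                          r_min = config$annotate$r_min,
                          tol = config$screen$tol_mz)
  } else integer(0)
  annotations <- annotate_candidates(candidates, library = library,
                                     tol_ppm = config$annotate$tol_ppm)
  if (!is.null(report_dir)) {
    write_report(candidates, annotations, pp$dataset, dir = report_dir,
                 groups = groups, tol = config$screen$tol_mz)
  }
  list(dataset = pp$dataset, truth = truth, model = model, labels = labels,
       candidates = candidates, groups = groups, annotations = annotations)
}
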