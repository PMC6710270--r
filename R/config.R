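#' Default pipeline configuration
#'
#' All tunable tolerances, thresholds and seeds of the pipeline in one nested
#' list, mirrored by the YAML config file consumed by the command-line
#' entry point.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(rows = 64L, cols = 64L, layout = "gut-bands",
                    n_regions = 6L, pitch_um = 60, bin = 0.05,
                    mz_range = c(20, 1500), spike_intensity = 400,
                    lipid_intensity = 30),
    preprocess = list(tophat_window = 5, snr_min = 5, noise_window = 101L),
    segment = list(k = 6L, bin_width = 0.1, max_iter = 500L, tol = 1e-6,
                   n_restarts = 5L),
    screen = list(tol_mz = 0.05, score_min = 0.95, roi_snr_min = 5,
                  dereplicate_tol = 0.15),
    # 200 ppm is the DIOS/TOF-grade annotation tolerance (0.05 Da profile
    # bins limit centroid accuracy); drop to 10 ppm for exact-mass peak lists
    annotate = list(tol_ppm = 200, r_min = 0.7)
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys fall back to [default_config]
#' values.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  def <- default_config()
  merge_section <- function(d, u, where) {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown)) {
      stop("unknown config key", if (nzchar(where)) paste0(" in ", where),
           ": ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]])) {
        merge_section(d[[k]], u[[k]], paste0(where, if (nzchar(where)) ".", k))
      } else u[[k]]
    }
    d
  }
  merge_section(def, user, "")
}
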