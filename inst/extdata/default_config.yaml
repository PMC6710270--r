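# bromsi pipeline configuration: all tolerances and seeds in one place.
seed: 1
simulate:
  rows: 64
  cols: 64
  layout: gut-bands
  n_regions: 6
  pitch_um: 60
  bin: 0.05
  mz_range: [20, 1500]
  spike_intensity: 400
  lipid_intensity: 30
preprocess:
  tophat_window: 5      # Da; >> TOF peak width, << baseline undulation
  snr_min: 5
  noise_window: 101     # bins, sliding MAD noise estimate
segment:
  k: 6                  # topics; mirrors the six histological gut layers
  bin_width: 0.1        # Da, peak binning for the pLSA data cube
  max_iter: 500
  tol: 1.0e-6
  n_restarts: 5
screen:
  tol_mz: 0.05          # Da; TOF-scale partner matching
  score_min: 0.95       # cosine vs Br template
  roi_snr_min: 5
  dereplicate_tol: 0.15 # Da; ~half peak FWHM in lipid range, absorbs overlap-pulled centroids
annotate:
  tol_ppm: 200          # DIOS/TOF-grade; use 10 for exact-mass peak lists
  r_min: 0.7            # spatial correlation threshold for grouping
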