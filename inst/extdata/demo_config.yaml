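# Demo configuration for protoconn::run_pipeline(): a small synthetic
# two-hemisphere study that exercises every stage in a few seconds.
out_dir: protoconn-demo
seed: 1
synth:
  n_voxels_per_area: 16
  n_ecc_bands: 8
  n_runs: 2
  run_len: 150
  tr_s: 2
coupling:
  homotopic_gain: 0.9
  adjacent_r: 0.5
  distal_r: 0.1
  quadrant_mismatch: 0.6
  gradient_width: 1.5
  noise_sd: 1
  ar1: 0.3
  smooth_fwhm_mm: 0
preprocess:
  n_trim: 5
  sd_thresh: 2.5
  f_low: 0.01
  f_high: 0.1
connectivity:
  n_iter: 20
  r_thresh: 0.15
eccentricity:
  n_bins: 8
  max_ecc: 10
  f_thresh: 20
structure:
  cutoff_inconsistency: 1
nullsim:
  n_reps: 3
  fwhm_mm: 3.5
  run_len: 100
phasemap:
  cycles_per_run: 8
  run_len: 160
  lag_s: 4
  snr: 2
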