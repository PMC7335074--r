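# Shared fixtures: a compact two-condition design for cheap simulations and
# a minimal probe, all built in code.

small_design <- function(run_duration = 60) {
  design_spec(
    conditions = c("taskA", "taskB"),
    trials_per_condition = 2,
    trial_duration = 2,
    isi_range = c(2, 17),
    initial_baseline = 5,
    n_runs = 1,
    run_duration = run_duration,
    sampling_rate = 25
  )
}

# one source with two long detectors and a short detector, plus a second
# source; enough to exercise channel classification and the MBLL
small_probe <- function() {
  opt <- tibble::tibble(
    optode = 1:6,
    role = c("source", "source", "detector", "detector", "detector",
             "detector"),
    x = c(0, 3, 3, 0, 0.8, 6),
    y = c(0, 3, 0, 3, 0, 3),
    z = 0,
    hemisphere = "left"
  )
  probe_layout(opt)
}

# truth with every nuisance disabled: pure condition-locked responses
quiet_truth <- function(layout, spec, ...) {
  truth_params(
    layout, spec,
    physiology = NULL, superficial_amp = 0, drift_amp = 0,
    n_spikes = 0, n_shifts = 0, noise_sd_frac = 0,
    subject_gain_sd = 0, cond_mod_sd = 0, region_mod_sd = 0,
    resid_amp_sd = 0, ...
  )
}

center_cols <- function(m) sweep(m, 2, colMeans(m))
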