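#' Event-related design specification
#'
#' Parameters of one acquisition run: five task conditions (execution and
#' observation of a simple and a complex hand action, plus a visual control),
#' seven trials per condition per run, 4 s trials, inter-stimulus intervals
#' drawn from 2-17 s, a 15 s initial baseline, and a 350 s total run, sampled
#' at 25 Hz. These defaults reproduce the standard event-related protocol for
#' this task; all are overridable.
#'
#' @param conditions Character vector of condition labels.
#' @param trials_per_condition Trials per condition per run.
#' @param trial_duration Trial length (s).
#' @param isi_range Length-2 numeric, admissible inter-stimulus interval (s).
#'   The interval after the last trial (to the end of the run) counts as an
#'   ISI too, so a run holds exactly `n_trials` ISIs.
#' @param initial_baseline Rest period before the first trial (s).
#' @param n_runs Number of runs per subject.
#' @param run_duration Total run length (s).
#' @param sampling_rate Acquisition rate (Hz).
#' @return A `nirs_design` list.
#' @export
design_spec <- function(conditions = c("exec_simple", "exec_complex",
                                       "obs_simple", "obs_complex", "control"),
                        trials_per_condition = 7,
                        trial_duration = 4,
                        isi_range = c(2, 17),
                        initial_baseline = 15,
                        n_runs = 3,
                        run_duration = 350,
                        sampling_rate = 25) {
  if (trial_duration <= 0 || run_duration <= 0 || sampling_rate <= 0 ||
      initial_baseline < 0) {
    abort("durations and sampling rate must be positive",
          class = "nirsflow_config_error")
  }
  if (isi_range[1] > isi_range[2]) {
    abort("isi_range must be non-decreasing", class = "nirsflow_config_error")
  }
  n_trials <- length(conditions) * trials_per_condition
  isi_budget <- run_duration - initial_baseline - n_trials * trial_duration
  if (isi_budget < n_trials * isi_range[1] - 1e-9) {
    abort(sprintf(
      "infeasible design: ISI budget %.3f s is below the minimum %g x %g = %g s",
      isi_budget, n_trials, isi_range[1], n_trials * isi_range[1]),
      class = "nirsflow_config_error")
  }
  if (isi_budget > n_trials * isi_range[2] + 1e-9) {
    abort(sprintf(
      "infeasible design: ISI budget %.3f s exceeds the maximum %g x %g = %g s",
      isi_budget, n_trials, isi_range[2], n_trials * isi_range[2]),
      class = "nirsflow_config_error")
  }
  structure(list(
    conditions = conditions,
    trials_per_condition = trials_per_condition,
    trial_duration = trial_duration,
    isi_range = isi_range,
    initial_baseline = initial_baseline,
    n_runs = n_runs,
    run_duration = run_duration,
    sampling_rate = sampling_rate,
    n_trials = n_trials,
    isi_budget = isi_budget
  ), class = "nirs_design")
}

#' @export
print.nirs_design <- function(x, ...) {
  cat("<nirs_design> ", length(x$conditions), " conditions x ",
      x$trials_per_condition, " trials, ", x$trial_duration, " s trials, ISI [",
      x$isi_range[1], ", ", x$isi_range[2], "] s, ", x$n_runs, " runs of ",
      x$run_duration, " s @ ", x$sampling_rate, " Hz\n", sep = "")
  invisible(x)
}

# draw n ISIs uniform in [lo, hi], rescale to sum `total`, then
# clip-and-redistribute until every ISI respects the bounds and the sum is
# exact (water-filling over the unclipped entries)
draw_isis <- function(n, lo, hi, total) {
  isi <- runif(n, lo, hi)
  isi <- isi * total / sum(isi)
  for (iter in 1:100) {
    isi <- pmin(pmax(isi, lo), hi)
    deficit <- total - sum(isi)
    if (abs(deficit) < 1e-12) break
    if (deficit > 0) {
      room <- hi - isi
      free <- room > 1e-12
      isi[free] <- isi[free] + deficit * room[free] / sum(room[free])
    } else {
      room <- isi - lo
      free <- room > 1e-12
      isi[free] <- isi[free] + deficit * room[free] / sum(room[free])
    }
  }
  # absorb any float residue in an interior entry
  resid <- total - sum(isi)
  k <- which(isi + resid >= lo & isi + resid <= hi)[1]
  isi[k] <- isi[k] + resid
  isi
}

#' Generate a pseudo-randomized run schedule
#'
#' Draws trial onsets for one run: condition order is a seeded random
#' permutation balanced within the run, and the `n_trials` inter-stimulus
#' intervals are drawn uniformly from `isi_range` and rescaled (with
#' clip-and-redistribute) so that baseline + trials + ISIs fill the run
#' exactly.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed controlling condition order and ISIs.
#' @param run_id Run index stored with the schedule.
#' @return A `nirs_schedule`: list with `events` (tibble: `condition`,
#'   `onset`, `duration`), `run_id` and the generating `spec`.
#' @examples
#' sch <- generate_schedule(design_spec(), seed = 1)
#' nrow(sch$events)   # 35 trials
#' @export
generate_schedule <- function(spec, seed, run_id = 1L) {
  stopifnot(inherits(spec, "nirs_design"))
  n <- spec$n_trials
  out <- with_seed(seed, {
    cond <- sample(rep(spec$conditions, spec$trials_per_condition))
    isi <- draw_isis(n, spec$isi_range[1], spec$isi_range[2], spec$isi_budget)
    list(cond = cond, isi = isi)
  })
  # onset_k = baseline + (k-1) trials + first k-1 ISIs; the n-th ISI runs out
  # to the end of the run
  onsets <- spec$initial_baseline +
    (seq_len(n) - 1) * spec$trial_duration +
    c(0, cumsum(out$isi))[seq_len(n)]
  events <- tibble(condition = out$cond, onset = onsets,
                   duration = spec$trial_duration)
  structure(list(events = events, isi = out$isi, run_id = run_id, spec = spec,
                 seed = seed),
            class = "nirs_schedule")
}

#' @export
print.nirs_schedule <- function(x, ...) {
  cat("<nirs_schedule> run ", x$run_id, ": ", nrow(x$events), " events over ",
      x$spec$run_duration, " s\n", sep = "")
  invisible(x)
}

#' @rdname generate_schedule
#' @param x A `nirs_schedule`.
#' @param ... Unused.
#' @export
tidy.nirs_schedule <- function(x, ...) {
  dplyr::mutate(x$events, run_id = x$run_id)
}
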