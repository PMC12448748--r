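#' Write a simulated cohort to plain-text files
#'
#' Writes `spikes.csv` (unit_id, spike_time_s), `trials.csv`,
#' `ground_truth.csv` and a `params.json` sidecar recording the generation
#' parameters (including the seed) to a directory.
#'
#' @param cohort A `tbs_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulated_data <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tbs_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spikes <- do.call(rbind, lapply(cohort$units, function(u) {
    if (length(u$spike_times))
      data.frame(unit_id = u$unit_id, spike_time_s = u$spike_times)
  }))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$schedule),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  prot <- attr(cohort$schedule, "protocol")
  jsonlite::write_json(
    list(seed = cohort$seed, n_units = length(cohort$units),
         n_trials = nrow(cohort$schedule), protocol = unclass(prot)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read spike and trial tables written by [write_simulated_data()]
#'
#' @param dir Directory containing `spikes.csv` and `trials.csv`.
#' @return List with `units` (list of `unit_record`s, no waveforms),
#'   `schedule` (a `trial_schedule` with the protocol restored from
#'   `params.json` when present).
#' @export
read_simulated_data <- function(dir) {
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  class(trials) <- c("trial_schedule", "data.frame")
  pj <- file.path(dir, "params.json")
  if (file.exists(pj)) {
    p <- jsonlite::read_json(pj, simplifyVector = TRUE)$protocol
    attr(trials, "protocol") <- stim_protocol(
      train_duration = p$train_duration, n_bursts = p$n_bursts,
      burst_rate = p$burst_rate, pulse_rate = p$pulse_rate,
      duty_cycle = p$duty_cycle, amplitude = p$amplitude)
  }
  units <- lapply(split(spikes$spike_time_s, spikes$unit_id), sort)
  units <- lapply(names(units), function(id)
    unit_record(id, spike_times = units[[id]]))
  list(units = units, schedule = trials)
}

#' Write a modulation analysis results table
#'
#' Long-format CSV of every contrast tested (unit, region, condition,
#' contrast, W, permutation p, significance, direction, effect sizes).
#'
#' @param analysis A `modulation_analysis` from [analyze_units()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_modulation_results <- function(analysis, path) {
  utils::write.csv(analysis$contrasts, path, row.names = FALSE)
  invisible(path)
}
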