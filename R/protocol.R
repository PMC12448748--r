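#' Theta-burst stimulation protocol
#'
#' Describes one 1 s train of intracranial theta-burst stimulation (TBS):
#' high-frequency pulses (default 50 Hz) nested within equally spaced bursts
#' repeated at a theta rate (default 8 bursts over 1 s, ~8 Hz), with a duty
#' cycle giving the fraction of each burst period during which pulses are
#' delivered.
#'
#' @param train_duration Train length in seconds.
#' @param n_bursts Number of bursts in the train.
#' @param burst_rate Burst repetition rate in Hz. Defaults to
#'   `n_bursts / train_duration` (equally spaced bursts filling the train).
#' @param pulse_rate Within-burst pulse rate in Hz (50; variants 33, 80).
#' @param duty_cycle Fraction of each burst period during which pulses are
#'   delivered, in (0, 1].
#' @param amplitude Current amplitude in mA (descriptive only).
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' tbs_pulse_train(p)
#' @export
stim_protocol <- function(train_duration = 1, n_bursts = 8,
                          burst_rate = n_bursts / train_duration,
                          pulse_rate = 50, duty_cycle = 0.5, amplitude = 1) {
  stopifnot(train_duration > 0, n_bursts >= 1)
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty_cycle must be in (0, 1]")
  if (pulse_rate <= burst_rate)
    stop("pulse_rate must exceed burst_rate")
  if (n_bursts / burst_rate > train_duration + 1e-9)
    stop("n_bursts / burst_rate exceeds train_duration: bursts do not fit")
  structure(
    list(train_duration = train_duration, n_bursts = as.integer(n_bursts),
         burst_rate = burst_rate, pulse_rate = pulse_rate,
         duty_cycle = duty_cycle, amplitude = amplitude),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "TBS protocol: %d bursts at %.3g Hz, %.3g Hz pulses, %.0f%% duty, %.2g mA, %.3g s train\n",
    x$n_bursts, x$burst_rate, x$pulse_rate, 100 * x$duty_cycle,
    x$amplitude, x$train_duration))
  invisible(x)
}

#' Named protocol variants used in the experiments
#'
#' @param name One of `"default"` (1 mA, 50 Hz), `"lowamp"` (0.5 mA, 50 Hz),
#'   `"freq33"` (33 Hz pulses), `"freq80"` (80 Hz pulses).
#' @return A `stim_protocol`.
#' @export
protocol_variant <- function(name = c("default", "lowamp", "freq33", "freq80")) {
  switch(match.arg(name),
         default = stim_protocol(),
         lowamp  = stim_protocol(amplitude = 0.5),
         freq33  = stim_protocol(pulse_rate = 33),
         freq80  = stim_protocol(pulse_rate = 80))
}

#' Pulse onset times of a TBS train
#'
#' Burst `k` (0-based) starts at `k / burst_rate`; within each burst, pulses
#' are placed at the pulse period for the duty-cycle on-window
#' (`duty_cycle / burst_rate`). With the default protocol this yields 4
#' pulses per burst at 0, 20, 40, 60 ms offsets, 32 pulses in total, all
#' within the 1 s train.
#'
#' @param protocol A [stim_protocol()].
#' @return Numeric vector of pulse onset times in seconds, in `[0,
#'   train_duration)`.
#' @export
tbs_pulse_train <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  burst_period <- 1 / protocol$burst_rate
  on_window <- protocol$duty_cycle * burst_period
  pulse_period <- 1 / protocol$pulse_rate
  if (on_window < pulse_period)
    warning("duty on-window shorter than one pulse period; one pulse per burst")
  n_pulses <- max(1L, floor(on_window / pulse_period - 1e-9) + 1L)
  offsets <- (seq_len(n_pulses) - 1L) * pulse_period
  onsets <- rep((seq_len(protocol$n_bursts) - 1L) * burst_period,
                each = n_pulses) + offsets
  onsets[onsets < protocol$train_duration - 1e-12]
}
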