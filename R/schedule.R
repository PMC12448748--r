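#' Build a randomized trial schedule
#'
#' One trial is a 3 s image presentation followed by an ~6 s interstimulus
#' interval (fixation). On half of the trials (randomly interleaved) a 1 s
#' TBS train starts at the moment the image is removed from the screen; the
#' other half are no-stimulation (image-only) trials. Condition counts differ
#' by at most one when `n_trials` is odd.
#'
#' @param n_trials Number of trials (>= 2; sessions in the emulated
#'   experiments used 160 or 320).
#' @param protocol A [stim_protocol()] attached to stim trials.
#' @param isi_mean Mean interstimulus interval in seconds (>= 2 so that
#'   consecutive peri-stimulation epochs cannot overlap).
#' @param jitter Half-width of the uniform ISI jitter in seconds.
#' @param image_duration Image presentation time in seconds.
#' @param seed Optional integer seed; identical seeds give identical
#'   schedules.
#' @return A data frame of class `trial_schedule` with columns
#'   `trial_index`, `image_onset`, `image_offset`, `condition`
#'   (`"stim"`/`"no_stim"`), `stim_onset` (`NA` on no-stim trials) and
#'   `isi_to_next`, ordered and non-overlapping in time, with the protocol
#'   stored as an attribute.
#' @export
build_trial_schedule <- function(n_trials, protocol = stim_protocol(),
                                 isi_mean = 6, jitter = 0.5,
                                 image_duration = 3, seed = NULL) {
  if (!is.numeric(n_trials) || n_trials < 2)
    stop("n_trials must be at least 2")
  n_trials <- as.integer(n_trials)
  if (isi_mean < 2)
    stop("isi_mean below 2 s: peri-stimulation epochs of consecutive trials would overlap")
  if (jitter < 0 || jitter > isi_mean - 2)
    stop("jitter must be in [0, isi_mean - 2]")
  if (!is.null(seed)) set.seed(seed)

  condition <- sample(rep_len(c("stim", "no_stim"), n_trials))
  isi <- stats::runif(n_trials, isi_mean - jitter, isi_mean + jitter)
  # first ISI places the first trial late enough for its 1 s PRE window
  image_onset <- cumsum(c(isi[n_trials], image_duration + isi[-n_trials]))
  image_offset <- image_onset + image_duration
  stim_onset <- ifelse(condition == "stim", image_offset, NA_real_)

  out <- data.frame(trial_index = seq_len(n_trials),
                    image_onset = image_onset,
                    image_offset = image_offset,
                    condition = condition,
                    stim_onset = stim_onset,
                    isi_to_next = isi)
  attr(out, "protocol") <- protocol
  attr(out, "image_duration") <- image_duration
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("Trial schedule: %d trials (%d stim, %d no-stim), %.1f-%.1f s\n",
              nrow(x), sum(x$condition == "stim"),
              sum(x$condition == "no_stim"),
              min(x$image_onset), max(x$image_offset)))
  NextMethod()
}

#' Session span covered by a schedule
#'
#' Runs from time 0 to 1 s past the end of the last trial's post-stimulation
#' epoch.
#'
#' @param schedule A [build_trial_schedule()] result.
#' @return Length-2 numeric `c(0, end)` in seconds.
#' @export
session_span <- function(schedule) {
  c(0, max(schedule$image_offset) + 3)
}
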