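#' Peri-stimulation epoch windows
#'
#' Four 1 s half-open analysis windows per trial, anchored to t0 =
#' image offset (= stimulation onset on stim trials):
#' PRE `[image_onset - 1, image_onset)` (final second of the preceding
#' interstimulus interval), IMG `[image_onset, image_onset + 1)`,
#' DUR `[t0, t0 + 1)` and POST `[t0 + 1, t0 + 2)`. Identical construction
#' for stim and no-stim trials.
#'
#' @param schedule A [build_trial_schedule()] result (or any data frame with
#'   `image_onset` and `image_offset` columns, offset = onset + 3).
#' @return Data frame with one row per trial x epoch: `trial_index`,
#'   `condition`, `epoch` (factor PRE/IMG/DUR/POST), `start`, `end`.
#' @export
epoch_windows <- function(schedule) {
  stopifnot(all(c("image_onset", "image_offset") %in% names(schedule)))
  if (any(abs(schedule$image_offset - schedule$image_onset - 3) > 1e-9))
    stop("image_offset must equal image_onset + 3 s")
  on <- schedule$image_onset
  t0 <- schedule$image_offset
  starts <- cbind(PRE = on - 1, IMG = on, DUR = t0, POST = t0 + 1)
  # a trial's PRE must not overlap the preceding trial's POST
  if (nrow(schedule) > 1 &&
      any(starts[-1, "PRE"] < starts[-nrow(schedule), "POST"] + 1))
    stop("schedule invalid: PRE window overlaps preceding trial's POST window")
  out <- data.frame(
    trial_index = rep(schedule$trial_index %||% seq_len(nrow(schedule)), 4),
    condition = rep(schedule$condition %||% NA_character_, 4),
    epoch = factor(rep(colnames(starts), each = nrow(schedule)),
                   levels = epoch_levels()),
    start = as.vector(starts))
  out$end <- out$start + 1
  out[order(out$trial_index, out$epoch), , drop = FALSE]
}

epoch_levels <- function() c("PRE", "IMG", "DUR", "POST")

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of spike times strictly below each value in x (spikes sorted)
n_spikes_before <- function(x, spikes) {
  findInterval(x, spikes, left.open = TRUE)
}

#' Count spikes per trial and epoch
#'
#' Counts spikes of one unit in each of the four 1 s peri-stimulation
#' epochs of every trial of the requested condition. Windows are half-open
#' `[start, end)`: a spike exactly at a window start belongs to that window.
#'
#' @param unit A `unit_record` (see [unit_record()]) or a sorted numeric
#'   vector of spike times in seconds.
#' @param schedule A [build_trial_schedule()] result.
#' @param condition `"stim"`, `"no_stim"`, or `"both"`.
#' @return Object of class `epoch_counts`: list with `counts` (trials x 4
#'   integer matrix, columns PRE/IMG/DUR/POST), `trial_index`, `condition`,
#'   `unit_id`.
#' @export
count_spikes <- function(unit, schedule, condition = c("both", "stim", "no_stim")) {
  condition <- match.arg(condition)
  st <- if (inherits(unit, "unit_record")) unit$spike_times else as.numeric(unit)
  if (is.unsorted(st)) stop("spike times must be sorted ascending")
  keep <- if (condition == "both") rep(TRUE, nrow(schedule))
          else schedule$condition == condition
  sub <- schedule[keep, , drop = FALSE]
  win <- epoch_windows(sub)
  n <- sum(keep)
  cm <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, epoch_levels()))
  cnt <- n_spikes_before(win$end, st) - n_spikes_before(win$start, st)
  cm[cbind(match(win$trial_index, sub$trial_index),
           as.integer(win$epoch))] <- as.integer(cnt)
  structure(list(counts = cm, trial_index = sub$trial_index,
                 condition = condition,
                 unit_id = if (inherits(unit, "unit_record")) unit$unit_id else NA),
            class = "epoch_counts")
}

#' @export
print.epoch_counts <- function(x, ...) {
  cat(sprintf("Epoch counts: unit %s, %s trials (n = %d)\n",
              format(x$unit_id), x$condition, nrow(x$counts)))
  print(utils::head(x$counts, 5))
  invisible(x)
}

#' Trial-averaged baseline firing rate
#'
#' Mean of the PRE (final pre-trial ISI second) spike counts across trials,
#' divided by the 1 s window length. By default both conditions are pooled,
#' maximizing the number of trials contributing to the estimate; set
#' `condition` to restrict.
#'
#' @inheritParams count_spikes
#' @return Baseline rate in Hz.
#' @export
baseline_rate <- function(unit, schedule, condition = "both") {
  ec <- count_spikes(unit, schedule, condition)
  if (nrow(ec$counts) < 1) stop("at least one trial required")
  mean(ec$counts[, "PRE"]) / 1
}

#' Baseline-rate inclusion filter
#'
#' Units with trial-averaged baseline firing below the threshold are
#' excluded from modulation analyses because sparse firing limits the power
#' to detect modulation.
#'
#' @param baseline_rates Named or unnamed numeric vector of per-unit
#'   baseline rates in Hz.
#' @param threshold Inclusion threshold in Hz (default 0.1).
#' @return List with `included` (logical vector), `n_total`, `n_excluded`,
#'   and `pct_excluded` (percent, 1 decimal place as reported).
#' @export
include_units <- function(baseline_rates, threshold = 0.1) {
  if (threshold < 0) stop("threshold must be non-negative")
  inc <- baseline_rates >= threshold
  list(included = inc,
       n_total = length(inc),
       n_excluded = sum(!inc),
       pct_excluded = proportion_pct(sum(!inc), length(inc)))
}

#' Percentage with the pipeline's reporting convention
#'
#' `100 * k / n` rounded to one decimal place; all proportions in summary
#' tables and reports are formatted through this helper.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return Percentage rounded to 1 d.p.
#' @export
proportion_pct <- function(k, n) round(100 * k / n, 1)

#' Smoothed trial-averaged firing rate
#'
#' Bins spikes (aligned per trial to a common window), averages the binned
#' counts across trials, and convolves with a unit-area Gaussian kernel.
#' Symmetric (reflective) edge padding preserves the total spike mass, so
#' the integral of the trace times the bin width equals the mean spike count
#' per trial in the window.
#'
#' @param trial_spikes List of numeric vectors: spike times per trial,
#'   already aligned to the window reference (see [align_trials()]).
#' @param window Length-2 numeric window `c(from, to)` in aligned seconds.
#' @param bin Bin width in seconds (default 0.1).
#' @param kernel_sd Gaussian kernel SD in seconds (default 0.1, matching the
#'   bin width).
#' @return Data frame with `time` (bin centers) and `rate` (Hz).
#' @export
smoothed_rate <- function(trial_spikes, window, bin = 0.1, kernel_sd = 0.1) {
  if (length(window) != 2 || diff(window) <= 0) stop("window must be non-empty")
  if (kernel_sd <= 0) stop("kernel_sd must be positive")
  breaks <- seq(window[1], window[2], by = bin)
  if (breaks[length(breaks)] < window[2]) breaks <- c(breaks, window[2])
  centers <- utils::head(breaks, -1) + diff(breaks) / 2
  n_trials <- length(trial_spikes)
  acc <- rep(0, length(centers))
  for (st in trial_spikes) {
    st <- st[st >= window[1] & st < window[2]]
    if (length(st))
      acc <- acc + tabulate(findInterval(st, breaks, rightmost.closed = FALSE),
                            nbins = length(centers))
  }
  mean_counts <- acc / max(n_trials, 1)
  half <- ceiling(4 * kernel_sd / bin)
  kern <- stats::dnorm(seq(-half, half) * bin, sd = kernel_sd)
  kern <- kern / sum(kern)
  if (half > length(mean_counts))
    stop("window too short for the requested kernel_sd")
  # reflective padding conserves total mass under a symmetric kernel
  padded <- c(rev(mean_counts[seq_len(half)]), mean_counts,
              rev(mean_counts)[seq_len(half)])
  sm <- stats::filter(padded, kern, sides = 2)
  sm <- sm[(half + 1):(half + length(mean_counts))]
  data.frame(time = centers, rate = as.numeric(sm) / bin)
}

#' Align spike times to a per-trial reference
#'
#' @param spike_times Sorted numeric spike times in seconds.
#' @param schedule A [build_trial_schedule()] result.
#' @param t0 Reference event per trial: `"image_offset"` (stimulation onset
#'   on stim trials) or `"image_onset"`.
#' @param window Window around the reference, in seconds, spikes outside are
#'   dropped.
#' @param condition Restrict to one condition, or `"both"`.
#' @return List of per-trial aligned spike-time vectors.
#' @export
align_trials <- function(spike_times, schedule,
                         t0 = c("image_offset", "image_onset"),
                         window = c(-4, 2), condition = "both") {
  t0 <- match.arg(t0)
  keep <- if (condition == "both") rep(TRUE, nrow(schedule))
          else schedule$condition == condition
  refs <- schedule[[t0]][keep]
  lapply(refs, function(r) {
    st <- spike_times - r
    st[st >= window[1] & st < window[2]]
  })
}
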