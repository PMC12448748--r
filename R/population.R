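#' Pseudo-population firing-rate matrix
#'
#' Pools units (across sessions/subjects) into one matrix of z-scored,
#' trial-averaged firing rates: rows are units, columns are time bins
#' spanning -3 to +2 s around t0 (= image offset / stimulation onset), with
#' one block per condition concatenated along the time axis. Each unit row
#' is z-scored across the concatenated axis so both conditions share a
#' scale; zero-variance units are dropped and reported.
#'
#' @param units List of `unit_record`s or spike-time vectors.
#' @param schedule A [build_trial_schedule()] shared trial template.
#' @param conditions Condition blocks to concatenate (default stim then
#'   no-stim).
#' @param bin Bin width in seconds (default 0.1).
#' @param window Time window around t0 (default `c(-3, 2)`).
#' @return List of class `pseudo_population`: `matrix` (units x concatenated
#'   bins), `time` (bin centers, per block), `condition` (block label per
#'   column), `unit_ids`, `dropped`.
#' @export
pseudo_population_matrix <- function(units, schedule,
                                     conditions = c("stim", "no_stim"),
                                     bin = 0.1, window = c(-3, 2)) {
  breaks <- seq(window[1], window[2], by = bin)
  centers <- utils::head(breaks, -1) + bin / 2
  nb <- length(centers)
  rows <- lapply(units, function(u) {
    st <- if (inherits(u, "unit_record")) u$spike_times else as.numeric(u)
    unlist(lapply(conditions, function(cond) {
      tr <- align_trials(st, schedule, t0 = "image_offset", window = window,
                         condition = cond)
      acc <- rep(0, nb)
      for (s in tr)
        if (length(s))
          acc <- acc + tabulate(findInterval(s, breaks), nbins = nb)
      acc / length(tr) / bin
    }))
  })
  m <- do.call(rbind, rows)
  ids <- vapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (inherits(u, "unit_record")) as.character(u$unit_id) else sprintf("u%03d", i)
  }, character(1))
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("no units with non-zero rate variance")
  mz <- t(scale(t(m[keep, , drop = FALSE])))
  structure(list(matrix = mz,
                 time = rep(centers, length(conditions)),
                 condition = rep(conditions, each = nb),
                 unit_ids = ids[keep], dropped = ids[!keep]),
            class = "pseudo_population")
}

#' PCA trajectories of pseudo-population activity
#'
#' Principal component analysis of the pseudo-population matrix, treating
#' time bins as observations and units as variables, yielding low-
#' dimensional time courses of population coactivity per condition block.
#'
#' @param pop A `pseudo_population` (or a plain units x bins matrix).
#' @param n_components Components to return (default 3; reduced with a
#'   warning when the matrix rank is lower).
#' @return List of class `pca_trajectories`: `scores` (data frame with
#'   `time`, `condition` and PC columns), `explained_variance` (fractions),
#'   `loadings` (units x components), `n_components`.
#' @export
pca_trajectories <- function(pop, n_components = 3) {
  m <- if (inherits(pop, "pseudo_population")) pop$matrix else as.matrix(pop)
  x <- t(m)                                   # time bins x units
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank < n_components) {
    warning(sprintf("matrix rank %d < %d requested components", rank,
                    n_components))
    n_components <- rank
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as.data.frame(pc$x[, seq_len(n_components), drop = FALSE])
  if (inherits(pop, "pseudo_population")) {
    scores <- cbind(data.frame(time = pop$time, condition = pop$condition),
                    scores)
  }
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(n_components)],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 n_components = n_components, prcomp = pc),
            class = "pca_trajectories")
}

#' Spike-time autocorrelogram within an epoch
#'
#' Histogram of all within-trial pairwise spike-time differences between
#' distinct spikes inside the epoch window, summed over trials and
#' normalized to a maximum of 1. The central (zero-lag) bin is excluded from
#' the peak search; self-pairs never contribute by construction. Intended
#' for units with mean rate of at least 1 Hz (sparser trains give noisy
#' estimates).
#'
#' @param trial_spikes List of per-trial spike-time vectors (absolute or
#'   trial-aligned seconds).
#' @param epoch_window Length-2 window applied per trial, or NULL to use
#'   all supplied spikes.
#' @param bin Bin width in seconds (default 0.005).
#' @param max_lag Maximum lag in seconds (default 0.25).
#' @return List of class `autocorrelogram`: `lags` (bin centers, s),
#'   `counts` (raw), `normalized` (max 1), `peak_lag` (s, NA when empty).
#' @export
spike_autocorrelogram <- function(trial_spikes, epoch_window = NULL,
                                  bin = 0.005, max_lag = 0.25) {
  edges <- seq(-max_lag - bin / 2, max_lag + bin / 2, by = bin)
  centers <- utils::head(edges, -1) + bin / 2
  acc <- rep(0, length(centers))
  for (st in trial_spikes) {
    if (!is.null(epoch_window))
      st <- st[st >= epoch_window[1] & st < epoch_window[2]]
    n <- length(st)
    if (n < 2) next
    d <- outer(st, st, `-`)
    d <- d[row(d) != col(d)]
    d <- d[abs(d) <= max_lag + bin / 2]
    if (length(d))
      acc <- acc + tabulate(findInterval(d, edges), nbins = length(centers))
  }
  if (all(acc == 0)) {
    return(structure(list(lags = centers, counts = acc, normalized = acc,
                          peak_lag = NA_real_), class = "autocorrelogram"))
  }
  norm <- acc / max(acc)
  zero_bin <- which.min(abs(centers))
  search <- norm
  search[zero_bin] <- -Inf
  structure(list(lags = centers, counts = acc, normalized = norm,
                 peak_lag = centers[which.max(search)]),
            class = "autocorrelogram")
}

#' Detect threshold crossings on a filtered trace
#'
#' Zero-phase band-pass filters the trace (4th-order Butterworth applied
#' forward and backward), sets the threshold at `k` times the root mean
#' square of the filtered signal (over `baseline_window` when given, as in
#' multiunit mode, otherwise over the whole trace), and returns
#' negative-going crossing times with a dead time.
#'
#' @param trace Numeric trace, or a `wideband_trace`.
#' @param fs Sampling rate in Hz (taken from a `wideband_trace` input).
#' @param band Length-2 band edges in Hz, within Nyquist.
#' @param k Threshold multiplier (default -3.5; negative = downward
#'   crossings).
#' @param baseline_window Optional `c(start, end)` seconds for the RMS
#'   estimate.
#' @param dead_time Minimum separation between events in seconds (default
#'   0.001).
#' @return List of class `threshold_events`: `times` (s), `threshold`,
#'   `rms`, `filtered` trace.
#' @export
detect_threshold_crossings <- function(trace, fs = NULL, band = c(250, 500),
                                       k = -3.5, baseline_window = NULL,
                                       dead_time = 0.001) {
  if (inherits(trace, "wideband_trace")) {
    fs <- trace$fs
    trace <- trace$trace
  }
  if (is.null(fs)) stop("fs is required")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("invalid band edges for the given sampling rate")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, trace)
  seg <- if (is.null(baseline_window)) filt else {
    i0 <- max(1, floor(baseline_window[1] * fs) + 1)
    i1 <- min(length(filt), ceiling(baseline_window[2] * fs))
    filt[i0:i1]
  }
  rms <- sqrt(mean(seg^2))
  thr <- k * rms
  if (rms == 0) {
    return(structure(list(times = numeric(), threshold = thr, rms = rms,
                          filtered = filt), class = "threshold_events"))
  }
  below <- filt < thr
  idx <- which(below & !c(FALSE, below[-length(below)]))
  if (length(idx)) {
    keep <- rep(TRUE, length(idx))
    last <- idx[1]
    for (j in seq_along(idx)[-1]) {
      keep[j] <- (idx[j] - last) >= dead_time * fs
      if (keep[j]) last <- idx[j]
    }
    idx <- idx[keep]
  }
  structure(list(times = (idx - 1) / fs, threshold = thr, rms = rms,
                 filtered = filt),
            class = "threshold_events")
}

#' Multiunit activity counts around stimulation
#'
#' Filters the wideband trace in the multiunit band (default 300-3000 Hz),
#' thresholds at -3.5 times the RMS of the baseline (concatenated PRE
#' windows), and counts threshold crossings per trial in the PRE and POST
#' epochs only; the during-stimulation epoch is excluded because artifact
#' cannot be separated from multiunit activity without spike sorting.
#'
#' @param trace A `wideband_trace` (or numeric trace with `fs`).
#' @param schedule A [build_trial_schedule()] result.
#' @param fs Sampling rate in Hz if `trace` is numeric.
#' @param band Band edges in Hz (default `c(300, 3000)`).
#' @param k Threshold multiplier (default -3.5).
#' @return Data frame, one row per trial: `trial_index`, `condition`,
#'   `pre`, `post` crossing counts.
#' @export
mua_counts <- function(trace, schedule, fs = NULL, band = c(300, 3000),
                       k = -3.5) {
  if (inherits(trace, "wideband_trace")) {
    fs <- trace$fs
    trace <- trace$trace
  }
  if (is.null(fs)) stop("fs is required")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, trace)
  win <- epoch_windows(schedule)
  pre <- win[win$epoch == "PRE", ]
  # baseline RMS over the concatenated PRE windows
  idx <- unlist(lapply(seq_len(nrow(pre)), function(i) {
    (floor(pre$start[i] * fs) + 1):min(length(filt), ceiling(pre$end[i] * fs))
  }))
  rms <- sqrt(mean(filt[idx]^2))
  thr <- k * rms
  below <- filt < thr
  cross <- which(below & !c(FALSE, below[-length(below)]))
  if (length(cross) > 1) {
    keep <- rep(TRUE, length(cross))
    last <- cross[1]
    for (j in seq_along(cross)[-1]) {
      keep[j] <- (cross[j] - last) >= 0.001 * fs
      if (keep[j]) last <- cross[j]
    }
    cross <- cross[keep]
  }
  times <- (cross - 1) / fs
  count_in <- function(a, b) {
    vapply(seq_along(a), function(i) sum(times >= a[i] & times < b[i]),
           numeric(1))
  }
  post <- win[win$epoch == "POST", ]
  data.frame(trial_index = pre$trial_index,
             condition = pre$condition,
             pre = count_in(pre$start, pre$end),
             post = count_in(post$start, post$end))
}
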