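#' Inclusion-threshold sensitivity sweep
#'
#' Re-runs the inclusion filter over a grid of baseline-rate thresholds
#' (default 0 to 3 Hz in 0.1 Hz steps) and reports, per threshold and
#' condition, how many units pass and what fraction of them is classified
#' as modulated. Modulation tests are computed once for every unit (they do
#' not depend on the threshold); only the included set changes.
#'
#' @param units List of `unit_record`s or a `tbs_cohort`.
#' @param schedule Trial schedule (ignored for cohorts).
#' @param thresholds Numeric grid of thresholds in Hz (non-empty).
#' @param ... Passed to [analyze_units()] (`n_permutations`, `alpha`,
#'   `seed`, ...).
#' @return Data frame of class `sweep_result`: `threshold`, `condition`,
#'   `n_included`, `n_modulated`, `frac_modulated`.
#' @export
sensitivity_sweep <- function(units, schedule = NULL,
                              thresholds = seq(0, 3, by = 0.1), ...) {
  if (!length(thresholds)) stop("threshold grid must be non-empty")
  base <- analyze_units(units, schedule, threshold = 0, ...)
  sweep_from_analysis(base, thresholds)
}

sweep_from_analysis <- function(analysis, thresholds) {
  u <- analysis$units
  rows <- lapply(thresholds, function(th) {
    inc <- u[u$baseline_rate >= th, , drop = FALSE]
    do.call(rbind, lapply(c("stim", "no_stim"), function(cond) {
      k <- sum(inc[[paste0("modulated_", cond)]], na.rm = TRUE)
      data.frame(threshold = th, condition = cond, n_included = nrow(inc),
                 n_modulated = k,
                 frac_modulated = if (nrow(inc)) k / nrow(inc) else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Remove spikes near burst onsets (artifact-dropout censoring)
#'
#' Deletes spikes in a window of `w` seconds starting at each of the eight
#' burst onsets of the during-stimulation epoch, and at the same
#' within-epoch offsets of the PRE and POST epochs of every trial, so equal
#' effective durations are removed from all contrasted epochs.
#'
#' @param spike_times Sorted spike times in seconds.
#' @param schedule Trial schedule (its protocol gives the burst layout).
#' @param w Window length in seconds (>= 0; `w * n_bursts` must stay below
#'   the 1 s epoch).
#' @return Censored spike-time vector.
#' @export
censor_spikes <- function(spike_times, schedule, w) {
  if (w == 0) return(spike_times)
  prot <- attr(schedule, "protocol") %||% stim_protocol()
  burst_period <- 1 / prot$burst_rate
  if (w * prot$n_bursts >= 1)
    stop("dropout window times n_bursts reaches the epoch length")
  win <- epoch_windows(schedule)
  win <- win[win$epoch %in% c("PRE", "DUR", "POST"), ]
  drop <- rep(FALSE, length(spike_times))
  for (i in seq_len(nrow(win))) {
    rel <- spike_times - win$start[i]
    inside <- rel >= 0 & rel < 1
    drop <- drop | (inside & (rel %% burst_period) < w)
  }
  spike_times[!drop]
}

#' Artifact-dropout analysis
#'
#' Re-runs the full inclusion + modulation pipeline after censoring spikes
#' near burst onsets ([censor_spikes()]) for each dropout window length
#' (default 0 to 60 ms in 5 ms steps). Counts are compared raw, not
#' rescaled, because identical durations are removed from every epoch. A
#' window of 0 reproduces the base analysis exactly.
#'
#' @param units List of `unit_record`s or a `tbs_cohort`.
#' @param schedule Trial schedule (ignored for cohorts).
#' @param windows_ms Dropout window lengths in ms.
#' @param threshold Baseline inclusion threshold in Hz.
#' @param ... Passed to [analyze_units()].
#' @return Data frame of class `dropout_result`: `window_ms`, `condition`,
#'   `n_included`, `n_modulated`, `frac_modulated`.
#' @export
dropout_analysis <- function(units, schedule = NULL,
                             windows_ms = seq(0, 60, by = 5),
                             threshold = 0.1, ...) {
  if (inherits(units, "tbs_cohort")) {
    schedule <- units$schedule
    units <- units$units
  }
  rows <- lapply(windows_ms, function(wm) {
    cen <- lapply(units, function(u) {
      st <- if (inherits(u, "unit_record")) u$spike_times else u
      cs <- censor_spikes(st, schedule, wm / 1000)
      if (inherits(u, "unit_record")) {
        u$spike_times <- cs
        u
      } else cs
    })
    an <- analyze_units(cen, schedule, threshold = threshold, ...)
    s <- summarize_modulation(an)
    do.call(rbind, lapply(c("stim", "no_stim"), function(cond) {
      r <- s[s$measure == paste0("modulated_", cond), ]
      data.frame(window_ms = wm, condition = cond, n_included = r$total,
                 n_modulated = r$n,
                 frac_modulated = if (r$total) r$n / r$total else NA_real_)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dropout_result", "data.frame")
  out
}

#' Detection-probability simulation
#'
#' Estimates the probability that the modulation test detects a given true
#' effect, over a grid of baseline rates and effect sizes: for each cell,
#' `n_reps` synthetic units are generated on a shared trial schedule, the
#' full counting + permutation pipeline is run on the stim-condition
#' during-stimulation contrast, and the detected fraction is reported with
#' a 95% binomial (Clopper-Pearson) interval. Effects are absolute rate
#' changes in Hz by default; with `effect_mode = "ratio"` the effect values
#' are rate ratios and the additive effect is `baseline * (ratio - 1)`,
#' which shrinks with the baseline and reproduces the lower detectability
#' of sparsely active neurons.
#'
#' @param baseline_rates Baseline-rate grid in Hz.
#' @param effects Effect grid (Hz, or ratios for `effect_mode = "ratio"`).
#' @param n_trials Trials in the shared schedule (default 160).
#' @param n_reps Simulated units per cell (>= 50).
#' @param alpha Significance level.
#' @param n_permutations Permutations per test.
#' @param effect_mode `"absolute"` or `"ratio"`.
#' @param epoch Modulated/tested epoch (default `"DUR"`).
#' @param seed Master seed.
#' @return Data frame of class `detection_surface`: `baseline`, `effect`,
#'   `effect_hz`, `n_reps`, `n_detected`, `frac_detected`, `ci_lo`,
#'   `ci_hi`, `truncated` (rate clipped at zero).
#' @export
detection_probability_sim <- function(baseline_rates = c(0.1, 0.5, 1, 2, 5),
                                      effects = c(-0.7, -0.4, -0.1,
                                                  0.1, 0.4, 0.7),
                                      n_trials = 160, n_reps = 50,
                                      alpha = 0.05, n_permutations = 1000,
                                      effect_mode = c("absolute", "ratio"),
                                      epoch = "DUR", seed = 1) {
  effect_mode <- match.arg(effect_mode)
  if (!length(baseline_rates) || !length(effects)) stop("empty grid")
  if (n_reps < 50) stop("n_reps must be at least 50")
  schedule <- build_trial_schedule(n_trials, seed = seed)
  grid <- expand.grid(baseline = baseline_rates, effect = effects)
  cell <- 0L
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    b <- grid$baseline[g]
    e_raw <- grid$effect[g]
    e <- if (effect_mode == "ratio") b * (e_raw - 1) else e_raw
    truncated <- b + e < 0
    det <- vapply(seq_len(n_reps), function(rep) {
      gt <- ground_truth_unit("sim", baseline_rate = b, mod_effect = e,
                              mod_epoch = epoch)
      st <- simulate_unit_spikes(schedule, gt,
                                 seed = derive_seed(seed, g * 100003 + rep,
                                                    "stim", "DUR"))
      ec <- count_spikes(st, schedule, "stim")
      test_contrast(ec, test_epoch = epoch,
                    n_permutations = n_permutations, alpha = alpha,
                    seed = derive_seed(seed, g * 100003 + rep,
                                       "stim", "POST"))$significant
    }, logical(1))
    ci <- stats::binom.test(sum(det), n_reps)$conf.int
    data.frame(baseline = b, effect = e_raw, effect_hz = e, n_reps = n_reps,
               n_detected = sum(det), frac_detected = mean(det),
               ci_lo = ci[1], ci_hi = ci[2], truncated = truncated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("detection_surface", "data.frame")
  out
}

#' @export
plot.detection_surface <- function(x, ...) {
  bs <- sort(unique(x$baseline))
  cols <- grDevices::hcl.colors(length(bs), "viridis")
  graphics::plot(NA, xlim = range(x$effect), ylim = c(0, 1),
                 xlab = "Effect size", ylab = "Detection probability", ...)
  for (i in seq_along(bs)) {
    sub <- x[x$baseline == bs[i], ]
    sub <- sub[order(sub$effect), ]
    graphics::lines(sub$effect, sub$frac_detected, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = sprintf("%.1f Hz", bs),
                   col = cols, lwd = 2, title = "Baseline", bty = "n")
  invisible(x)
}
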