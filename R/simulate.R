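#' Ground-truth unit description for simulation
#'
#' Parameters of one simulated neuron: a homogeneous Poisson baseline, an
#' optional additive rate change during image display, and an optional
#' additive stimulation effect confined to a window after stimulation onset
#' on stim trials. Rates are truncated at zero.
#'
#' @param unit_id Identifier.
#' @param region One of HIP, OFC, AMY, ACC.
#' @param laterality `"ipsi"` or `"contra"` to the stimulation site.
#' @param baseline_rate Baseline rate in Hz (>= 0).
#' @param cell_class `"E"` or `"I"` (waveform class ground truth).
#' @param mod_effect Signed stimulation effect in Hz (0 = unmodulated).
#' @param mod_epoch `"DUR"`, `"POST"`, or `"both"`; sets the default
#'   modulation window (onset latency 0/1/0 s, duration 1/1/2 s after
#'   stimulation onset).
#' @param mod_onset_latency,mod_duration Optional explicit window (seconds
#'   after stimulation onset) overriding the `mod_epoch` defaults.
#' @param image_effect Signed rate change in Hz while the image is on
#'   screen.
#' @return Object of class `ground_truth_unit`.
#' @export
ground_truth_unit <- function(unit_id = "u001", region = "HIP",
                              laterality = "ipsi", baseline_rate = 1,
                              cell_class = "E", mod_effect = 0,
                              mod_epoch = c("DUR", "POST", "both"),
                              mod_onset_latency = NULL, mod_duration = NULL,
                              image_effect = 0) {
  mod_epoch <- match.arg(mod_epoch)
  stopifnot(baseline_rate >= 0)
  if (is.null(mod_onset_latency))
    mod_onset_latency <- switch(mod_epoch, DUR = 0, POST = 1, both = 0)
  if (is.null(mod_duration))
    mod_duration <- switch(mod_epoch, DUR = 1, POST = 1, both = 2)
  structure(list(unit_id = unit_id, region = region, laterality = laterality,
                 baseline_rate = baseline_rate, cell_class = cell_class,
                 mod_effect = mod_effect, mod_epoch = mod_epoch,
                 mod_onset_latency = mod_onset_latency,
                 mod_duration = mod_duration, image_effect = image_effect),
            class = "ground_truth_unit")
}

#' One recorded putative neuron
#'
#' @param unit_id Identifier.
#' @param region Recording region (HIP, OFC, AMY, ACC).
#' @param laterality `"ipsi"` or `"contra"`.
#' @param spike_times Sorted numeric spike times in seconds.
#' @param mean_waveform Averaged spike waveform (amplitude series), or NULL.
#' @param waveform_fs Waveform sampling rate in Hz (default 30000).
#' @return Object of class `unit_record`.
#' @export
unit_record <- function(unit_id, region = NA_character_,
                        laterality = NA_character_, spike_times = numeric(),
                        mean_waveform = NULL, waveform_fs = 30000) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike times must be sorted ascending")
  structure(list(unit_id = unit_id, region = region, laterality = laterality,
                 spike_times = spike_times, mean_waveform = mean_waveform,
                 waveform_fs = waveform_fs),
            class = "unit_record")
}

#' @export
print.unit_record <- function(x, ...) {
  cat(sprintf("Unit %s (%s, %s): %d spikes%s\n", x$unit_id, x$region,
              x$laterality, length(x$spike_times),
              if (length(x$spike_times))
                sprintf(" over %.1f s", diff(range(x$spike_times))) else ""))
  invisible(x)
}

#' Simulate a unit's spike train over a session
#'
#' Piecewise-constant-rate Poisson process: rate `baseline_rate`
#' everywhere, `baseline_rate + image_effect` while an image is on screen,
#' and `baseline_rate + mod_effect` within the modulation window
#' `[stim_onset + mod_onset_latency, + mod_duration)` of stim trials only.
#' Rates are truncated at zero. Within each constant-rate segment the spike
#' count is Poisson and spike times are iid uniform (the order-statistics
#' construction of the Poisson process).
#'
#' @param schedule A [build_trial_schedule()] result.
#' @param unit A [ground_truth_unit()].
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times in seconds.
#' @export
simulate_unit_spikes <- function(schedule, unit, seed = NULL) {
  stopifnot(inherits(unit, "ground_truth_unit"))
  if (!is.null(seed)) set.seed(seed)
  t_end <- session_span(schedule)[2]
  ws <- we <- wa <- numeric()
  if (unit$image_effect != 0) {
    ws <- c(ws, schedule$image_onset)
    we <- c(we, schedule$image_offset)
    wa <- c(wa, rep(unit$image_effect, nrow(schedule)))
  }
  if (unit$mod_effect != 0) {
    so <- schedule$stim_onset[schedule$condition == "stim"]
    ws <- c(ws, so + unit$mod_onset_latency)
    we <- c(we, so + unit$mod_onset_latency + unit$mod_duration)
    wa <- c(wa, rep(unit$mod_effect, length(so)))
  }
  breaks <- sort(unique(c(0, t_end, ws, we)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  seg_start <- utils::head(breaks, -1)
  seg_len <- diff(breaks)
  rate <- rep(unit$baseline_rate, length(seg_start))
  if (length(ws)) {
    mid <- seg_start + seg_len / 2
    for (j in seq_along(ws))
      rate <- rate + wa[j] * (mid >= ws[j] & mid < we[j])
  }
  rate <- pmax(rate, 0)
  n_seg <- stats::rpois(length(seg_start), rate * seg_len)
  if (sum(n_seg) == 0) return(numeric())
  sort(rep(seg_start, n_seg) + stats::runif(sum(n_seg)) * rep(seg_len, n_seg))
}

#' Parametric spike-waveform template
#'
#' Constructs a mean-waveform template with a single global valley followed
#' by a single peak, calibrated so that the realized valley-to-peak width
#' (VP) and peak half-width (PHW), as measured by [waveform_metrics()], land
#' within one sample period of the targets. The shape is a narrow negative
#' Gaussian (the valley) plus a broader positive Gaussian (the peak) whose
#' SD is solved numerically for the target PHW.
#'
#' @param target_vp Target valley-to-peak width in ms.
#' @param target_phw Target peak half-width in ms.
#' @param sampling_rate Sampling rate in Hz (default 30000).
#' @param noise_sd Per-sample noise SD used by [simulate_waveform_bank()]
#'   (amplitude units; the valley has amplitude 1).
#' @param duration_ms Template length in ms.
#' @return Object of class `waveform_template` with `samples`,
#'   `sampling_rate`, `target_vp`, `target_phw`, `noise_sd`.
#' @export
waveform_template <- function(target_vp = 0.32, target_phw = 0.31,
                              sampling_rate = 30000, noise_sd = 0.02,
                              duration_ms = 3) {
  stopifnot(target_vp > 0, target_phw > 0)
  fs_ms <- sampling_rate / 1000                 # samples per ms
  n <- round(duration_ms * fs_ms)
  t_ms <- (seq_len(n) - 1) / fs_ms
  valley_ms <- 1
  sd_v <- 0.08
  peak_amp <- 0.55
  peak_ms <- valley_ms + round(target_vp * fs_ms) / fs_ms
  shape <- function(sd_p, pk_ms) {
    -stats::dnorm(t_ms, valley_ms, sd_v) / stats::dnorm(0, 0, sd_v) +
      peak_amp * stats::dnorm(t_ms, pk_ms, sd_p) / stats::dnorm(0, 0, sd_p)
  }
  # solve the peak SD for the target half-width, re-centering the peak if
  # the valley's tail shifts the realized maximum by a full sample
  sd_guess <- target_phw / (2 * sqrt(2 * log(2)))
  for (iter in 1:5) {
    f <- function(sd_p) {
      m <- waveform_metrics(shape(sd_p, peak_ms), sampling_rate, refine = TRUE)
      m$PHW - target_phw
    }
    sd_p <- tryCatch(
      stats::uniroot(f, c(0.25 * sd_guess, 4 * sd_guess))$root,
      error = function(e) sd_guess)
    m <- waveform_metrics(shape(sd_p, peak_ms), sampling_rate, refine = TRUE)
    vp_err <- m$VP - target_vp
    if (abs(vp_err) <= 1 / fs_ms) break
    peak_ms <- peak_ms - round(vp_err * fs_ms) / fs_ms
  }
  structure(list(samples = shape(sd_p, peak_ms), sampling_rate = sampling_rate,
                 target_vp = target_vp, target_phw = target_phw,
                 noise_sd = noise_sd),
            class = "waveform_template")
}

#' Simulate a bank of noisy spike waveforms
#'
#' Each waveform is the template plus independent Gaussian sample noise;
#' the mean waveform's VP/PHW converge to the template targets as the
#' number of spikes grows (noise averages down as 1/sqrt(n)).
#'
#' @param template A [waveform_template()].
#' @param n_spikes Number of waveforms (>= 1).
#' @param seed Optional integer seed.
#' @return List with `waveforms` (n_spikes x samples matrix),
#'   `mean_waveform`, and `sampling_rate`.
#' @export
simulate_waveform_bank <- function(template, n_spikes, seed = NULL) {
  stopifnot(inherits(template, "waveform_template"), n_spikes >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(template$samples)
  wf <- matrix(rep(template$samples, each = n_spikes), n_spikes, n) +
    matrix(stats::rnorm(n_spikes * n, sd = template$noise_sd), n_spikes, n)
  list(waveforms = wf, mean_waveform = colMeans(wf),
       sampling_rate = template$sampling_rate)
}

#' Simulate a wideband extracellular trace
#'
#' Gaussian noise plus the spike template inserted at each spike time plus a
#' high-amplitude biphasic rectangular artifact transient (0.4 ms per phase)
#' at every stimulation pulse time of the schedule's stim trials.
#' Overlapping insertions are summed.
#'
#' @param spike_times Sorted spike times in seconds.
#' @param template A [waveform_template()] (resampled to `fs` if needed).
#' @param schedule A [build_trial_schedule()]; its protocol supplies the
#'   pulse times. NULL for a trace without stimulation artifacts (then
#'   `duration` must be given).
#' @param noise_sd Noise SD in template amplitude units.
#' @param fs Trace sampling rate in Hz (must be at least 4x the highest
#'   analysis band edge used downstream).
#' @param artifact_amplitude Artifact phase amplitude (default 20x the
#'   noise RMS).
#' @param duration Trace length in seconds (defaults to the session span).
#' @param seed Optional integer seed.
#' @return List of class `wideband_trace`: `trace`, `fs`, `spike_times`,
#'   `pulse_times`.
#' @export
simulate_wideband <- function(spike_times, template, schedule = NULL,
                              noise_sd = 1, fs = 12000,
                              artifact_amplitude = 20 * noise_sd,
                              duration = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) {
    if (is.null(schedule)) stop("either schedule or duration is required")
    duration <- session_span(schedule)[2]
  }
  n <- ceiling(duration * fs)
  trace <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
  shp <- template$samples
  if (template$sampling_rate != fs) {
    t_old <- seq_along(shp) / template$sampling_rate
    t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / fs)
    shp <- stats::approx(t_old, shp, t_new)$y
  }
  add_at <- function(trace, times, shape) {
    for (tt in times) {
      i0 <- floor(tt * fs) + 1
      idx <- i0:(i0 + length(shape) - 1)
      ok <- idx >= 1 & idx <= n
      trace[idx[ok]] <- trace[idx[ok]] + shape[ok]
    }
    trace
  }
  trace <- add_at(trace, spike_times[spike_times < duration], shp)
  pulse_times <- numeric()
  if (!is.null(schedule)) {
    prot <- attr(schedule, "protocol")
    so <- schedule$stim_onset[schedule$condition == "stim"]
    if (!is.null(prot) && length(so)) {
      pulse_times <- as.vector(outer(tbs_pulse_train(prot), so, `+`))
      phase <- round(0.0004 * fs)
      art <- c(rep(artifact_amplitude, phase), rep(-artifact_amplitude, phase))
      trace <- add_at(trace, pulse_times, art)
    }
  }
  structure(list(trace = trace, fs = fs, spike_times = spike_times,
                 pulse_times = sort(pulse_times)),
            class = "wideband_trace")
}

#' Simulate recognition-memory behavior
#'
#' Equal-variance Gaussian signal detection: with sensitivity d' and
#' criterion c, the hit probability is `pnorm(d'/2 + c)` and the
#' false-alarm probability `pnorm(-d'/2 + c)`. Per session and condition,
#' hit and false-alarm counts are binomial draws (or expected counts when
#' `sample = FALSE`, for noiseless round-trip checks).
#'
#' @param n_sessions Number of sessions.
#' @param dprime_nostim True d' in the no-stim condition.
#' @param dprime_delta Added d' in the stim condition.
#' @param n_old_per_cond Old (target) images per condition.
#' @param n_new New (lure) images scored per condition.
#' @param criterion Response criterion c (default 0).
#' @param experiment Experiment label(s), recycled across sessions.
#' @param session_sd SD of a session-level random shift of d' (default 0).
#' @param sample Draw binomial counts (TRUE) or use expected counts.
#' @param seed Optional integer seed.
#' @return Data frame, one row per session x condition: `session_id`,
#'   `experiment`, `condition`, `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`, `d_prime`.
#' @export
simulate_behavior <- function(n_sessions, dprime_nostim = 1,
                              dprime_delta = 0, n_old_per_cond = 40,
                              n_new = 40, criterion = 0, experiment = "exp1",
                              session_sd = 0, sample = TRUE, seed = NULL) {
  stopifnot(n_sessions >= 1, n_old_per_cond >= 1, n_new >= 1)
  if (!is.null(seed)) set.seed(seed)
  exps <- rep_len(experiment, n_sessions)
  shift <- if (session_sd > 0) stats::rnorm(n_sessions, sd = session_sd)
           else rep(0, n_sessions)
  rows <- lapply(seq_len(n_sessions), function(s) {
    do.call(rbind, lapply(c("no_stim", "stim"), function(cond) {
      d <- dprime_nostim + shift[s] +
        if (cond == "stim") dprime_delta else 0
      hp <- stats::pnorm(d / 2 + criterion)
      fp <- stats::pnorm(-d / 2 + criterion)
      hits <- if (sample) stats::rbinom(1, n_old_per_cond, hp)
              else hp * n_old_per_cond
      fas <- if (sample) stats::rbinom(1, n_new, fp) else fp * n_new
      data.frame(session_id = sprintf("s%03d", s), experiment = exps[s],
                 condition = cond, hits = hits,
                 misses = n_old_per_cond - hits, false_alarms = fas,
                 correct_rejections = n_new - fas,
                 d_prime = dprime(hits, n_old_per_cond - hits, fas,
                                  n_new - fas)$d_prime)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates a trial schedule and a population of units emulating the
#' structure of the TBS recognition-memory experiments: baseline rates
#' spanning ~0.03-10 Hz (log-uniform), a truly modulated subpopulation
#' (default 30%) with heterogeneous direction and epoch of effect, two
#' waveform classes (default 85% E / 15% I, I with the shorter
#' valley-to-peak waveform and higher baseline rates), and region labels in
#' the proportions of the recorded dataset. Modulated units draw baselines
#' of at least 2 Hz and effect magnitudes of at least 1.5 Hz so the cohort
#' matches the detection-power regime of the emulated study.
#'
#' @param n_units Number of units (default 200).
#' @param n_trials Trials in the schedule (default 160).
#' @param prop_modulated Fraction of truly modulated units.
#' @param prop_inhibitory Fraction of fast-spiking (I) units.
#' @param prop_image_responsive Fraction of units with an image-onset rate
#'   change.
#' @param mod_baseline_range Baseline-rate range (Hz) for modulated units.
#' @param effect_range Magnitude range (Hz) of the stimulation effect.
#' @param p_suppressed Probability a modulated unit is suppressed.
#' @param epoch_probs Probabilities of mod epoch DUR / POST / both.
#' @param baseline_range Log-uniform baseline range (Hz) for unmodulated
#'   units.
#' @param protocol,isi_mean,jitter Passed to [build_trial_schedule()].
#' @param seed Master seed; per-unit spike seeds are derived from it.
#' @return Object of class `tbs_cohort`: list with `schedule`,
#'   `ground_truth` (data frame), and `units` (list of `unit_record`s with
#'   spike trains and mean waveforms).
#' @export
simulate_cohort <- function(n_units = 200, n_trials = 160,
                            prop_modulated = 0.3, prop_inhibitory = 0.15,
                            prop_image_responsive = 0.15,
                            mod_baseline_range = c(2, 10),
                            effect_range = c(1.5, 3), p_suppressed = 0.56,
                            epoch_probs = c(DUR = 0.765, POST = 0.196,
                                            both = 0.039),
                            baseline_range = c(0.03, 10),
                            protocol = stim_protocol(), isi_mean = 6,
                            jitter = 0.5, seed = 1) {
  set.seed(seed)
  schedule <- build_trial_schedule(n_trials, protocol, isi_mean, jitter,
                                   seed = seed)
  regions <- sample(c("HIP", "OFC", "AMY", "ACC"), n_units, replace = TRUE,
                    prob = c(95, 44, 39, 25))
  lat <- sample(c("ipsi", "contra"), n_units, replace = TRUE)
  n_mod <- round(prop_modulated * n_units)
  modulated <- sample(c(rep(TRUE, n_mod), rep(FALSE, n_units - n_mod)))
  cls <- sample(c("I", "E"), n_units, replace = TRUE,
                prob = c(prop_inhibitory, 1 - prop_inhibitory))
  base <- exp(stats::runif(n_units, log(baseline_range[1]),
                           log(baseline_range[2])))
  # fast-spiking units tend to fire faster at baseline
  base[cls == "I"] <- pmax(base[cls == "I"],
                           exp(stats::runif(sum(cls == "I"),
                                            log(0.5), log(10))))
  base[modulated] <- exp(stats::runif(n_mod, log(mod_baseline_range[1]),
                                      log(mod_baseline_range[2])))
  eff <- rep(0, n_units)
  eff[modulated] <- stats::runif(n_mod, effect_range[1], effect_range[2]) *
    ifelse(stats::runif(n_mod) < p_suppressed, -1, 1)
  mod_epoch <- rep("DUR", n_units)
  mod_epoch[modulated] <- sample(names(epoch_probs), n_mod, replace = TRUE,
                                 prob = epoch_probs)
  img <- rep(0, n_units)
  is_img <- stats::runif(n_units) < prop_image_responsive
  img[is_img] <- stats::runif(sum(is_img), 0.5, 1.5) *
    ifelse(stats::runif(sum(is_img)) < 0.7, 1, -1)

  tmpl_e <- waveform_template(0.50, 0.51)
  tmpl_i <- waveform_template(0.32, 0.31)
  units <- vector("list", n_units)
  gt <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    id <- sprintf("u%03d", i)
    g <- ground_truth_unit(id, regions[i], lat[i], base[i], cls[i],
                           mod_effect = eff[i], mod_epoch = mod_epoch[i],
                           image_effect = img[i])
    st <- simulate_unit_spikes(schedule, g,
                               seed = derive_seed(seed, i, "stim", "DUR"))
    tmpl <- if (cls[i] == "I") tmpl_i else tmpl_e
    bank <- simulate_waveform_bank(tmpl, 200,
                                   seed = derive_seed(seed, i, "no_stim", "POST"))
    units[[i]] <- unit_record(id, regions[i], lat[i], st,
                              mean_waveform = bank$mean_waveform,
                              waveform_fs = tmpl$sampling_rate)
    gt[[i]] <- data.frame(unit_id = id, region = regions[i],
                          laterality = lat[i], baseline_rate = base[i],
                          cell_class = cls[i], mod_effect = eff[i],
                          mod_epoch = mod_epoch[i], image_effect = img[i],
                          modulated = modulated[i])
  }
  structure(list(schedule = schedule, ground_truth = do.call(rbind, gt),
                 units = units, seed = seed),
            class = "tbs_cohort")
}

#' @export
print.tbs_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(
    "Synthetic cohort: %d units (%d modulated, %d I / %d E), %d trials\n",
    nrow(gt), sum(gt$modulated), sum(gt$cell_class == "I"),
    sum(gt$cell_class == "E"), nrow(x$schedule)))
  invisible(x)
}
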