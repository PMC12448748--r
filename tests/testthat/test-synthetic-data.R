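test_that("trial schedules are balanced, ordered and reproducible", {
  sch <- build_trial_schedule(160, seed = 1)
  expect_equal(sum(sch$condition == "stim"), 80)
  expect_equal(sum(sch$condition == "no_stim"), 80)
  expect_true(all(diff(sch$image_onset) > 0))
  expect_true(all(sch$image_onset[-1] >= sch$image_offset[-160]))
  expect_equal(sch$image_offset, sch$image_onset + 3)
  expect_true(all(is.na(sch$stim_onset[sch$condition == "no_stim"])))
  expect_equal(sch$stim_onset[sch$condition == "stim"],
               sch$image_offset[sch$condition == "stim"])

  # two trials: one of each, order decided by the seed
  s2 <- build_trial_schedule(2, seed = 3)
  expect_setequal(s2$condition, c("stim", "no_stim"))

  # odd n: counts differ by at most one
  s9 <- build_trial_schedule(9, seed = 4)
  expect_lte(abs(sum(s9$condition == "stim") - sum(s9$condition == "no_stim")), 1)

  expect_identical(build_trial_schedule(40, seed = 5),
                   build_trial_schedule(40, seed = 5))
  expect_false(identical(build_trial_schedule(40, seed = 5)$condition,
                         build_trial_schedule(40, seed = 6)$condition))

  expect_error(build_trial_schedule(0), "at least 2")
  expect_error(build_trial_schedule(10, isi_mean = 1.5), "overlap")
})

test_that("TBS pulse train has the nested burst layout", {
  pt <- tbs_pulse_train(stim_protocol())
  expect_length(pt, 32)                     # 8 bursts x 4 pulses at 50 Hz
  expect_identical(pt[1], 0)                # burst 0 starts at train onset
  expect_lt(max(pt), 1.0)                   # all pulses within the 1 s train
  # within-burst offsets at the 20 ms pulse period over the 62.5 ms on-window
  offs <- round(1000 * (pt %% 0.125), 9)
  expect_setequal(offs, c(0, 20, 40, 60))
  # burst onsets equally spaced at 125 ms
  expect_equal(sort(unique(pt[offs == 0])), (0:7) * 0.125)

  expect_error(stim_protocol(duty_cycle = 0), "duty_cycle")
  expect_error(stim_protocol(pulse_rate = 5), "pulse_rate")
  expect_warning(tbs_pulse_train(stim_protocol(pulse_rate = 9)), "one pulse")
})

test_that("simulated spike trains follow the piecewise-constant rate model", {
  sch <- build_trial_schedule(160, seed = 2)

  silent <- ground_truth_unit(baseline_rate = 0)
  expect_length(simulate_unit_spikes(sch, silent, seed = 1), 0)

  # empirical PRE rate within 3 Poisson SE of the generative 2 Hz
  flat <- ground_truth_unit(baseline_rate = 2)
  st <- simulate_unit_spikes(sch, flat, seed = 7)
  pre <- count_spikes(st, sch, "both")$counts[, "PRE"]
  se <- sqrt(2 / 160)
  expect_lt(abs(mean(pre) - 2), 3 * se)

  # identical seed, identical train
  expect_identical(st, simulate_unit_spikes(sch, flat, seed = 7))

  # suppression truncated at zero: DUR rate ~0 on stim trials, ~2 on no-stim
  supp <- ground_truth_unit(baseline_rate = 2, mod_effect = -2,
                            mod_epoch = "DUR")
  st2 <- simulate_unit_spikes(sch, supp, seed = 8)
  dur_stim <- count_spikes(st2, sch, "stim")$counts[, "DUR"]
  dur_nostim <- count_spikes(st2, sch, "no_stim")$counts[, "DUR"]
  expect_lt(mean(dur_stim), 0.2)
  expect_lt(abs(mean(dur_nostim) - 2), 3 * sqrt(2 / 80))

  # modulation confined to stim trials and to the configured epoch
  post_stim <- count_spikes(st2, sch, "stim")$counts[, "POST"]
  expect_lt(abs(mean(post_stim) - 2), 3 * sqrt(2 / 80))
})

test_that("waveform bank realizes the target morphology", {
  tm <- waveform_template(target_vp = 0.32, target_phw = 0.31,
                          noise_sd = 0)
  bank <- simulate_waveform_bank(tm, 5)
  # zero noise: every waveform identical to the template
  expect_equal(bank$waveforms[1, ], tm$samples, ignore_attr = TRUE)
  expect_equal(bank$waveforms[5, ], tm$samples, ignore_attr = TRUE)

  # measured metrics on the mean waveform within one sample period (1/30 ms)
  m <- waveform_metrics(bank$mean_waveform, bank$sampling_rate)
  expect_lt(abs(m$VP - 0.32), 1 / 30)
  expect_lt(abs(m$PHW - 0.31), 1 / 30)

  m2 <- waveform_metrics(waveform_template(0.50, 0.51)$samples, 30000)
  expect_lt(abs(m2$VP - 0.50), 1 / 30)
  expect_lt(abs(m2$PHW - 0.51), 1 / 30)

  # averaging improves SNR over any single noisy waveform
  tmn <- waveform_template(0.32, 0.31, noise_sd = 0.2)
  bn <- simulate_waveform_bank(tmn, 1000, seed = 9)
  snr_of <- function(w) max(abs(w)) / stats::sd(w - tmn$samples)
  single_snrs <- apply(bn$waveforms[1:50, ], 1, snr_of)
  expect_gt(snr_of(bn$mean_waveform), max(single_snrs))
})

test_that("wideband traces contain spikes and artifacts where placed", {
  tm <- waveform_template(0.32, 0.31, noise_sd = 0)
  sch <- build_trial_schedule(6, seed = 21)

  # no spikes, no artifacts, no noise: an all-zero trace
  wb0 <- simulate_wideband(numeric(), tm, schedule = NULL, noise_sd = 0,
                           fs = 12000, duration = 2)
  expect_true(all(wb0$trace == 0))

  # injected spikes at 10x noise RMS are recovered by the detector
  set.seed(31)
  spikes <- sort(runif(10, 1, 19))
  tm10 <- waveform_template(0.32, 0.31, noise_sd = 0)
  tm10$samples <- tm10$samples * 10
  wb <- simulate_wideband(spikes, tm10, schedule = NULL, noise_sd = 1,
                          fs = 12000, duration = 20, seed = 32)
  ev <- detect_threshold_crossings(wb, band = c(300, 3000))
  matched <- vapply(spikes, function(s) any(abs(ev$times - s) < 0.002),
                    logical(1))
  expect_gte(sum(matched), 9)

  # artifacts produce no crossings outside the stimulation trains
  wba <- simulate_wideband(numeric(), tm, schedule = sch, noise_sd = 1,
                           fs = 12000, seed = 33)
  ev2 <- detect_threshold_crossings(wba, band = c(300, 3000),
                                    baseline_window = c(0, 1))
  so <- sch$stim_onset[sch$condition == "stim"]
  big <- ev2$times[abs(ev2$filtered[round(ev2$times * 12000) + 1]) >
                     3 * abs(ev2$threshold)]
  in_train <- vapply(big, function(tt)
    any(tt >= so - 0.01 & tt <= so + 1.01), logical(1))
  expect_true(all(in_train))
})

test_that("behavioral generator matches signal-detection expectations", {
  # d' = 1, criterion 0: hit rate Phi(0.5), FA rate Phi(-0.5)
  b <- simulate_behavior(500, dprime_nostim = 1, n_old_per_cond = 40,
                         n_new = 40, seed = 13)
  hr <- with(b, hits / (hits + misses))
  fr <- with(b, false_alarms / (false_alarms + correct_rejections))
  expect_lt(abs(mean(hr) - pnorm(0.5)), 0.01)   # 0.691
  expect_lt(abs(mean(fr) - pnorm(-0.5)), 0.01)  # 0.309

  # noiseless round trip: recovered d' equals the input d'
  nb <- simulate_behavior(3, dprime_nostim = 1.3, dprime_delta = 0.4,
                          sample = FALSE)
  expect_equal(nb$d_prime[nb$condition == "no_stim"], rep(1.3, 3),
               tolerance = 1e-10)
  expect_equal(nb$d_prime[nb$condition == "stim"], rep(1.7, 3),
               tolerance = 1e-10)

  # null case: mean recovered delta d' near zero
  nullb <- simulate_behavior(200, dprime_nostim = 1, dprime_delta = 0,
                             n_old_per_cond = 80, n_new = 80, seed = 14)
  expect_lt(abs(mean(behavior_summary(nullb)$delta_d)), 0.05)
})

test_that("cohort generator respects its own ground truth", {
  coh <- simulate_cohort(n_units = 60, n_trials = 40, seed = 17)
  gt <- coh$ground_truth
  expect_equal(nrow(gt), 60)
  expect_equal(sum(gt$modulated), 18)             # 30% truly modulated
  expect_true(all(gt$baseline_rate[gt$modulated] >= 2))
  expect_true(all(abs(gt$mod_effect[gt$modulated]) >= 1.5))
  expect_true(all(gt$mod_effect[!gt$modulated] == 0))
  # conservation of trials
  expect_equal(sum(coh$schedule$condition == "stim") +
                 sum(coh$schedule$condition == "no_stim"), 40)
  # waveform class drives the waveform morphology
  i_unit <- coh$units[[which(gt$cell_class == "I")[1]]]
  e_unit <- coh$units[[which(gt$cell_class == "E")[1]]]
  expect_lt(waveform_metrics(i_unit$mean_waveform, i_unit$waveform_fs)$VP,
            waveform_metrics(e_unit$mean_waveform, e_unit$waveform_fs)$VP)
})

test_that("simulated data round-trips through the CSV writers", {
  coh <- simulate_cohort(n_units = 5, n_trials = 10, seed = 19)
  dir <- withr_local_tempdir()
  write_simulated_data(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("spikes.csv", "trials.csv", "ground_truth.csv", "params.json")))))
  rt <- read_simulated_data(dir)
  expect_equal(nrow(rt$schedule), 10)
  ids <- vapply(rt$units, function(u) u$unit_id, character(1))
  orig <- coh$units[[match(ids[1], vapply(coh$units, `[[`, "", "unit_id"))]]
  expect_equal(rt$units[[1]]$spike_times, orig$spike_times,
               tolerance = 1e-12)
  # schedule round-trips closely enough to reproduce epoch counts
  expect_equal(count_spikes(orig$spike_times, rt$schedule, "stim")$counts,
               count_spikes(orig$spike_times, coh$schedule, "stim")$counts)
})
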