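test_that("pseudo-population rows are z-scored condition-concatenated traces", {
  sch <- build_trial_schedule(40, seed = 91)
  # two-level unit: 2 Hz baseline, strong DUR enhancement on stim trials
  g <- ground_truth_unit(baseline_rate = 2, mod_effect = 6, mod_epoch = "DUR")
  st <- simulate_unit_spikes(sch, g, seed = 92)
  flat <- simulate_unit_spikes(sch, ground_truth_unit(baseline_rate = 3),
                               seed = 93)
  pop <- pseudo_population_matrix(list(st, flat), sch)
  expect_equal(nrow(pop$matrix), 2)
  expect_equal(ncol(pop$matrix), 100)        # 50 bins x 2 condition blocks
  # every row standardized across the concatenated axis
  expect_equal(unname(rowMeans(pop$matrix)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(pop$matrix, 1, sd)), c(1, 1), tolerance = 1e-12)
  # modulated unit: positive z in stim-DUR bins, lower elsewhere
  stim_dur <- pop$condition == "stim" & pop$time >= 0 & pop$time < 1
  expect_gt(mean(pop$matrix[1, stim_dur]), 1)
  expect_lt(mean(pop$matrix[1, !stim_dur]), mean(pop$matrix[1, stim_dur]))

  # constant-rate (zero-variance) unit is dropped with a report
  empty <- numeric()
  pop2 <- pseudo_population_matrix(list(st, empty), sch)
  expect_equal(nrow(pop2$matrix), 1)
  expect_length(pop2$dropped, 1)
})

test_that("PCA trajectories are ordered, orthonormal and reconstructive", {
  set.seed(95)
  # rank-1 matrix: PC1 explains everything
  u <- rnorm(10)
  v <- rnorm(30)
  m1 <- outer(u, v)
  p1 <- suppressWarnings(pca_trajectories(m1, n_components = 3))
  expect_equal(p1$explained_variance[1], 1, tolerance = 1e-10)

  m <- matrix(rnorm(12 * 40), 12, 40)
  p <- pca_trajectories(m, n_components = 3)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # full reconstruction from all components
  pc <- p$prcomp
  rec <- pc$x %*% t(pc$rotation) + matrix(pc$center, nrow(pc$x),
                                          ncol(pc$rotation), byrow = TRUE)
  expect_equal(rec, t(m), tolerance = 1e-10, ignore_attr = TRUE)

  # condition blocks recoverable from the score table
  sch <- build_trial_schedule(30, seed = 96)
  units <- lapply(1:5, function(i)
    simulate_unit_spikes(sch, ground_truth_unit(baseline_rate = 4,
                                                mod_effect = 4 * (i %% 2)),
                         seed = 100 + i))
  pop <- pseudo_population_matrix(units, sch)
  pt <- pca_trajectories(pop)
  expect_setequal(unique(pt$scores$condition), c("stim", "no_stim"))
  expect_equal(sum(pt$scores$condition == "stim"), 50)
})

test_that("autocorrelograms are symmetric with interpretable peaks", {
  # single spike per trial: all-zero histogram, no peak
  acg0 <- spike_autocorrelogram(list(0.1, 0.5, 0.9))
  expect_true(all(acg0$counts == 0))
  expect_true(is.na(acg0$peak_lag))

  # regular 100 ms train: peak at the 100 ms bin
  trials <- replicate(20, seq(0, 0.9, by = 0.1), simplify = FALSE)
  acg <- spike_autocorrelogram(trials)
  expect_equal(abs(acg$peak_lag), 0.1, tolerance = 1e-9)
  expect_equal(max(acg$normalized), 1)
  # symmetry ACG(-l) = ACG(+l)
  expect_equal(acg$counts, rev(acg$counts))

  # homogeneous Poisson: flat in expectation off zero
  set.seed(97)
  ptrials <- replicate(300, sort(runif(rpois(1, 10), 0, 1)), simplify = FALSE)
  acgp <- spike_autocorrelogram(ptrials)
  off <- acgp$counts[abs(acgp$lags) > 0.01]
  expect_lt(max(off), mean(off) + 4 * sd(off))

  # epoch windowing restricts the pairs used
  acgw <- spike_autocorrelogram(trials, epoch_window = c(0, 0.15))
  expect_equal(sum(acgw$counts), 20 * 2)    # two spikes per trial -> 2 ordered pairs
})

test_that("threshold detection is scale invariant with controlled recall", {
  set.seed(98)
  fs <- 12000
  # flat trace: no crossings
  ev0 <- detect_threshold_crossings(rep(0, fs), fs, band = c(300, 3000))
  expect_length(ev0$times, 0)

  tm <- waveform_template(0.32, 0.31, noise_sd = 0)
  tm$samples <- tm$samples * 10
  spikes <- seq(0.5, 9.5, by = 1)
  wb <- simulate_wideband(spikes, tm, schedule = NULL, noise_sd = 1,
                          fs = fs, duration = 10, seed = 99)
  ev <- detect_threshold_crossings(wb, band = c(300, 3000))
  matched <- vapply(spikes, function(s) any(abs(ev$times - s) < 0.002),
                    logical(1))
  expect_gte(sum(matched), 9)                        # recall >= 0.9

  # precision >= 0.9 at SNR 10 with a 30 Hz multiunit-like event rate:
  # the noise-crossing rate at the fixed -3.5 x RMS threshold is constant,
  # so precision is assessed where events are dense enough to dominate it
  dense <- seq(0.1, 4, by = 1 / 30)
  wbd <- simulate_wideband(dense, tm, schedule = NULL, noise_sd = 1,
                           fs = fs, duration = 4.2, seed = 100)
  evd <- detect_threshold_crossings(wbd, band = c(300, 3000))
  hits <- vapply(evd$times, function(tt) any(abs(tt - dense) < 0.002),
                 logical(1))
  expect_gte(mean(hits), 0.9)                        # precision
  recall_d <- mean(vapply(dense, function(s)
    any(abs(evd$times - s) < 0.002), logical(1)))
  expect_gte(recall_d, 0.9)

  # doubling the trace leaves the crossing count unchanged
  ev2 <- detect_threshold_crossings(list(trace = wb$trace * 2, fs = fs) |>
                                      structure(class = "wideband_trace"),
                                    band = c(300, 3000))
  expect_equal(length(ev2$times), length(ev$times))

  expect_error(detect_threshold_crossings(rnorm(100), 1000,
                                          band = c(300, 600)), "band")
})

test_that("MUA counting excludes the stimulation epoch", {
  set.seed(100)
  fs <- 12000
  sch <- build_trial_schedule(10, seed = 101)
  tm <- waveform_template(0.32, 0.31, noise_sd = 0)
  tm$samples <- tm$samples * 12
  win <- epoch_windows(sch)
  post <- win[win$epoch == "POST", ]
  dur <- win[win$epoch == "DUR", ]
  # inject events into every POST epoch and (artifact-like) into DUR
  post_spikes <- sort(as.vector(outer(c(0.2, 0.5, 0.8), post$start, `+`)))
  dur_spikes <- sort(dur$start + 0.5)
  wb <- simulate_wideband(sort(c(post_spikes, dur_spikes)), tm,
                          schedule = NULL, noise_sd = 1, fs = fs,
                          duration = session_span(sch)[2], seed = 102)
  mc <- mua_counts(wb, sch)
  expect_equal(nrow(mc), 10)
  # post-minus-pre difference is positive and detected by the signed-rank test
  # (noise crossings contribute equally to both epochs)
  expect_gt(mean(mc$post - mc$pre), 1.5)
  expect_lt(mean(mc$post - mc$pre), 4.5)
  W <- signed_rank_stat(mc$pre, mc$post)
  expect_gt(W$W, W$rank_sum * 0.9)

  # events during the stimulation train never appear in the counts:
  # a trace differing only inside DUR gives identical PRE/POST counts
  wb_duronly <- simulate_wideband(dur_spikes, tm, schedule = NULL,
                                  noise_sd = 1, fs = fs,
                                  duration = session_span(sch)[2],
                                  seed = 102)
  wb_none <- simulate_wideband(numeric(), tm, schedule = NULL, noise_sd = 1,
                               fs = fs, duration = session_span(sch)[2],
                               seed = 102)
  expect_equal(mua_counts(wb_duronly, sch)[, c("pre", "post")],
               mua_counts(wb_none, sch)[, c("pre", "post")])

  # symmetric pre/post activity: paired difference centered near zero
  sym_spikes <- sort(as.vector(outer(c(0.3, 0.6), c(post$start,
                                                    post$start - 5), `+`)))
  wb2 <- simulate_wideband(sym_spikes, tm, schedule = NULL, noise_sd = 1,
                           fs = fs, duration = session_span(sch)[2],
                           seed = 103)
  mc2 <- mua_counts(wb2, sch)
  expect_lt(abs(mean(mc2$post - mc2$pre)), 1)
})
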