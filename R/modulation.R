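#' Wilcoxon signed-rank statistic on paired spike counts
#'
#' Standard signed-rank statistic: zero paired differences are dropped,
#' tied absolute differences receive midranks, and W is the sum of the
#' ranks of the positive differences.
#'
#' @param baseline_counts,test_counts Equal-length per-trial spike counts.
#' @return List with `W` (NA when every difference is zero), `n_nonzero`,
#'   and `rank_sum` (total rank mass `n(n+1)/2`).
#' @export
signed_rank_stat <- function(baseline_counts, test_counts) {
  if (length(baseline_counts) != length(test_counts))
    stop("paired vectors must have equal length")
  d <- test_counts - baseline_counts
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(list(W = NA_real_, n_nonzero = 0L, rank_sum = 0))
  r <- rank(abs(d))
  list(W = sum(r[d > 0]), n_nonzero = m, rank_sum = m * (m + 1) / 2)
}

#' Permutation null distribution for the signed-rank statistic
#'
#' Each permutation independently swaps, per trial with probability 1/2, the
#' trial's baseline/test epoch labels and recomputes W. Swapping the two
#' labels of a trial negates that trial's paired difference while leaving
#' the absolute differences (hence their ranks) unchanged, so the null is
#' computed exactly as a random sign-flip distribution over the rank masses
#' -- an exact, vectorized implementation of the label-swap scheme.
#'
#' With `shuffle = "threeway"` all three epoch labels of each trial (the
#' baseline, the tested epoch and the third remaining epoch) are randomly
#' permuted within the trial before W is recomputed; this requires
#' `third_counts`.
#'
#' @inheritParams signed_rank_stat
#' @param n_permutations Number of permutations (>= 100; default 1000).
#' @param seed Optional integer seed for reproducible nulls.
#' @param shuffle `"pairwise"` (default; label swap within the tested pair)
#'   or `"threeway"`.
#' @param third_counts Per-trial counts of the third epoch, only for
#'   `shuffle = "threeway"`.
#' @return Numeric vector of `n_permutations` null W values (all NA when
#'   every observed difference is zero).
#' @export
permutation_null <- function(baseline_counts, test_counts,
                             n_permutations = 1000, seed = NULL,
                             shuffle = c("pairwise", "threeway"),
                             third_counts = NULL) {
  shuffle <- match.arg(shuffle)
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (shuffle == "threeway") {
    if (is.null(third_counts)) stop("threeway shuffle requires third_counts")
    n <- length(baseline_counts)
    cnt <- cbind(baseline_counts, test_counts, third_counts)
    vapply(seq_len(n_permutations), function(k) {
      pick <- matrix(0L, n, 2)
      for (i in seq_len(n)) pick[i, ] <- sample.int(3, 2)
      b <- cnt[cbind(seq_len(n), pick[, 1])]
      t2 <- cnt[cbind(seq_len(n), pick[, 2])]
      signed_rank_stat(b, t2)$W %||% NA_real_
    }, numeric(1))
  } else {
    d <- test_counts - baseline_counts
    d <- d[d != 0]
    m <- length(d)
    if (m == 0) return(rep(NA_real_, n_permutations))
    r <- rank(abs(d))
    flips <- matrix(stats::runif(m * n_permutations) < 0.5, m, n_permutations)
    pos_after <- xor(flips, d > 0)
    as.vector(crossprod(r, pos_after))
  }
}

#' Test one firing-rate contrast for a unit
#'
#' Compares spike counts of a test epoch against the pre-trial baseline
#' epoch across trials of one condition, using the Wilcoxon signed-rank
#' statistic against a shuffled-epoch-label permutation null. A unit is
#' significant when the observed W lies outside the central `1 - alpha`
#' interval of the null (`decision = "interval"`, mirroring the
#' 95-percent shaded null band), or when the center-symmetric permutation
#' p-value falls below `alpha` (`decision = "pvalue"`). The permutation
#' p-value always carries the +1 correction, so it is bounded below by
#' `1 / (n_permutations + 1)`.
#'
#' @param counts An `epoch_counts` object from [count_spikes()], or a
#'   trials x epochs matrix with PRE/IMG/DUR/POST columns.
#' @param test_epoch `"DUR"`, `"POST"`, or `"IMG"`.
#' @param baseline_epoch Baseline epoch label (default `"PRE"`).
#' @param n_permutations,seed,shuffle Passed to [permutation_null()].
#' @param alpha Two-tailed significance level (default 0.05).
#' @param decision `"interval"` (default) or `"pvalue"`.
#' @return Object of class `modulation_result`: list with `W_observed`,
#'   `p_perm`, `significant`, `direction` (`"enhanced"`, `"suppressed"`,
#'   `"none"`), `mean_delta` (Hz), `z_effect` (see [zscored_effect()]),
#'   `null_interval`, and the contrast description.
#' @export
test_contrast <- function(counts, test_epoch = c("DUR", "POST", "IMG"),
                          baseline_epoch = "PRE", n_permutations = 1000,
                          alpha = 0.05, seed = NULL,
                          decision = c("interval", "pvalue"),
                          shuffle = c("pairwise", "threeway")) {
  test_epoch <- match.arg(test_epoch)
  decision <- match.arg(decision)
  shuffle <- match.arg(shuffle)
  if (test_epoch == baseline_epoch) stop("test epoch must differ from baseline")
  cm <- if (inherits(counts, "epoch_counts")) counts$counts else counts
  b <- cm[, baseline_epoch]
  x <- cm[, test_epoch]
  obs <- signed_rank_stat(b, x)
  mean_delta <- mean(x) - mean(b)  # 1 s windows: counts are rates in Hz
  z_eff <- zscored_effect(cm, test_epoch, baseline_epoch)
  res <- list(unit_id = if (inherits(counts, "epoch_counts")) counts$unit_id else NA,
              condition = if (inherits(counts, "epoch_counts")) counts$condition else NA,
              test_epoch = test_epoch, baseline_epoch = baseline_epoch,
              n_trials = length(b), n_permutations = n_permutations,
              alpha = alpha, decision = decision,
              W_observed = obs$W, mean_delta = mean_delta, z_effect = z_eff)
  if (is.na(obs$W)) {
    res$p_perm <- 1
    res$significant <- FALSE
    res$direction <- "none"
    res$null_interval <- c(NA_real_, NA_real_)
    res$degenerate <- TRUE
    class(res) <- "modulation_result"
    return(res)
  }
  third <- setdiff(c("PRE", "DUR", "POST", "IMG"),
                   c(baseline_epoch, test_epoch))[1]
  null <- permutation_null(b, x, n_permutations, seed = seed,
                           shuffle = shuffle,
                           third_counts = if (shuffle == "threeway") cm[, third])
  mu <- mean(null)
  res$p_perm <- (1 + sum(abs(null - mu) >= abs(obs$W - mu))) /
    (n_permutations + 1)
  lo <- stats::quantile(null, alpha / 2, names = FALSE)
  hi <- stats::quantile(null, 1 - alpha / 2, names = FALSE)
  res$null_interval <- c(lo, hi)
  res$significant <- if (decision == "interval") obs$W < lo || obs$W > hi
                     else res$p_perm < alpha
  res$direction <- if (!res$significant) "none"
                   else if (mean_delta > 0) "enhanced" else "suppressed"
  res$degenerate <- FALSE
  class(res) <- "modulation_result"
  res
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (%s trials, n = %d): W = %s, p_perm = %.4g, %s%s\n",
    x$baseline_epoch, x$test_epoch, format(x$condition), x$n_trials,
    format(x$W_observed), x$p_perm,
    if (x$significant) sprintf("significant (%s)", x$direction)
    else "not significant",
    if (isTRUE(x$degenerate)) " [degenerate: all differences zero]" else ""))
  invisible(x)
}

#' Z-scored firing-rate effect
#'
#' Mean test-epoch rate minus mean baseline (PRE) rate, in units of the
#' across-trial SD of the baseline rates. Undefined (NA) when the baseline
#' SD is zero; such units are excluded from group effect-size summaries.
#'
#' @param counts `epoch_counts` or trials x epochs count matrix.
#' @param test_epoch Epoch to score.
#' @param baseline_epoch Baseline epoch (default PRE).
#' @return Dimensionless z, or NA.
#' @export
zscored_effect <- function(counts, test_epoch, baseline_epoch = "PRE") {
  cm <- if (inherits(counts, "epoch_counts")) counts$counts else counts
  s <- stats::sd(cm[, baseline_epoch])
  if (is.na(s) || s == 0) return(NA_real_)
  (mean(cm[, test_epoch]) - mean(cm[, baseline_epoch])) / s
}

#' Classify a unit's modulation epoch pattern
#'
#' A unit is "modulated" when its during- or post-stimulation contrast is
#' significant; the epoch class records which. Image responsiveness is
#' carried separately from the PRE-vs-IMG contrast.
#'
#' @param dur_result,post_result,img_result `modulation_result` objects for
#'   the DUR, POST and (optionally) IMG contrasts of one unit x condition.
#' @return List with `epoch_class` (`"none"`, `"during_only"`,
#'   `"post_only"`, `"both"`), `modulated` (flag), and `image_responsive`.
#' @export
classify_unit <- function(dur_result, post_result, img_result = NULL) {
  d <- isTRUE(dur_result$significant)
  p <- isTRUE(post_result$significant)
  epoch_class <- if (d && p) "both" else if (d) "during_only"
                 else if (p) "post_only" else "none"
  list(epoch_class = epoch_class, modulated = d || p,
       image_responsive = isTRUE(img_result$significant))
}

#' Run the modulation pipeline over a cohort of units
#'
#' Applies the baseline inclusion filter, then tests the PRE-vs-DUR,
#' PRE-vs-POST and PRE-vs-IMG contrasts within each condition for every
#' included unit, and classifies each unit's modulation pattern. Per-unit
#' permutation seeds are derived deterministically from the master seed.
#'
#' @param units List of `unit_record`s (or of sorted spike-time vectors), or
#'   a `tbs_cohort` from [simulate_cohort()] (its schedule is then used).
#' @param schedule A [build_trial_schedule()] result (ignored for cohorts).
#' @param threshold Baseline inclusion threshold in Hz.
#' @param n_permutations,alpha,decision Passed to [test_contrast()].
#' @param seed Master seed for the permutation nulls.
#' @param contrasts Test epochs to run (default DUR, POST, IMG).
#' @return Object of class `modulation_analysis`: list with `units` (one
#'   row per unit: id, region, baseline rate, inclusion flag, per-condition
#'   epoch class and image responsiveness) and `contrasts` (long data frame
#'   of every test performed).
#' @export
analyze_units <- function(units, schedule = NULL, threshold = 0.1,
                          n_permutations = 1000, alpha = 0.05, seed = 1,
                          decision = "interval",
                          contrasts = c("DUR", "POST", "IMG")) {
  if (inherits(units, "tbs_cohort")) {
    schedule <- units$schedule
    units <- units$units
  }
  if (is.null(schedule)) stop("a trial schedule is required")
  ids <- vapply(seq_along(units), function(i) {
    u <- units[[i]]
    if (inherits(u, "unit_record")) as.character(u$unit_id) else sprintf("u%03d", i)
  }, character(1))
  regions <- vapply(units, function(u)
    if (inherits(u, "unit_record")) u$region else NA_character_, character(1))
  base <- vapply(units, baseline_rate, numeric(1), schedule = schedule)
  inc <- include_units(base, threshold)

  unit_rows <- list()
  contrast_rows <- list()
  for (i in seq_along(units)) {
    row <- list(unit_id = ids[i], region = regions[i], baseline_rate = base[i],
                included = inc$included[i])
    if (inc$included[i]) {
      for (cond in c("stim", "no_stim")) {
        ec <- count_spikes(units[[i]], schedule, cond)
        res <- lapply(contrasts, function(ep) {
          test_contrast(ec, test_epoch = ep,
                        n_permutations = n_permutations, alpha = alpha,
                        seed = derive_seed(seed, i, cond, ep),
                        decision = decision)
        })
        names(res) <- contrasts
        cls <- classify_unit(res[["DUR"]], res[["POST"]], res[["IMG"]])
        row[[paste0("epoch_class_", cond)]] <- cls$epoch_class
        row[[paste0("modulated_", cond)]] <- cls$modulated
        row[[paste0("image_responsive_", cond)]] <- cls$image_responsive
        for (ep in contrasts) {
          r <- res[[ep]]
          contrast_rows[[length(contrast_rows) + 1]] <- data.frame(
            unit_id = ids[i], region = regions[i], condition = cond,
            contrast = paste0("PRE_vs_", ep), W = r$W_observed,
            p_perm = r$p_perm, significant = r$significant,
            direction = r$direction, mean_delta = r$mean_delta,
            z_effect = r$z_effect)
        }
      }
    }
    unit_rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- list(units = do.call(rbind_fill, list(unit_rows)),
              contrasts = if (length(contrast_rows))
                do.call(rbind, contrast_rows) else NULL,
              threshold = threshold, inclusion = inc,
              n_permutations = n_permutations, alpha = alpha, seed = seed)
  class(out) <- "modulation_analysis"
  out
}

# rbind a list of one-row data frames that may differ in columns
rbind_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  }))
}

derive_seed <- function(master, i, cond, epoch) {
  offs <- match(cond, c("stim", "no_stim")) * 1000003L +
    match(epoch, c("DUR", "POST", "IMG")) * 10007L
  as.integer((as.numeric(master) + 7919 * i + offs) %% 2147483629)
}

#' @export
print.modulation_analysis <- function(x, ...) {
  s <- summarize_modulation(x)
  cat(sprintf("Modulation analysis: %d units, %d included (threshold %.2g Hz)\n",
              x$inclusion$n_total, sum(x$units$included), x$threshold))
  print(s)
  invisible(x)
}

#' Summarize modulated proportions
#'
#' Per-condition counts and percentages of modulated units among the
#' included units, plus the exclusion report; every percentage goes through
#' the reporting helper [proportion_pct()].
#'
#' @param analysis A `modulation_analysis` from [analyze_units()].
#' @return Data frame with one row per condition: `n_modulated`,
#'   `n_included`, `pct_modulated`, plus rows for exclusion and
#'   stim-and-image overlap.
#' @export
summarize_modulation <- function(analysis) {
  u <- analysis$units
  inc <- u[u$included, , drop = FALSE]
  n_inc <- nrow(inc)
  rows <- list()
  for (cond in c("stim", "no_stim")) {
    k <- sum(inc[[paste0("modulated_", cond)]], na.rm = TRUE)
    rows[[cond]] <- data.frame(measure = paste0("modulated_", cond),
                               n = k, total = n_inc,
                               pct = proportion_pct(k, n_inc))
  }
  k_both <- sum(inc$modulated_stim & inc$modulated_no_stim, na.rm = TRUE)
  rows$both <- data.frame(measure = "modulated_both_conditions", n = k_both,
                          total = n_inc, pct = proportion_pct(k_both, n_inc))
  k_img <- sum(inc$modulated_stim & inc$image_responsive_no_stim, na.rm = TRUE)
  rows$img <- data.frame(measure = "stim_modulated_and_image_responsive",
                         n = k_img, total = n_inc,
                         pct = proportion_pct(k_img, n_inc))
  rows$exc <- data.frame(measure = "excluded_low_baseline",
                         n = analysis$inclusion$n_excluded,
                         total = analysis$inclusion$n_total,
                         pct = analysis$inclusion$pct_excluded)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
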