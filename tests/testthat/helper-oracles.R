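# Independent brute-force oracles used across test files.

# interval-membership spike counting, one trial x epoch at a time
brute_force_counts <- function(spike_times, schedule, condition = "both") {
  keep <- if (condition == "both") rep(TRUE, nrow(schedule))
          else schedule$condition == condition
  sub <- schedule[keep, , drop = FALSE]
  out <- matrix(0L, nrow(sub), 4, dimnames = list(NULL, c("PRE", "IMG", "DUR", "POST")))
  for (i in seq_len(nrow(sub))) {
    on <- sub$image_onset[i]; t0 <- sub$image_offset[i]
    win <- list(PRE = c(on - 1, on), IMG = c(on, on + 1),
                DUR = c(t0, t0 + 1), POST = c(t0 + 1, t0 + 2))
    for (e in names(win))
      out[i, e] <- sum(spike_times >= win[[e]][1] & spike_times < win[[e]][2])
  }
  out
}

# hand-computed signed-rank W: rank |nonzero diffs| with midranks,
# sum ranks of positive diffs
brute_force_W <- function(baseline, test) {
  d <- test - baseline
  d <- d[d != 0]
  if (!length(d)) return(NA_real_)
  sum(rank(abs(d))[d > 0])
}

# exhaustive 2^m sign-flip null distribution of W
exhaustive_signflip_null <- function(baseline, test) {
  d <- test - baseline
  d <- d[d != 0]
  m <- length(d)
  stopifnot(m <= 12)
  r <- rank(abs(d))
  flips <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  apply(flips, 1, function(fl) sum(r[xor(unlist(fl), d > 0) ]))
}

# a small schedule + spike train pair for reuse
quick_schedule <- function(n_trials = 20, seed = 11) {
  build_trial_schedule(n_trials, seed = seed)
}

withr_local_tempdir <- function() {
  d <- tempfile("tbsmod")
  dir.create(d)
  d
}
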