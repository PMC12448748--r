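#' Waveform morphology metrics
#'
#' Computes the two metrics used to discriminate presumed cell types from a
#' unit's averaged spike waveform: the valley-to-peak width (VP, time from
#' the global valley to the subsequent maximum) and the peak half-width
#' (PHW, width of the post-valley peak at half its height above the zero
#' line). The half-height crossings are refined below the sample period by
#' linear interpolation. Fast-spiking (putative inhibitory) units have
#' short VP and PHW.
#'
#' @param mean_waveform Numeric amplitude series (averaged waveform).
#' @param fs Sampling rate in Hz.
#' @param refine Linear sub-sample interpolation of half-height crossings
#'   (default TRUE).
#' @return List with `VP` and `PHW` in ms, or both `NA` (with `failure`
#'   message) when the waveform lacks a valley-then-peak structure; such
#'   units are excluded from clustering.
#' @export
waveform_metrics <- function(mean_waveform, fs, refine = TRUE) {
  w <- as.numeric(mean_waveform)
  n <- length(w)
  fail <- function(msg) list(VP = NA_real_, PHW = NA_real_, failure = msg)
  if (n < 3 || all(w == w[1])) return(fail("flat waveform"))
  iv <- which.min(w)
  if (length(which(w == w[iv])) > 1) return(fail("non-unique global valley"))
  if (iv >= n - 1) return(fail("no samples after the valley"))
  post <- w[(iv + 1):n]
  ip <- iv + which.max(post)
  # a residual tail is not a peak: require a substantive positive deflection
  if (w[ip] <= 0.05 * abs(w[iv])) return(fail("no positive post-valley peak"))
  if (ip == n && post[length(post) - 1] < post[length(post)])
    return(fail("peak not resolved within the waveform"))
  vp_ms <- (ip - iv) / fs * 1000

  half <- w[ip] / 2
  # left crossing: last sample below half before the peak
  li <- max(which(w[1:ip] < half))
  # right crossing: first sample below half after the peak
  right <- which(w[(ip + 1):n] < half)
  if (!length(right)) return(fail("peak right flank not resolved"))
  ri <- ip + right[1]
  if (refine) {
    tl <- li + (half - w[li]) / (w[li + 1] - w[li])
    tr <- (ri - 1) + (half - w[ri - 1]) / (w[ri] - w[ri - 1])
  } else {
    tl <- li
    tr <- ri
  }
  list(VP = vp_ms, PHW = (tr - tl) / fs * 1000, failure = NULL)
}

#' Spike-train and waveform quality metrics
#'
#' The standard single-unit curation panel: mean firing rate, percentage of
#' interspike intervals (ISIs) under 3 ms (refractory violations),
#' coefficient of variation of the ISIs, presence ratio (fraction of
#' consecutive 1 s bins spanning the session that contain at least one
#' spike), peak amplitude of the averaged waveform over its standard
#' deviation, and waveform signal-to-noise ratio. When a waveform bank is
#' supplied, the waveform SD and noise are taken across spikes; otherwise
#' they fall back to the spread of the mean waveform itself.
#'
#' @param unit A `unit_record`.
#' @param session_span Length-2 numeric `c(start, end)` in seconds (see
#'   [session_span()]).
#' @param waveform_bank Optional n_spikes x samples matrix of individual
#'   waveforms.
#' @param units_per_bundle Number of units isolated on the same microwire
#'   bundle (bookkeeping; default NA).
#' @return List of class `quality_metrics`; ISI-based entries are NA with
#'   fewer than two spikes.
#' @export
quality_metrics <- function(unit, session_span, waveform_bank = NULL,
                            units_per_bundle = NA_integer_) {
  st <- unit$spike_times
  span <- diff(session_span)
  stopifnot(span > 0)
  mean_rate <- length(st) / span
  if (length(st) >= 2) {
    isi <- diff(st)
    isi_violation_pct <- 100 * mean(isi < 0.003)
    cv <- stats::sd(isi) / mean(isi)
  } else {
    isi_violation_pct <- NA_real_
    cv <- NA_real_
  }
  bins <- seq(session_span[1], session_span[2], by = 1)
  if (bins[length(bins)] < session_span[2]) bins <- c(bins, session_span[2])
  occupied <- tabulate(findInterval(st, bins, rightmost.closed = TRUE),
                       nbins = length(bins) - 1) > 0
  presence_ratio <- mean(occupied)
  wf <- unit$mean_waveform
  peak_to_sd <- snr <- NA_real_
  if (!is.null(wf)) {
    if (!is.null(waveform_bank)) {
      sds <- apply(waveform_bank, 2, stats::sd)
      peak_to_sd <- max(abs(wf)) / mean(sds)
      snr <- (max(wf) - min(wf)) / (2 * mean(sds))
    } else {
      peak_to_sd <- max(abs(wf)) / stats::sd(wf)
      snr <- (max(wf) - min(wf)) / (2 * stats::sd(wf))
    }
  }
  structure(list(unit_id = unit$unit_id, units_per_bundle = units_per_bundle,
                 mean_rate = mean_rate, isi_violation_pct = isi_violation_pct,
                 cv = cv, presence_ratio = presence_ratio,
                 peak_to_sd = peak_to_sd, snr = snr),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf(
    "Unit %s: %.3g Hz, ISI<3ms %.2g%%, CV %.3g, presence %.3g, peak/SD %.3g, SNR %.3g\n",
    format(x$unit_id), x$mean_rate, x$isi_violation_pct, x$cv,
    x$presence_ratio, x$peak_to_sd, x$snr))
  invisible(x)
}

#' Cluster units into presumed excitatory / inhibitory classes
#'
#' K-means (k = 2 by default) on the (VP, PHW) plane in raw milliseconds,
#' with multiple seeded restarts keeping the solution with the lowest
#' within-cluster sum of squares. The cluster with the shorter mean VP is
#' labeled I (fast-spiking, putative inhibitory), the other E
#' (regular-spiking, putative excitatory). Units with failed metrics (NA)
#' are dropped before clustering and reported.
#'
#' @param metrics Data frame with columns `VP` and `PHW` (ms) and
#'   optionally `unit_id`.
#' @param k Number of clusters (default 2).
#' @param n_restarts Restarts for [stats::kmeans()] (default 50).
#' @param seed Optional integer seed.
#' @param standardize Z-score VP and PHW before clustering (default FALSE:
#'   both metrics share units and comparable ranges).
#' @return List of class `celltype_clusters`: `labels` (factor E/I aligned
#'   to the input rows, NA where metrics failed), `centroids` (k x 2 matrix
#'   in ms, rows named by label), `sizes`, `tot_withinss`, `dropped`.
#' @export
cluster_celltypes <- function(metrics, k = 2, n_restarts = 50, seed = NULL,
                              standardize = FALSE) {
  stopifnot(all(c("VP", "PHW") %in% names(metrics)))
  ok <- stats::complete.cases(metrics[, c("VP", "PHW")])
  x <- as.matrix(metrics[ok, c("VP", "PHW")])
  if (nrow(x) < k) stop("need at least k units with valid metrics")
  if (nrow(unique(x)) < k)
    stop("fewer distinct metric points than clusters; clustering degenerate")
  xc <- if (standardize) scale(x) else x
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(xc, centers = k, nstart = n_restarts, iter.max = 100)
  cent <- km$centers
  if (standardize)
    cent <- sweep(sweep(cent, 2, attr(xc, "scaled:scale"), `*`), 2,
                  -attr(xc, "scaled:center"), `-`)
  # shorter valley-to-peak -> fast-spiking (I)
  ord <- order(cent[, "VP"])
  lab_for <- rep("E", k)
  lab_for[ord[1]] <- "I"
  labels <- rep(NA_character_, nrow(metrics))
  labels[ok] <- lab_for[km$cluster]
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- lab_for[ord]
  structure(list(labels = factor(labels, levels = c("E", "I")),
                 centroids = cent,
                 sizes = table(factor(lab_for[km$cluster],
                                      levels = c("E", "I"))),
                 tot_withinss = km$tot.withinss, dropped = sum(!ok)),
            class = "celltype_clusters")
}

#' @export
print.celltype_clusters <- function(x, ...) {
  cat(sprintf("Cell-type clusters: %d E, %d I (%d dropped)\n",
              x$sizes["E"], x$sizes["I"], x$dropped))
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
plot.celltype_clusters <- function(x, metrics, ...) {
  ok <- !is.na(x$labels)
  graphics::plot(metrics$VP[ok], metrics$PHW[ok],
                 col = ifelse(x$labels[ok] == "I", "firebrick", "steelblue"),
                 pch = 19, xlab = "Valley-to-peak width (ms)",
                 ylab = "Peak half-width (ms)", ...)
  graphics::points(x$centroids[, "VP"], x$centroids[, "PHW"], pch = 4,
                   cex = 2, lwd = 2)
  invisible(x)
}
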