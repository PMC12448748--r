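#' Recognition-memory sensitivity (d')
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. Extreme rates (0 or 1)
#' would give infinite d'; the default correction is the log-linear rule
#' (add 0.5 to every cell and 1 to every total of the affected rate), the
#' alternative clamps extreme rates to `1/(2n)` / `1 - 1/(2n)`. A
#' correction is applied only to a rate that is exactly 0 or 1.
#'
#' @param hits,misses Old-image outcome counts (hits + misses = n old).
#' @param false_alarms,correct_rejections New-image outcome counts.
#' @param correction `"loglinear"` (default) or `"clamp"`.
#' @return List with `d_prime`, `hit_rate`, `fa_rate` (after correction),
#'   and `corrected` flag.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  n_old <- hits + misses
  n_new <- false_alarms + correct_rejections
  if (n_old < 1 || n_new < 1) stop("at least one old and one new image required")
  fix_rate <- function(k, n) {
    r <- k / n
    if (r > 0 && r < 1) return(list(r = r, fixed = FALSE))
    r <- switch(correction,
                loglinear = (k + 0.5) / (n + 1),
                clamp = min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n)))
    list(r = r, fixed = TRUE)
  }
  h <- fix_rate(hits, n_old)
  f <- fix_rate(false_alarms, n_new)
  list(d_prime = stats::qnorm(h$r) - stats::qnorm(f$r),
       hit_rate = h$r, fa_rate = f$r, corrected = h$fixed || f$fixed)
}

#' Classify a session's stimulation response
#'
#' Sessions are split by the change in d' between conditions using a
#' threshold of +/- 0.5 (the conventional medium-effect magnitude):
#' positive responder above +0.5, negative responder below -0.5,
#' non-responder inside the closed interval.
#'
#' @param delta_d `d'(stim) - d'(no_stim)`; finite, vectorized.
#' @return Character vector in `{"positive", "negative", "non_responder"}`.
#' @export
classify_responder <- function(delta_d) {
  stopifnot(all(is.finite(delta_d)))
  ifelse(delta_d > 0.5, "positive",
         ifelse(delta_d < -0.5, "negative", "non_responder"))
}

#' Fisher's exact test with the sample odds ratio
#'
#' The p-value comes from the hypergeometric distribution
#' ([stats::fisher.test()]); the reported odds ratio is the sample odds
#' ratio `a*d / (b*c)` (not the conditional maximum-likelihood estimate),
#' infinite when `b*c = 0` with `a*d > 0` and undefined (NA) when a margin
#' is zero.
#'
#' @param a,b,c,d Non-negative counts; rows are groups, columns outcome
#'   yes/no, i.e. the table is `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two.sided"`, `"greater"` (odds ratio > 1) or
#'   `"less"`.
#' @return List with `odds_ratio`, `p_value`, `table`, `alternative`.
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  tab <- matrix(c(a, c, b, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab,
                alternative = alternative, degenerate = TRUE))
  }
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(odds_ratio = or, p_value = p, table = tab,
       alternative = alternative, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Rank-sum U for the first group with midrank tie handling. The p-value is
#' exact (full enumeration of group assignments, valid under ties) when
#' `n_a + n_b <= 12`, otherwise a two-sided normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `U` (for `group_a`), `U_b`, `p_value`, `method`.
#' @export
mann_whitney <- function(group_a, group_b) {
  na <- length(group_a)
  nb <- length(group_b)
  stopifnot(na >= 1, nb >= 1)
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 12) {
    pooled <- c(group_a, group_b)
    rs <- rank(pooled)
    combos <- utils::combn(na + nb, na)
    us <- apply(combos, 2, function(ix) sum(rs[ix]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- na + nb
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    mu <- na * nb / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "normal approximation with tie correction"
  }
  list(U = U, U_b = na * nb - U, p_value = p, method = method)
}

#' Linear mixed model for d' across conditions
#'
#' Fits `d_prime ~ condition + experiment + (1 | session_id)` by restricted
#' maximum likelihood ([lme4::lmer()]). When the session variance is
#' estimated at (numerically) zero the fit is singular and the model falls
#' back to ordinary least squares with a flag. The condition effect is the
#' stim-minus-no-stim fixed effect with a Wald 95% interval.
#'
#' @param sessions Data frame with one row per session x condition and
#'   columns `session_id`, `condition`, `d_prime`, optionally `experiment`.
#' @return List of class `dprime_model`: `condition_estimate`, `conf_int`,
#'   `se`, `p_value` (Wald normal), `variance_components`, `singular`
#'   flag, and the fitted model.
#' @export
mixed_model_dprime <- function(sessions) {
  stopifnot(all(c("session_id", "condition", "d_prime") %in% names(sessions)))
  if (length(unique(sessions$session_id)) < 2)
    stop("at least two sessions required")
  sessions$condition <- stats::relevel(factor(sessions$condition), "no_stim")
  multi_exp <- !is.null(sessions$experiment) &&
    length(unique(sessions$experiment)) > 1
  form <- if (multi_exp)
    d_prime ~ condition + experiment + (1 | session_id)
  else d_prime ~ condition + (1 | session_id)
  fit <- suppressMessages(lme4::lmer(form, data = sessions, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    form2 <- if (multi_exp) d_prime ~ condition + experiment
             else d_prime ~ condition
    ols <- stats::lm(form2, data = sessions)
    co <- summary(ols)$coefficients["conditionstim", ]
    est <- co["Estimate"]
    se <- co["Std. Error"]
    vc <- c(session = 0, residual = summary(ols)$sigma^2)
    model <- ols
  } else {
    co <- summary(fit)$coefficients["conditionstim", ]
    est <- co["Estimate"]
    se <- co["Std. Error"]
    v <- as.data.frame(lme4::VarCorr(fit))
    vc <- stats::setNames(v$vcov, ifelse(is.na(v$grp), "residual", v$grp))
    model <- fit
  }
  z <- est / se
  structure(list(condition_estimate = unname(est),
                 conf_int = unname(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 se = unname(se),
                 p_value = unname(2 * stats::pnorm(abs(z), lower.tail = FALSE)),
                 variance_components = vc, singular = singular,
                 model = model),
            class = "dprime_model")
}

#' @export
print.dprime_model <- function(x, ...) {
  cat(sprintf(
    "Condition (stim - no_stim) effect on d': %.3f [%.3f, %.3f], p = %.3g%s\n",
    x$condition_estimate, x$conf_int[1], x$conf_int[2], x$p_value,
    if (x$singular) " (singular fit; OLS fallback)" else ""))
  invisible(x)
}

#' Paired t-test on per-session hit rates
#'
#' @param sessions Data frame as in [mixed_model_dprime()] with `hits` and
#'   `misses` columns (hit rate = hits / (hits + misses)).
#' @return List with `t`, `df`, `p_value`, `mean_difference`
#'   (stim - no_stim), `degenerate` flag (zero-variance differences).
#' @export
hit_rate_ttest <- function(sessions) {
  wide <- merge(
    sessions[sessions$condition == "stim",
             c("session_id", "hits", "misses")],
    sessions[sessions$condition == "no_stim",
             c("session_id", "hits", "misses")],
    by = "session_id", suffixes = c("_stim", "_nostim"))
  if (nrow(wide) < 2) stop("at least two paired sessions required")
  hr_s <- wide$hits_stim / (wide$hits_stim + wide$misses_stim)
  hr_n <- wide$hits_nostim / (wide$hits_nostim + wide$misses_nostim)
  d <- hr_s - hr_n
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = length(d) - 1, p_value = 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(hr_s, hr_n, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(d), degenerate = FALSE)
}

#' Per-session behavioral summary
#'
#' Collapses a session x condition table into one row per session with
#' per-condition d', the d' difference, and the responder category.
#'
#' @param sessions Data frame from [simulate_behavior()] or equivalent.
#' @return Data frame with `session_id`, `experiment`, `d_stim`,
#'   `d_no_stim`, `delta_d`, `responder`.
#' @export
behavior_summary <- function(sessions) {
  s <- sessions[sessions$condition == "stim", ]
  n <- sessions[sessions$condition == "no_stim", ]
  m <- merge(s[, c("session_id", "experiment", "d_prime")],
             n[, c("session_id", "d_prime")],
             by = "session_id", suffixes = c("_stim", "_no_stim"))
  out <- data.frame(session_id = m$session_id, experiment = m$experiment,
                    d_stim = m$d_prime_stim, d_no_stim = m$d_prime_no_stim,
                    delta_d = m$d_prime_stim - m$d_prime_no_stim)
  out$responder <- classify_responder(out$delta_d)
  out
}
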