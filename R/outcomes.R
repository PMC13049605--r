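#' Lifetime acute-coronary-event NTCP from mean heart dose
#'
#' Linear relative-risk form of the Darby-type model: the lifetime risk is
#' the baseline lifetime risk (supplied, from age, sex and risk factors;
#' patients younger than 40 are evaluated at age 40 by the baseline-input
#' contract) increased by a constant relative excess per Gy(RBE) of mean
#' heart dose:
#' `risk = baseline * (1 + coefficient * MHD)`.
#'
#' @param mhd mean heart dose in Gy(RBE), >= 0.
#' @param params a [ace_model_params()].
#' @return lifetime risk in percent.
#' @export
ace_ntcp <- function(mhd, params = ace_model_params()) {
  if (any(mhd < 0)) stop("mean heart dose must be >= 0")
  params$baseline_lifetime_risk * (1 + params$excess_rate_per_gy * mhd)
}

#' Parameters of the acute-coronary-event risk model
#'
#' @param baseline_lifetime_risk baseline lifetime ACE risk in percent
#'   (derived upstream from age, sex and risk factors; an age floor of 40
#'   years applies to that derivation).
#' @param excess_rate_per_gy relative excess risk per Gy(RBE) of mean heart
#'   dose (default 0.074, i.e. 7.4 %/Gy).
#' @param age_floor_years informational; the model is validated for age
#'   >= 40 and younger patients are evaluated at 40.
#' @return An `ace_model_params` list.
#' @export
ace_model_params <- function(baseline_lifetime_risk = 10,
                             excess_rate_per_gy = 0.074,
                             age_floor_years = 40) {
  if (baseline_lifetime_risk < 0) stop("baseline risk must be >= 0")
  if (excess_rate_per_gy < 0) stop("excess rate must be >= 0")
  structure(list(baseline_lifetime_risk = baseline_lifetime_risk,
                 excess_rate_per_gy = excess_rate_per_gy,
                 age_floor_years = age_floor_years),
            class = "ace_model_params")
}

#' Excess risk between photon and proton plans, and the selection gate
#'
#' `delta_ntcp()` is the photon-plan risk minus the proton-plan risk;
#' `mbs_gate()` implements the national model-based selection threshold:
#' the patient qualifies for protons when the excess risk is at least 2 %.
#'
#' @param photon_mhd,proton_mhd mean heart doses in Gy(RBE).
#' @param params a [ace_model_params()].
#' @return `delta_ntcp`: excess risk in percent; `mbs_gate`: logical.
#' @export
delta_ntcp <- function(photon_mhd, proton_mhd, params = ace_model_params()) {
  ace_ntcp(photon_mhd, params) - ace_ntcp(proton_mhd, params)
}

#' @rdname delta_ntcp
#' @param delta excess risk in percent.
#' @param threshold_pct gate threshold (default 2 %).
#' @export
mbs_gate <- function(delta, threshold_pct = 2) {
  delta >= threshold_pct
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on paired differences.  Zero differences are
#' dropped; ties receive average ranks.  For n <= `exact_max` non-zero
#' differences the p-value is computed from the exact null distribution of
#' the signed-rank sum via a generating-function convolution over the
#' (doubled, hence integer) ranks, which remains exact in the presence of
#' ties; above that, a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y paired samples, or `x` a vector of differences if `y` is NULL.
#' @param exact_max largest n for the exact distribution (default 25).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used`, `method`, and `warning` (non-NULL for degenerate input).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n_used = 0L,
                method = "undefined", warning = "all differences are zero"))
  }
  warn <- if (n < 5) "fewer than 5 non-zero differences" else NULL
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null distribution over doubled ranks (integers even with ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)   # f[s + 1] = #assignments with doubled sum s
    f[1] <- 1
    for (ri in r2) {
      f[(ri + 1):(total + 1)] <- f[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
    }
    probs <- f / sum(f)
    v2 <- as.integer(round(2 * v))
    lo <- sum(probs[seq_len(v2 + 1)])             # P(V2 <= v2)
    hi <- sum(probs[(v2 + 1):(total + 1)])        # P(V2 >= v2)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = v, p_value = p, n_used = n, method = method,
       warning = warn)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise alpha divided by the number of comparisons; the displayed
#' value is rounded to 3 decimals (0.05 over 3 comparisons displays as
#' 0.017) while the unrounded value is kept for internal comparisons.
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons (>= 1).
#' @return list with `alpha_corrected` and `alpha_displayed`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  a <- alpha / m
  list(alpha_corrected = a, alpha_displayed = round(a, 3))
}

#' Median (range) summary in table style
#'
#' @param values non-empty numeric vector.
#' @param digits decimals used in the formatted string (default 1, matching
#'   the reporting style of the dose tables).
#' @return list with `median`, `min`, `max`, and `formatted`
#'   ("median (min-max)" with an en dash).
#' @export
summarize_median_range <- function(values, digits = 1) {
  if (!length(values)) stop("empty input")
  md <- median(values)
  fmt <- paste0("%.", digits, "f")
  list(median = md, min = min(values), max = max(values),
       formatted = sprintf(paste0(fmt, " (", fmt, "–", fmt, ")"),
                           md, min(values), max(values)))
}

#' Paired comparison across two settings
#'
#' Convenience wrapper producing the test summary used in the study report.
#'
#' @param metric_name label.
#' @param a,b paired per-patient values at two settings.
#' @param alpha_corrected corrected significance threshold.
#' @return one-row data.frame with the median difference, p-value and
#'   significance verdict.
#' @export
paired_comparison <- function(metric_name, a, b, alpha_corrected) {
  stopifnot(length(a) == length(b))
  t <- wilcoxon_signed_rank(a, b)
  data.frame(metric = metric_name, n = length(a),
             median_diff = median(a - b), p_value = t$p_value,
             significant = !is.na(t$p_value) && t$p_value < alpha_corrected)
}
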