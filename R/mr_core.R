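#' Wald ratio causal estimate at a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order delta-method standard
#' error `se = se_out / |beta_exp|` (uncertainty in the exposure effect is
#' ignored, the standard default for two-sample ratio methods; see
#' `second_order` for the correction).
#'
#' @param beta_exp,se_exp Exposure effect and SE.
#' @param beta_out,se_out Outcome effect and SE.
#' @param second_order Add the second-order term
#'   `beta_out^2 * se_exp^2 / beta_exp^4` to the variance.
#' @return List with `beta` and `se` (vectorized over instruments).
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, second_order = FALSE) {
  if (any(beta_exp == 0)) stopf("degenerate instrument: beta_exp == 0")
  b <- beta_out / beta_exp
  v <- se_out^2 / beta_exp^2
  if (second_order) v <- v + beta_out^2 * se_exp^2 / beta_exp^4
  list(beta = b, se = sqrt(v))
}

#' Cochran's Q heterogeneity test across instrument-level estimates
#'
#' `Q = sum(w_i * (b_i - beta_ivw)^2)` referred to a chi-square with `k - 1`
#' degrees of freedom.
#'
#' @param b Per-instrument ratio estimates.
#' @param se Their standard errors (weights are `1/se^2`).
#' @param beta_ivw Pooled estimate; recomputed from `b`, `se` if omitted.
#' @return List with `Q`, `df`, `pvalue`; all `NA` when fewer than 2
#'   instruments are supplied.
#' @export
cochran_q <- function(b, se, beta_ivw = NULL) {
  k <- length(b)
  if (k < 2L) return(list(Q = NA_real_, df = NA_integer_, pvalue = NA_real_))
  w <- 1 / se^2
  if (is.null(beta_ivw)) beta_ivw <- sum(w * b) / sum(w)
  Q <- sum(w * (b - beta_ivw)^2)
  list(Q = Q, df = k - 1L, pvalue = stats::pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' Inverse-variance-weighted meta-analysis of per-instrument Wald ratios
#'
#' Fixed-effect pooling of ratio estimates with weights `1/se_i^2`. When
#' Cochran's Q signals heterogeneity (`p <= het_p`), the standard error is
#' inflated multiplicatively by `sqrt(max(1, Q/(k-1)))` (multiplicative
#' random effects, floored at the fixed-effect SE) and the method is
#' labelled `ivw_random`.
#'
#' @param pairs Harmonized pairs (columns `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`), at least two rows.
#' @param het_p Q p-value at or below which random effects are used.
#' @return List with `beta`, `se`, `pvalue`, `method`, `cochran_q`,
#'   `q_pvalue`, `n_snps`.
#' @export
ivw <- function(pairs, het_p = 0.05) {
  k <- nrow(pairs)
  if (k < 2L)
    stopf("ivw requires >= 2 instruments; use wald_ratio for a single instrument")
  wr <- wald_ratio(pairs$beta_exp, pairs$se_exp, pairs$beta_out, pairs$se_out)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- cochran_q(wr$beta, wr$se, beta)
  method <- "ivw_fixed"
  if (!is.na(q$pvalue) && q$pvalue <= het_p) {
    se <- se * sqrt(max(1, q$Q / (k - 1)))
    method <- "ivw_random"
  }
  list(beta = beta, se = se,
       pvalue = 2 * stats::pnorm(-abs(beta / se)),
       method = method, cochran_q = q$Q, q_pvalue = q$pvalue, n_snps = k)
}

#' MR-Egger intercept test for directional horizontal pleiotropy
#'
#' Instruments are first oriented so every exposure effect is non-negative
#' (both betas flipped where needed), then outcome effects are regressed on
#' exposure effects with an intercept, weighted by `1/se_out^2`. A nonzero
#' intercept indicates directional pleiotropy; p is two-sided from a t
#' distribution with `k - 2` degrees of freedom.
#'
#' @param pairs Harmonized pairs, at least three rows.
#' @return List with `intercept`, `se`, `pvalue`, `slope`; or
#'   `list(reason = "insufficient_snps")` when `k < 3`.
#' @export
egger_intercept <- function(pairs) {
  k <- nrow(pairs)
  if (k < 3L) return(list(intercept = NA_real_, se = NA_real_,
                          pvalue = NA_real_, slope = NA_real_,
                          reason = "insufficient_snps"))
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  bx <- pairs$beta_exp * flip
  by <- pairs$beta_out * flip
  fit <- stats::lm(by ~ bx, weights = 1 / pairs$se_out^2)
  sm <- summary(fit)
  cf <- sm$coefficients
  intercept <- cf[1, 1]
  # perfect (noise-free) fit: zero residual variance makes the t-ratio 0/0;
  # no residual scatter means no evidence against the fitted intercept
  if (sm$sigma < 1e-10 * max(abs(by), 1)) {
    p <- if (abs(intercept) < 1e-10 * max(abs(by), 1)) 1 else 0
    return(list(intercept = intercept, se = 0, pvalue = p, slope = cf[2, 1]))
  }
  list(intercept = intercept, se = cf[1, 2],
       pvalue = 2 * stats::pt(-abs(intercept / cf[1, 2]), df = k - 2),
       slope = cf[2, 1])
}

#' Steiger directionality test
#'
#' Compares the variance in exposure vs outcome explained by the instrument
#' set, using the per-SNP approximation `r2_i = z_i^2 / (z_i^2 + n - 2)`
#' summed over instruments. `direction` is `TRUE` when the instruments
#' explain strictly more variance in the exposure; p comes from a two-sample
#' z-test on the difference of `atanh(sqrt(r2))` with variance
#' `1/(n_exp-3) + 1/(n_out-3)`. Causality in the assumed direction is
#' supported when `direction` is `TRUE` with `p < 0.05`.
#'
#' @param pairs Harmonized pairs.
#' @param n_exp,n_out Sample sizes (defaults: medians of the pair columns).
#' @return List with `direction`, `pvalue`, `r2_exp`, `r2_out`.
#' @export
steiger_filter <- function(pairs, n_exp = NULL, n_out = NULL) {
  n_exp <- n_exp %||% stats::median(pairs$n_exp)
  n_out <- n_out %||% stats::median(pairs$n_out)
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 3 || n_out <= 3)
    stopf("steiger_filter requires sample sizes > 3")
  r2_of <- function(beta, se, n) {
    z2 <- (beta / se)^2
    r2 <- sum(z2 / (z2 + n - 2))
    if (r2 >= 1) { warning("instrument r2 >= 1; clamping"); r2 <- 1 - 1e-12 }
    r2
  }
  r2_exp <- r2_of(pairs$beta_exp, pairs$se_exp, n_exp)
  r2_out <- r2_of(pairs$beta_out, pairs$se_out, n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction = r2_exp > r2_out,
       pvalue = 2 * stats::pnorm(-abs(z)),
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min over j >= rank(i) of m * p_(j) / j`, capped at 1, returned in
#' the input order.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  ord <- order(p)
  q_sorted <- pmin(1, cummin(rev(m * p[ord] / seq_len(m)))[m:1])
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Classify an association as significant, suggestive or null
#'
#' `significant` when the FDR q-value is below `alpha`; `suggestive` when
#' only the nominal p is below `alpha` (nominal association that does not
#' survive multiplicity correction); `null` otherwise.
#'
#' @param p Nominal p-value(s).
#' @param q FDR-adjusted q-value(s).
#' @param alpha Threshold (default 0.05).
#' @return Character vector in `{significant, suggestive, null}`.
#' @export
classify_significance <- function(p, q, alpha = 0.05) {
  ifelse(q < alpha, "significant", ifelse(p < alpha, "suggestive", "null"))
}

#' Run the primary MR analysis for one exposure-outcome pair
#'
#' Routes to the Wald ratio for a single instrument and to [ivw()] for two or
#' more; attaches Cochran's Q, the MR-Egger intercept (when at least three
#' instruments are available) and the Steiger directionality test. Effects
#' are reported as odds ratios with 95% confidence bounds
#' `exp(beta +/- 1.96 se)`.
#'
#' @param pairs Harmonized pairs (one or more rows).
#' @param exposure_id,outcome_id Labels copied into the result.
#' @param n_exp,n_out Sample sizes for the Steiger test.
#' @return One-row data frame of class `mr_result` with columns
#'   `exposure_id`, `outcome_id`, `method`, `n_snps`, `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `pvalue`, `q_fdr` (NA until [bh_fdr()] is applied
#'   across a family), `cochran_q`, `q_pvalue`, `egger_intercept`,
#'   `egger_intercept_p`, `steiger_direction`, `steiger_p`, `significance`.
#' @export
mr_run <- function(pairs, exposure_id = "exposure", outcome_id = "outcome",
                   n_exp = NULL, n_out = NULL) {
  k <- nrow(pairs)
  if (k == 0L) stopf("no instruments supplied")
  if (k == 1L) {
    wr <- wald_ratio(pairs$beta_exp, pairs$se_exp, pairs$beta_out, pairs$se_out)
    est <- list(beta = wr$beta, se = wr$se,
                pvalue = 2 * stats::pnorm(-abs(wr$beta / wr$se)),
                method = "wald_ratio", cochran_q = NA_real_,
                q_pvalue = NA_real_, n_snps = 1L)
  } else {
    est <- ivw(pairs)
  }
  eg <- egger_intercept(pairs)
  st <- steiger_filter(pairs, n_exp, n_out)
  out <- data.frame(
    exposure_id = exposure_id, outcome_id = outcome_id,
    method = est$method, n_snps = est$n_snps,
    beta = est$beta, se = est$se, or_ = exp(est$beta),
    ci_low = exp(est$beta - 1.96 * est$se),
    ci_high = exp(est$beta + 1.96 * est$se),
    pvalue = est$pvalue, q_fdr = NA_real_,
    cochran_q = est$cochran_q, q_pvalue = est$q_pvalue,
    egger_intercept = eg$intercept, egger_intercept_p = eg$pvalue,
    steiger_direction = st$direction, steiger_p = st$pvalue,
    significance = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("mr_result", class(out))
  out
}

#' Apply FDR correction and significance classes across a result family
#'
#' Computes BH q-values across the rows of an MR result table (one family,
#' e.g. all proteins tested against one outcome dataset) and fills
#' `q_fdr` and `significance`.
#'
#' @param results Data frame of stacked [mr_run()] rows.
#' @param alpha Significance threshold.
#' @return `results` with `q_fdr` and `significance` filled.
#' @export
fdr_correct <- function(results, alpha = 0.05) {
  if (nrow(results) == 0L) return(results)
  results$q_fdr <- bh_fdr(results$pvalue)
  results$significance <- classify_significance(results$pvalue, results$q_fdr, alpha)
  results
}
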