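#' Colocalization priors
#'
#' Per-SNP prior probabilities of association: `p1` with trait 1 only, `p2`
#' with trait 2 only, `p12` with both. Defaults are the conventional
#' single-causal-variant colocalization priors.
#'
#' @param p1,p2,p12 Priors, each in (0, 1) with `p1 + p2 + p12 < 1`.
#' @return List of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 < 1, p2 < 1, p12 < 1,
            p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor for a single association
#'
#' Wakefield-style ABF against the null, computed stably in log space:
#' with `V = se^2`, `W = w_prior_sd^2`, `r=W/(V+W)` and `z = beta/se`,
#' `log ABF = 0.5*log(1 - r) + 0.5*z^2*r`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param w_prior_sd Prior standard deviation of the true effect. The
#'   conventional defaults are 0.15 for quantitative traits (SD units) and
#'   0.20 for case-control traits (log-odds).
#' @return Vector of log ABFs.
#' @export
log_abf <- function(beta, se, w_prior_sd) {
  if (any(se <= 0)) stopf("se must be > 0")
  if (any(w_prior_sd < 0)) stopf("w_prior_sd must be >= 0")
  V <- se^2
  W <- w_prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

abf_prior_sd <- function(type) {
  switch(match.arg(type, c("quant", "cc")), quant = 0.15, cc = 0.20)
}

#' Bayesian colocalization of two traits over a shared variant set
#'
#' Evaluates the five single-causal-variant hypotheses for a region:
#' H0 no association with either trait; H1/H2 association with one trait
#' only; H3 both traits associated through distinct causal variants; H4 a
#' single shared causal variant. Per-SNP log ABFs are combined entirely in
#' log space (`logsumexp`; H3 via log-diff-exp with a non-negativity clamp)
#' so that regions with very large z-scores do not overflow.
#'
#' @param trait1,trait2 Data frames in the canonical summary-statistics
#'   layout (only `variant_id`, `beta`, `se` are used); intersected on
#'   `variant_id`.
#' @param priors A [coloc_priors()].
#' @param type1,type2 `"quant"` or `"cc"`; selects the ABF prior SD per trait.
#' @param sd1,sd2 Override the per-trait ABF prior SD directly.
#' @return List of class `coloc_result` with `pph0`..`pph4`, `n_snps` and
#'   `colocalized` (`pph4 >= 0.8`).
#' @export
colocalize <- function(trait1, trait2, priors = coloc_priors(),
                       type1 = "quant", type2 = "cc",
                       sd1 = NULL, sd2 = NULL) {
  shared <- intersect(trait1$variant_id, trait2$variant_id)
  if (length(shared) == 0L) stopf("no shared variants between the two traits")
  i1 <- match(shared, trait1$variant_id)
  i2 <- match(shared, trait2$variant_id)
  l1 <- log_abf(trait1$beta[i1], trait1$se[i1], sd1 %||% abf_prior_sd(type1))
  l2 <- log_abf(trait2$beta[i2], trait2$se[i2], sd2 %||% abf_prior_sd(type2))

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over ordered pairs i != j of BF1_i * BF2_j = e^{s1+s2} - e^{s12}
  s3 <- logdiffexp(s1 + s2, s12)

  lh <- c(h0 = 0,
          h1 = log(priors$p1) + s1,
          h2 = log(priors$p2) + s2,
          h3 = log(priors$p1) + log(priors$p2) + s3,
          h4 = log(priors$p12) + s12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  stopifnot(abs(sum(pp) - 1) < 1e-9)
  structure(list(pph0 = pp[["h0"]], pph1 = pp[["h1"]], pph2 = pp[["h2"]],
                 pph3 = pp[["h3"]], pph4 = pp[["h4"]],
                 n_snps = length(shared),
                 colocalized = pp[["h4"]] >= 0.8,
                 priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> %d SNPs | PPH0-4: %.3g %.3g %.3g %.3g %.3g | colocalized: %s\n",
    x$n_snps, x$pph0, x$pph1, x$pph2, x$pph3, x$pph4, x$colocalized))
  invisible(x)
}
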