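#' Upper-tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k * chisq_1 > q)` for nonnegative weights, by
#' Imhof's inversion integral (numerical integration), with a seeded
#' Monte-Carlo fallback when the integral misbehaves numerically.
#'
#' @param q Observed statistic.
#' @param lambda Weights (eigenvalues), nonnegative; zeros are dropped.
#' @param method `"imhof"` (default) or `"mc"`.
#' @param mc_draws Monte-Carlo sample size (default 1e6).
#' @param mc_seed Seed for the fallback sampler, for reproducibility.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
pchisqsum <- function(q, lambda, method = c("imhof", "mc"),
                      mc_draws = 1e6, mc_seed = 1L) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0L) return(as.numeric(q <= 0))
  if (q <= 1e-10 * sum(lambda)) return(1)
  if (method == "mc") return(pchisqsum_mc(q, lambda, mc_draws, mc_seed))
  p <- tryCatch(pchisqsum_imhof(q, lambda), error = function(e) NA_real_)
  if (is.na(p) || p < -1e-6 || p > 1 + 1e-6)
    p <- pchisqsum_mc(q, lambda, mc_draws, mc_seed)
  min(max(p, 0), 1)
}

# Imhof (1961) inversion: P(Q > q) = 1/2 + (1/pi) * int_0^Inf sin(theta(u)) /
# (u * rho(u)) du with theta(u) = sum(atan(lambda u))/2 - q u / 2,
# rho(u) = prod (1 + lambda^2 u^2)^(1/4). The integrand oscillates with
# period 4*pi/q under an algebraically decaying envelope, so it is summed
# per period; by parts, the truncation error is O(envelope(U)/q).
pchisqsum_imhof <- function(q, lambda) {
  k <- length(lambda)
  if (k == 1L) return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  if (max(lambda) - min(lambda) < 1e-12 * max(lambda))
    return(stats::pchisq(q / mean(lambda), df = k, lower.tail = FALSE))
  integrand <- function(u) {
    vapply(u, function(ui) {
      if (ui == 0) return(0.5 * (sum(lambda) - q))
      theta <- 0.5 * sum(atan(lambda * ui)) - 0.5 * q * ui
      rho <- exp(0.25 * sum(log1p((lambda * ui)^2)))
      sin(theta) / (ui * rho)
    }, numeric(1))
  }
  envelope <- function(u) 1 / (u * exp(0.25 * sum(log1p((lambda * u)^2))))
  period <- 4 * pi / q
  total <- 0; U <- 0; n <- 0
  repeat {
    piece <- stats::integrate(integrand, U, U + period, rel.tol = 1e-10,
                              abs.tol = 1e-13, subdivisions = 200L,
                              stop.on.error = FALSE)
    total <- total + piece$value
    U <- U + period; n <- n + 1L
    if (envelope(U) / (0.5 * q) < 5e-8 || n >= 3000L) break
  }
  0.5 + total / pi
}

pchisqsum_mc <- function(q, lambda, draws, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- numeric(draws)
  for (lam in lambda) acc <- acc + lam * stats::rchisq(draws, df = 1)
  mean(acc > q)
}

#' Summary-data-based MR test at the top cis-eQTL
#'
#' Tests whether gene expression mediates a GWAS signal using the shared top
#' variant: `b_xy = beta_gwas / beta_eqtl`, with the SMR chi-square
#' `T = z_g^2 * z_e^2 / (z_g^2 + z_e^2)` referred to one degree of freedom.
#' The effect is also reported as an odds ratio with 95% bounds
#' `exp(b_xy +/- 1.96 se_bxy)` where
#' `se_bxy = |b_xy| * sqrt(1/z_g^2 + 1/z_e^2)`.
#'
#' @param eqtl_top,gwas_top One-row data frames (or lists) with `beta`, `se`
#'   (and `variant_id`) for the same, allele-harmonized variant.
#' @param gene_id,outcome_id Labels copied into the result.
#' @return List of class `smr_result` with `gene_id`, `outcome_id`,
#'   `top_snp`, `b_xy`, `se_bxy`, `or_`, `ci_low`, `ci_high`, `t_smr`,
#'   `p_smr`, and placeholders `p_heidi = NA`, `n_heidi_snps = 0`.
#' @export
smr_test <- function(eqtl_top, gwas_top, gene_id = "gene", outcome_id = "outcome") {
  if (!is.null(eqtl_top$variant_id) && !is.null(gwas_top$variant_id) &&
      eqtl_top$variant_id != gwas_top$variant_id)
    stopf("SMR requires the same top variant in both traits")
  if (eqtl_top$beta == 0) stopf("degenerate eQTL: beta == 0")
  z_e <- eqtl_top$beta / eqtl_top$se
  z_g <- gwas_top$beta / gwas_top$se
  b_xy <- gwas_top$beta / eqtl_top$beta
  t_smr <- if (z_g == 0) 0 else z_g^2 * z_e^2 / (z_g^2 + z_e^2)
  se_bxy <- if (z_g == 0) abs(gwas_top$se / eqtl_top$beta)
  else abs(b_xy) * sqrt(1 / z_g^2 + 1 / z_e^2)
  structure(list(gene_id = gene_id, outcome_id = outcome_id,
                 top_snp = eqtl_top$variant_id %||% NA_character_,
                 b_xy = b_xy, se_bxy = se_bxy,
                 or_ = exp(b_xy),
                 ci_low = exp(b_xy - 1.96 * se_bxy),
                 ci_high = exp(b_xy + 1.96 * se_bxy),
                 t_smr = t_smr,
                 p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
                 p_heidi = NA_real_, n_heidi_snps = 0L),
            class = "smr_result")
}

#' HEIDI test: linkage versus a single shared causal variant
#'
#' Heterogeneity-in-dependent-instruments test. Under a single shared causal
#' variant (pleiotropy), the expression-to-outcome effect `b_xy` estimated at
#' every SNP in LD with the top eQTL is identical; under linkage (distinct
#' causal variants) it varies. The statistic sums squared standardized
#' differences `d_i = b_xy(i) - b_xy(top)` over eligible SNPs, with the
#' covariance of `d` from the delta method using within-trait covariances
#' `cov(beta_i, beta_j) ~ r_ij * se_i * se_j` (the two traits come from
#' independent samples). Eligible SNPs have eQTL `p < p_eqtl_max`, LD r^2 to
#' the top SNP within `[r2_min, r2_max]`, capped at the `max_snps` strongest
#' eQTL associations; fewer than `min_snps` eligible SNPs yields an absent
#' p-value. The p-value refers the statistic to a weighted sum of
#' chi-square(1) with weights from the eigenvalues of the correlation matrix
#' of `d` (see [pchisqsum()]). Small p (`< 0.05`) indicates linkage.
#'
#' @param eqtl_region,gwas_region Data frames in the canonical layout,
#'   allele-aligned to each other, covering the region.
#' @param ld An [ld_matrix()] covering the region.
#' @param top_snp Variant id of the top cis-eQTL.
#' @param p_eqtl_max,r2_min,r2_max,max_snps,min_snps Eligibility thresholds
#'   (defaults follow the published SMR tool: `1.57e-3`, `[0.05, 0.9]`,
#'   20, 3).
#' @param mc_seed Seed for the Monte-Carlo fallback of the tail probability.
#' @return List with `p_heidi` (NA when too few eligible SNPs) and
#'   `n_snps_used`.
#' @export
heidi_test <- function(eqtl_region, gwas_region, ld, top_snp,
                       p_eqtl_max = 1.57e-3, r2_min = 0.05, r2_max = 0.9,
                       max_snps = 20L, min_snps = 3L, mc_seed = 1L) {
  shared <- Reduce(intersect, list(eqtl_region$variant_id,
                                   gwas_region$variant_id, colnames(ld)))
  if (!top_snp %in% shared) stopf("top SNP %s absent from a trait or the LD matrix", top_snp)
  ei <- match(shared, eqtl_region$variant_id)
  gi <- match(shared, gwas_region$variant_id)
  e <- eqtl_region[ei, ]; g <- gwas_region[gi, ]
  r_top <- unclass(ld)[shared, top_snp]
  r2 <- r_top^2
  elig <- shared != top_snp & e$pvalue < p_eqtl_max & r2 >= r2_min & r2 <= r2_max
  idx <- which(elig)
  if (length(idx) > max_snps) idx <- idx[order(e$pvalue[idx])][seq_len(max_snps)]
  if (length(idx) < min_snps)
    return(list(p_heidi = NA_real_, n_snps_used = length(idx)))

  sel <- c(match(top_snp, shared), idx)       # position 1 = top
  ids <- shared[sel]
  be <- e$beta[sel]; se_e <- e$se[sel]
  bg <- g$beta[sel]; se_g <- g$se[sel]
  R <- unclass(ld)[ids, ids]
  b_xy <- bg / be
  m <- length(idx)

  # delta method: cov(b_xy_i, b_xy_j) with independent eQTL and GWAS samples
  cov_g <- R * tcrossprod(se_g)
  cov_e <- R * tcrossprod(se_e)
  grad_g <- 1 / be
  grad_e <- -bg / be^2
  cov_b <- tcrossprod(grad_g) * cov_g + tcrossprod(grad_e) * cov_e

  # d_i = b_xy(i) - b_xy(top), i = 2..m+1
  A <- cbind(-1, diag(m))                    # m x (m+1) contrast matrix
  d <- as.numeric(A %*% b_xy)
  cov_d <- A %*% cov_b %*% t(A)
  sd_d <- sqrt(diag(cov_d))
  z_d <- d / sd_d
  stat <- sum(z_d^2)
  corr_d <- cov_d / tcrossprod(sd_d)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  p <- pchisqsum(stat, lambda, mc_seed = mc_seed)
  list(p_heidi = p, n_snps_used = m, stat = stat, lambda = lambda)
}

#' Run SMR plus HEIDI for one gene region
#'
#' Picks the top cis-eQTL (smallest eQTL p, ties broken by variant id),
#' harmonizes the two traits, runs [smr_test()] at the top SNP and
#' [heidi_test()] across the region.
#'
#' @param eqtl,gwas Data frames in the canonical layout for the region.
#' @param ld An [ld_matrix()].
#' @param gene_id,outcome_id Labels.
#' @param ... Passed to [heidi_test()].
#' @return An `smr_result` with `p_heidi` and `n_heidi_snps` filled.
#' @export
smr_analyze <- function(eqtl, gwas, ld, gene_id = "gene",
                        outcome_id = "outcome", ...) {
  h <- harmonize(eqtl, gwas, drop_palindromic = FALSE)
  if (nrow(h) == 0L) stopf("no shared variants between eQTL and GWAS")
  eqtl_h <- eqtl[match(h$variant_id, eqtl$variant_id), ]
  gwas_h <- gwas[match(h$variant_id, gwas$variant_id), ]
  gwas_h$beta <- h$beta_out                  # aligned to the eQTL effect allele
  gwas_h$eaf <- h$eaf_out
  ord <- order(eqtl_h$pvalue, eqtl_h$variant_id)
  top <- eqtl_h$variant_id[ord[1]]
  res <- smr_test(eqtl_h[ord[1], ], gwas_h[ord[1], ], gene_id, outcome_id)
  hd <- heidi_test(eqtl_h, gwas_h, ld, top, ...)
  res$p_heidi <- hd$p_heidi
  res$n_heidi_snps <- hd$n_snps_used
  res
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf(
    "<smr_result> %s ~ %s @ %s | b_xy=%.4g OR=%.3g [%.3g, %.3g] T=%.3g p=%.3g | HEIDI p=%s (%d SNPs)\n",
    x$gene_id, x$outcome_id, x$top_snp, x$b_xy, x$or_, x$ci_low, x$ci_high,
    x$t_smr, x$p_smr, format(x$p_heidi, digits = 3), x$n_heidi_snps))
  invisible(x)
}
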