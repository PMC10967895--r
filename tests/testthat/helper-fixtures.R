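# Shared fixture builders: everything is generated in code at test time.

# minimal canonical sumstats frame
make_sumstats <- function(variant_id, beta, se,
                          chrom = "1", pos = seq_along(variant_id) * 1000,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, n = 10000,
                          pvalue = pmax(2 * pnorm(-abs(beta / se)),
                                        .Machine$double.xmin)) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             n_cases = NA_real_, n_controls = NA_real_,
             stringsAsFactors = FALSE)
}

make_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                       n_exp = 10000, n_out = 10000) {
  k <- length(beta_exp)
  data.frame(variant_id = sprintf("rs%d", seq_len(k)),
             effect_allele = "A", other_allele = "G",
             beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out,
             eaf_exp = 0.3, eaf_out = 0.3, n_exp = n_exp, n_out = n_out,
             stringsAsFactors = FALSE)
}

write_tsv <- function(x, path = tempfile(fileext = ".tsv")) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent greedy-clump oracle: recursive re-derivation
clump_oracle <- function(assocs, ld, r2_max) {
  kept <- character(0)
  pool <- assocs[order(assocs$pvalue, assocs$variant_id), ]
  while (nrow(pool) > 0) {
    top <- pool$variant_id[1]
    kept <- c(kept, top)
    r2 <- unclass(ld)[pool$variant_id, top]^2
    pool <- pool[r2 <= r2_max, , drop = FALSE]
  }
  kept
}

# linear-space colocalization oracle for small regions
coloc_oracle <- function(beta1, se1, beta2, se2, p1, p2, p12, sd1, sd2) {
  abf <- function(beta, se, w_sd) {
    V <- se^2; W <- w_sd^2
    sqrt(V / (V + W)) * exp(beta^2 / V * (W / (V + W)) / 2)
  }
  bf1 <- abf(beta1, se1, sd1)
  bf2 <- abf(beta2, se2, sd2)
  h0 <- 1
  h1 <- p1 * sum(bf1)
  h2 <- p2 * sum(bf2)
  h3 <- p1 * p2 * (sum(outer(bf1, bf2)) - sum(bf1 * bf2))
  h4 <- p12 * sum(bf1 * bf2)
  u <- c(h0, h1, h2, h3, h4)
  u / sum(u)
}

# correlated two-trait quantitative regions for colocalization tests
sim_coloc_pair <- function(ld, idx1, idx2, z1 = 12, z2 = 8, n = 10000,
                           seed = 1) {
  t1 <- simulate_region(sim_config(n_snps = ncol(ld), n_exp = n,
                                   exposure_z = z1, causal_idx = idx1,
                                   seed = seed), ld = ld)$exposure
  t2 <- simulate_region(sim_config(n_snps = ncol(ld), n_exp = n,
                                   exposure_z = z2, causal_idx = idx2,
                                   seed = seed + 1L), ld = ld)$exposure
  list(t1 = t1, t2 = t2)
}
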