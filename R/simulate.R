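#' Simulate a regional LD correlation matrix
#'
#' Two parametric models: `ar1` with `r_ij = rho^|i-j|` (decaying LD along
#' the region) and `block` with constant within-block correlation and zero
#' across blocks. The result is forced positive semi-definite by flooring
#' eigenvalues at `1e-8` and re-normalizing to unit diagonal.
#'
#' @param n_snps Number of variants.
#' @param model `"ar1"` or `"block"`.
#' @param rho AR(1) decay parameter in `[0, 1)`.
#' @param block_sizes Integer vector of block sizes summing to `n_snps`.
#' @param within_r Constant within-block correlation.
#' @param variant_ids Optional ids (default `snp_001`, ...).
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(n_snps, model = c("ar1", "block"), rho = 0.9,
                        block_sizes = NULL, within_r = 0.8,
                        variant_ids = NULL) {
  model <- match.arg(model)
  if (model == "ar1") {
    stopifnot(rho >= 0, rho < 1)
    r <- rho^abs(outer(seq_len(n_snps), seq_len(n_snps), "-"))
  } else {
    block_sizes <- block_sizes %||% rep(n_snps, 1L)
    stopifnot(sum(block_sizes) == n_snps)
    blocks <- lapply(block_sizes, function(s) {
      b <- matrix(within_r, s, s); diag(b) <- 1; b
    })
    r <- matrix(0, n_snps, n_snps)
    at <- 0L
    for (b in blocks) {
      idx <- at + seq_len(nrow(b)); r[idx, idx] <- b; at <- at + nrow(b)
    }
  }
  ev <- eigen(r, symmetric = TRUE)
  if (any(ev$values < 1e-8)) {
    vals <- pmax(ev$values, 1e-8)
    r <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(r))
    r <- r / tcrossprod(d)
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  ld_matrix(r, variant_ids %||% sprintf("snp_%03d", seq_len(n_snps)))
}

#' Simulation configuration for a regional summary-statistics draw
#'
#' The defaults emulate the statistical setting of a plasma-protein
#' drug-target study: a pQTL exposure panel of ~35,559 individuals, a binary
#' osteoarthritis-like outcome GWAS of ~403,124 individuals with ~6.2% cases
#' (imbalanced UK-Biobank-style phenotype), and a blood eQTL panel of
#' ~31,684 individuals. Effects are simulated directly at the summary level:
#' marginal expected z-scores are the LD projection `R %*% u` of joint
#' causal z-scores, and observed z-scores are multivariate normal around
#' them with covariance `R` — the exact sampling model two-sample MR
#' assumes.
#'
#' @param n_snps Variants per region.
#' @param ld_model,rho,block_sizes,within_r Passed to [simulate_ld()].
#' @param scenario One of `shared_causal`, `distinct_causal`,
#'   `exposure_only`, `null`, `reverse_causal`, `pleiotropic`.
#' @param theta True causal effect of the exposure on the outcome
#'   (log-odds per SD of exposure).
#' @param causal_idx Indices of exposure causal variants (default: region
#'   midpoint).
#' @param causal_idx_out Outcome causal variant for `distinct_causal`.
#' @param exposure_z Expected marginal z at each exposure causal variant
#'   (default 12, a clearly genome-wide-significant cis signal).
#' @param outcome_z Expected marginal z at the outcome causal variant in
#'   `distinct_causal` (default 8).
#' @param pleiotropy Constant direct effect on the outcome per instrument
#'   (log-odds), for `pleiotropic`.
#' @param n_exp,n_out,n_eqtl Sample sizes.
#' @param case_fraction Outcome case fraction in (0, 1).
#' @param eaf_range Allele-frequency bounds for the uniform EAF draw.
#' @param seed Integer seed; the draw is fully reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200, ld_model = "ar1", rho = 0.98,
                       block_sizes = NULL, within_r = 0.8,
                       scenario = c("shared_causal", "distinct_causal",
                                    "exposure_only", "null",
                                    "reverse_causal", "pleiotropic"),
                       theta = 0.3, causal_idx = NULL, causal_idx_out = NULL,
                       exposure_z = 12, outcome_z = 8, pleiotropy = 0,
                       n_exp = 35559, n_out = 403124, n_eqtl = 31684,
                       case_fraction = 24955 / 403124,
                       eaf_range = c(0.05, 0.95), seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_snps > 0, n_exp > 10, n_out > 10, n_eqtl > 10,
            case_fraction > 0, case_fraction < 1)
  structure(list(n_snps = n_snps, ld_model = ld_model, rho = rho,
                 block_sizes = block_sizes, within_r = within_r,
                 scenario = scenario, theta = theta,
                 causal_idx = causal_idx %||% ceiling(n_snps / 2),
                 causal_idx_out = causal_idx_out,
                 exposure_z = exposure_z, outcome_z = outcome_z,
                 pleiotropy = pleiotropy,
                 n_exp = n_exp, n_out = n_out, n_eqtl = n_eqtl,
                 case_fraction = case_fraction, eaf_range = eaf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw one trait's marginal summary statistics given joint per-allele effects
draw_trait <- function(b_joint, R, chol_R, se, n, n_cases = NA, n_controls = NA,
                       region) {
  z_mu <- as.numeric(R %*% (b_joint / se))
  z <- z_mu + as.numeric(crossprod(chol_R, stats::rnorm(length(se))))
  beta_hat <- z * se
  data.frame(variant_id = region$variant_id, chrom = region$chrom,
             pos = region$pos, effect_allele = region$effect_allele,
             other_allele = region$other_allele, eaf = region$eaf,
             beta = beta_hat, se = se,
             pvalue = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
             n = n, n_cases = n_cases, n_controls = n_controls,
             stringsAsFactors = FALSE)
}

#' Simulate one region's exposure, outcome and eQTL summary statistics
#'
#' Draws correlated regional z-scores under a known causal architecture.
#' Exposure (protein level) and eQTL traits are quantitative with per-SNP
#' sampling variance `1/(2 eaf (1-eaf) n)`; the binary outcome's variance is
#' additionally inflated by `1/(case_fraction (1-case_fraction))` (log-odds
#' scale, emulating an imbalanced case-control GWAS). Scenarios:
#' `shared_causal`/`exposure_only` put the outcome effect `theta * b_exp` at
#' the exposure causal variants; `distinct_causal` gives the outcome its own
#' causal variant (linkage); `null` leaves the outcome unaffected;
#' `reverse_causal` makes the exposure inherit `theta` times the outcome's
#' causal effect; `pleiotropic` adds a constant direct effect at each
#' exposure causal variant.
#'
#' @param cfg A [sim_config()].
#' @param ld Optional pre-built [ld_matrix()] (rebuilt from `cfg` otherwise).
#' @param chrom,region_start Genomic placement of the region (variants are
#'   spaced 5 kb apart).
#' @return List with `exposure`, `outcome`, `eqtl` (canonical
#'   summary-statistics data frames), `ld` and `truth` (causal indices, true
#'   effects, scenario).
#' @export
simulate_region <- function(cfg, ld = NULL, chrom = "1", region_start = 1e6) {
  set.seed(cfg$seed)
  m <- cfg$n_snps
  ld <- ld %||% simulate_ld(m, cfg$ld_model, cfg$rho, cfg$block_sizes,
                            cfg$within_r)
  R <- unclass(ld)
  chol_R <- chol(R + diag(1e-10, m))
  eaf <- stats::runif(m, cfg$eaf_range[1], cfg$eaf_range[2])
  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, replace = TRUE)
  # avoid palindromic pairs so simulated instruments survive harmonization
  partner <- c(A = "C", C = "A", G = "T", T = "G")
  a2 <- partner[a1]
  region <- data.frame(variant_id = colnames(ld), chrom = chrom,
                       pos = region_start + 5000 * (seq_len(m) - 1L),
                       effect_allele = a1, other_allele = unname(a2),
                       eaf = eaf, stringsAsFactors = FALSE)

  se_exp <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_exp)
  se_eqtl <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_eqtl)
  phi <- cfg$case_fraction
  se_out <- 1 / sqrt(2 * eaf * (1 - eaf) * cfg$n_out * phi * (1 - phi))

  b_exp <- numeric(m)
  b_out <- numeric(m)
  ci <- cfg$causal_idx
  if (cfg$scenario == "reverse_causal") {
    co <- cfg$causal_idx_out %||% ci
    b_out[co] <- cfg$outcome_z * se_out[co]
    b_exp <- cfg$theta * b_out
  } else {
    b_exp[ci] <- cfg$exposure_z * se_exp[ci]
    b_out <- switch(cfg$scenario,
      shared_causal = , exposure_only = cfg$theta * b_exp,
      null = b_out,
      pleiotropic = { d <- cfg$theta * b_exp
                      d[ci] <- d[ci] + cfg$pleiotropy; d },
      distinct_causal = { d <- numeric(m)
                          co <- cfg$causal_idx_out %||% max(1L, ci - 60L)
                          d[co] <- cfg$outcome_z * se_out[co]; d })
  }
  b_eqtl <- (b_exp / se_exp) * se_eqtl  # same causal z-profile, eQTL-panel scale

  exposure <- draw_trait(b_exp, R, chol_R, se_exp, cfg$n_exp, region = region)
  n_cases <- round(cfg$n_out * phi)
  outcome <- draw_trait(b_out, R, chol_R, se_out, cfg$n_out,
                        n_cases = n_cases, n_controls = cfg$n_out - n_cases,
                        region = region)
  eqtl <- draw_trait(b_eqtl, R, chol_R, se_eqtl, cfg$n_eqtl, region = region)
  list(exposure = exposure, outcome = outcome, eqtl = eqtl, ld = ld,
       truth = list(scenario = cfg$scenario, theta = cfg$theta,
                    causal_idx = ci,
                    causal_idx_out = if (cfg$scenario %in%
                                         c("distinct_causal", "reverse_causal"))
                      cfg$causal_idx_out %||% (if (cfg$scenario == "reverse_causal")
                        ci else max(1L, ci - 60L)) else ci,
                    b_exp = b_exp, b_out = b_out, b_eqtl = b_eqtl))
}

#' Write a multi-protein synthetic study bundle to disk
#'
#' Generates `n_proteins` independent gene regions with a configurable mix
#' of causal scenarios and writes a directory the pipeline (and CLI) can
#' consume end-to-end: per-gene pQTL/eQTL/outcome TSVs, LD matrices, a gene
#' annotation table, a ground-truth table and a JSON manifest.
#'
#' @param dir Output directory (must be empty unless `force = TRUE`).
#' @param n_proteins Number of gene regions.
#' @param scenarios Character vector recycled across proteins (default: all
#'   `null`); see [sim_config()].
#' @param theta True causal effect for non-null scenarios.
#' @param seed Master seed; per-protein seeds are derived deterministically.
#' @param n_snps,rho,... Further arguments forwarded to [sim_config()].
#' @return The bundle directory path, invisibly.
#' @export
make_study <- function(dir, n_proteins, scenarios = "null", theta = 0.3,
                       seed = 1L, n_snps = 120, rho = 0.9, force = FALSE, ...) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stopf("output directory %s is not empty (use force = TRUE)", dir)
  for (d in file.path(dir, c("pqtl", "eqtl", "gwas", "ld")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  scenarios <- rep_len(scenarios, max(n_proteins, 1L))
  ann <- list(); truth <- list()
  for (i in seq_len(n_proteins)) {
    gene <- sprintf("GENE%03d", i)
    chrom <- as.character((i - 1L) %% 22L + 1L)
    start <- 1e6 + (i - 1L) * 5e6
    cfg <- sim_config(n_snps = n_snps, rho = rho, scenario = scenarios[i],
                      theta = if (scenarios[i] == "null") 0 else theta,
                      seed = (seed * 1000L + i) %% .Machine$integer.max, ...)
    sim <- simulate_region(cfg, chrom = chrom, region_start = start)
    pref <- function(x) { x$variant_id <- paste0(gene, "_", x$variant_id); x }
    write_sumstats(pref(sim$exposure), file.path(dir, "pqtl", paste0(gene, ".tsv")))
    write_sumstats(pref(sim$eqtl), file.path(dir, "eqtl", paste0(gene, ".tsv")))
    write_sumstats(pref(sim$outcome), file.path(dir, "gwas", paste0(gene, ".tsv")))
    ldm <- sim$ld
    dimnames(ldm) <- list(paste0(gene, "_", rownames(ldm)),
                          paste0(gene, "_", colnames(ldm)))
    write_ld_matrix(ldm, file.path(dir, "ld", paste0(gene, ".ld")))
    span <- 5000 * (n_snps - 1)
    ann[[i]] <- data.frame(gene_id = gene, chrom = chrom,
                           start = start, end = start + span,
                           stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(gene_id = gene, scenario = scenarios[i],
                             theta = cfg$theta,
                             causal_idx = sim$truth$causal_idx,
                             stringsAsFactors = FALSE)
  }
  ann_df <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(), chrom = character(),
               start = numeric(), end = numeric())
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), scenario = character(),
               theta = numeric(), causal_idx = integer())
  utils::write.table(ann_df, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_proteins = n_proteins, seed = seed,
                            n_snps = n_snps, rho = rho,
                            scenarios = scenarios, theta = theta),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
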