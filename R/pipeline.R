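#' Study configuration for the end-to-end pipeline
#'
#' Bundles the input paths and all thresholds of the discovery ->
#' validation -> tiering flow. Threshold defaults are the conventional
#' values used throughout the package: instrument filters per
#' [instrument_config()] (MAF filter 0 for the pQTL stage, 0.01 for the
#' eQTL stage), colocalization priors per [coloc_priors()] with
#' `PPH4 >= 0.8`, tier thresholds per [tier_thresholds()], and `alpha =
#' 0.05` for FDR significance.
#'
#' @param bundle Directory containing `annotation.tsv`, `pqtl/`, `eqtl/`,
#'   `gwas/`, `ld/` (the layout written by [make_study()]).
#' @param out_dir Output directory for result TSVs and the run manifest.
#' @param pqtl_cfg,eqtl_cfg Instrument configurations for the two stages.
#' @param priors Colocalization priors.
#' @param tier_th Tier thresholds.
#' @param alpha FDR significance threshold.
#' @param outcome_id Label for the outcome GWAS.
#' @return List of class `study_config`.
#' @export
study_config <- function(bundle, out_dir = NULL,
                         pqtl_cfg = instrument_config(maf_min = 0),
                         eqtl_cfg = instrument_config(maf_min = 0.01),
                         priors = coloc_priors(), tier_th = tier_thresholds(),
                         alpha = 0.05, outcome_id = "outcome") {
  if (!dir.exists(bundle)) stopf("bundle directory not found: %s", bundle)
  structure(list(bundle = bundle, out_dir = out_dir, pqtl_cfg = pqtl_cfg,
                 eqtl_cfg = eqtl_cfg, priors = priors, tier_th = tier_th,
                 alpha = alpha, outcome_id = outcome_id),
            class = "study_config")
}

bundle_paths <- function(cfg, gene) {
  list(pqtl = file.path(cfg$bundle, "pqtl", paste0(gene, ".tsv")),
       eqtl = file.path(cfg$bundle, "eqtl", paste0(gene, ".tsv")),
       gwas = file.path(cfg$bundle, "gwas", paste0(gene, ".tsv")),
       ld = file.path(cfg$bundle, "ld", paste0(gene, ".ld")))
}

#' Discovery phase: instrument selection and primary MR for every protein
#'
#' For each gene region in the bundle annotation: select cis-pQTL
#' instruments against the outcome GWAS, estimate the causal effect (Wald
#' ratio / IVW) with heterogeneity, pleiotropy and directionality
#' diagnostics, then apply BH-FDR across proteins within the outcome and
#' classify significance. Proteins with no surviving instrument get a
#' `no_instruments` status row so the table conserves one row per protein.
#'
#' @param cfg A [study_config()].
#' @return Data frame (one row per protein) with the [mr_run()] columns plus
#'   `status`; attribute `"funnel"` holds per-protein filter counts.
#' @export
run_discovery <- function(cfg) {
  ann <- read_gene_regions(file.path(cfg$bundle, "annotation.tsv"))
  rows <- list(); funnel <- list()
  for (i in seq_len(nrow(ann))) {
    gene <- ann$gene_id[i]
    p <- bundle_paths(cfg, gene)
    exposure <- read_sumstats(p$pqtl)
    outcome <- read_sumstats(p$gwas)
    ld <- read_ld_matrix(p$ld)
    iset <- select_instruments(exposure, ann[i, ], ld, outcome, cfg$pqtl_cfg)
    tab <- table(iset$selection_log$status)
    funnel[[gene]] <- data.frame(gene_id = gene, status = names(tab),
                                 n = as.integer(tab), stringsAsFactors = FALSE)
    if (nrow(iset$pairs) == 0L) {
      r <- data.frame(exposure_id = gene, outcome_id = cfg$outcome_id,
                      method = NA_character_, n_snps = 0L, beta = NA_real_,
                      se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, pvalue = NA_real_, q_fdr = NA_real_,
                      cochran_q = NA_real_, q_pvalue = NA_real_,
                      egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                      steiger_direction = NA, steiger_p = NA_real_,
                      significance = NA_character_, status = "no_instruments",
                      stringsAsFactors = FALSE)
    } else {
      r <- mr_run(iset$pairs, exposure_id = gene, outcome_id = cfg$outcome_id)
      r$status <- "ok"
    }
    rows[[gene]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- out$status == "ok"
  if (any(ok)) {
    corrected <- fdr_correct(out[ok, , drop = FALSE], cfg$alpha)
    out$q_fdr[ok] <- corrected$q_fdr
    out$significance[ok] <- corrected$significance
  }
  attr(out, "funnel") <- do.call(rbind, funnel)
  out
}

#' Validation phase: colocalization, SMR/HEIDI and tier assignment
#'
#' For each protein passing the discovery filter (FDR-significant by
#' default): colocalize the pQTL and, when present, the eQTL signal with
#' the outcome GWAS over the cis region; run the expression-level SMR test
#' with HEIDI; evaluate the five validation criteria and assign a tier.
#' Proteins whose eQTL file is missing or empty follow the
#' no-expression-data special rule of [assign_tier()].
#'
#' @param cfg A [study_config()].
#' @param discovery Output of [run_discovery()].
#' @param which_rows Selection of proteins to validate; default
#'   `significance == "significant"`.
#' @return Data frame: per protein the evidence values (`pph4_pqtl`,
#'   `pph4_eqtl`, `p_smr`, `p_heidi`, `mr_or`, `smr_or`), the criteria
#'   `c1`..`c5`, `n_passed` and `tier`.
#' @export
run_validation_and_tier <- function(cfg, discovery,
                                    which_rows = discovery$significance %in%
                                      "significant") {
  sel <- discovery[which_rows & !is.na(discovery$exposure_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sel))) {
    gene <- sel$exposure_id[i]
    p <- bundle_paths(cfg, gene)
    pqtl <- read_sumstats(p$pqtl)
    gwas <- read_sumstats(p$gwas)
    ld <- read_ld_matrix(p$ld)
    cl_p <- colocalize(pqtl, gwas, cfg$priors, type1 = "quant", type2 = "cc")
    eqtl_ok <- file.exists(p$eqtl)
    pph4_eqtl <- NA_real_; p_smr <- NA_real_; p_heidi <- NA_real_
    smr_or <- NA_real_
    if (eqtl_ok) {
      eqtl <- read_sumstats(p$eqtl)
      eqtl <- eqtl[pmin(eqtl$eaf, 1 - eqtl$eaf) > cfg$eqtl_cfg$maf_min, ]
      eqtl_ok <- nrow(eqtl) > 0 && any(eqtl$pvalue < cfg$eqtl_cfg$p_max)
      if (eqtl_ok) {
        cl_e <- colocalize(eqtl, gwas, cfg$priors, type1 = "quant", type2 = "cc")
        pph4_eqtl <- cl_e$pph4
        sm <- smr_analyze(eqtl, gwas, ld, gene_id = gene,
                          outcome_id = cfg$outcome_id)
        p_smr <- sm$p_smr; p_heidi <- sm$p_heidi; smr_or <- sm$or_
      }
    }
    rec <- list(protein_id = gene, outcome_id = cfg$outcome_id,
                mr_or = sel$or_[i], smr_or = smr_or, p_smr = p_smr,
                p_heidi = p_heidi, pph4_pqtl = cl_p$pph4,
                pph4_eqtl = pph4_eqtl, eqtl_available = eqtl_ok)
    tr <- evaluate_criteria(rec, cfg$tier_th)
    tr$tier <- assign_tier(tr)
    tr$mr_or <- sel$or_[i]; tr$smr_or <- smr_or; tr$p_smr <- p_smr
    tr$p_heidi <- p_heidi; tr$pph4_pqtl <- cl_p$pph4; tr$pph4_eqtl <- pph4_eqtl
    rows[[gene]] <- tr
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out))
    out <- data.frame(protein_id = character(), outcome_id = character(),
                      c1 = logical(), c2 = logical(), c3 = logical(),
                      c4 = logical(), c5 = logical(), n_passed = integer(),
                      eqtl_available = logical(), tier = integer())
  rownames(out) <- NULL
  out
}

#' Run the full pipeline on a study bundle and write result tables
#'
#' Discovery, validation and tiering in sequence; writes `discovery.tsv`,
#' `tiers.tsv`, `funnel.tsv`, `volcano.tsv` (effect vs -log10 p, for
#' plotting) and `manifest.json` (input hashes and thresholds) under
#' `cfg$out_dir`.
#'
#' @param cfg A [study_config()] with `out_dir` set.
#' @return List with `discovery` and `tiers` tables, invisibly.
#' @export
run_study <- function(cfg) {
  stopifnot(!is.null(cfg$out_dir))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  disc <- run_discovery(cfg)
  tiers <- run_validation_and_tier(cfg, disc)
  wt <- function(x, f) utils::write.table(
    x, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(disc, "discovery.tsv")
  wt(tiers, "tiers.tsv")
  wt(attr(disc, "funnel"), "funnel.tsv")
  ok <- !is.na(disc$pvalue)
  wt(data.frame(exposure_id = disc$exposure_id[ok], beta = disc$beta[ok],
                or_ = disc$or_[ok], neglog10_p = -log10(disc$pvalue[ok]),
                significance = disc$significance[ok]), "volcano.tsv")
  inputs <- list.files(cfg$bundle, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    bundle = normalizePath(cfg$bundle),
    input_md5 = as.list(tools::md5sum(inputs)),
    thresholds = list(pqtl = unclass(cfg$pqtl_cfg), eqtl = unclass(cfg$eqtl_cfg),
                      coloc_priors = unclass(cfg$priors),
                      tier = unclass(cfg$tier_th), alpha = cfg$alpha),
    package_version = as.character(utils::packageVersion("protargetmr")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(discovery = disc, tiers = tiers))
}
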