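#' Tier-classification thresholds
#'
#' @param p_smr_max Expression-level validation passes when the SMR p-value
#'   is strictly below this (default 0.05).
#' @param p_heidi_min HEIDI passes when its p-value is strictly above this
#'   (default 0.05; small HEIDI p indicates linkage, not pleiotropy).
#' @param pph4_min Colocalization passes at `PPH4 >= pph4_min` (default 0.8).
#' @return List of class `tier_thresholds`.
#' @export
tier_thresholds <- function(p_smr_max = 0.05, p_heidi_min = 0.05,
                            pph4_min = 0.8) {
  structure(list(p_smr_max = p_smr_max, p_heidi_min = p_heidi_min,
                 pph4_min = pph4_min), class = "tier_thresholds")
}

#' Evaluate the five target-validation criteria for one protein
#'
#' Criteria: (1) expression-level validation, SMR `p < 0.05`; (2) HEIDI
#' passed, `p > 0.05`; (3) pQTL colocalization, `PPH4 >= 0.8`; (4) eQTL
#' colocalization, `PPH4 >= 0.8`; (5) direction consistency, the primary MR
#' and SMR odds ratios on the same side of 1 (both strictly above or both
#' strictly below). Absent inputs score as failed; an odds ratio exactly 1
#' fails criterion 5.
#'
#' @param rec List/one-row data frame with `protein_id`, `outcome_id`,
#'   `mr_or` (required, `> 0`), and optionally `smr_or`, `p_smr`, `p_heidi`,
#'   `pph4_pqtl`, `pph4_eqtl`, `eqtl_available` (logical).
#' @param thresholds A [tier_thresholds()].
#' @return One-row data frame with `protein_id`, `outcome_id`, `c1`..`c5`,
#'   `n_passed`, `eqtl_available` and `tier = NA` (set by [assign_tier()]).
#' @export
evaluate_criteria <- function(rec, thresholds = tier_thresholds()) {
  if (!is_true_num(rec$mr_or) || rec$mr_or <= 0)
    stopf("mr_or must be a positive number")
  th <- thresholds
  c1 <- is_true_num(rec$p_smr) && rec$p_smr < th$p_smr_max
  c2 <- is_true_num(rec$p_heidi) && rec$p_heidi > th$p_heidi_min
  c3 <- is_true_num(rec$pph4_pqtl) && rec$pph4_pqtl >= th$pph4_min
  c4 <- is_true_num(rec$pph4_eqtl) && rec$pph4_eqtl >= th$pph4_min
  c5 <- is_true_num(rec$smr_or) &&
    ((rec$mr_or > 1 && rec$smr_or > 1) || (rec$mr_or < 1 && rec$smr_or < 1))
  data.frame(protein_id = rec$protein_id %||% NA_character_,
             outcome_id = rec$outcome_id %||% NA_character_,
             c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
             n_passed = sum(c1, c2, c3, c4, c5),
             eqtl_available = isTRUE(rec$eqtl_available %||% TRUE) &&
               !is.na(rec$eqtl_available %||% TRUE),
             tier = NA_integer_, stringsAsFactors = FALSE)
}

#' Assign a target tier from the evaluated criteria
#'
#' With expression (eQTL) data available, direction consistency (criterion
#' 5) is a prerequisite: failing it yields tier 4 regardless of the other
#' criteria. Otherwise the tier counts passed criteria: 5 -> tier 1, 4 ->
#' tier 2, 3 -> tier 3, fewer -> tier 4. Proteins with no usable expression
#' data are classified separately on pQTL colocalization alone: criterion 3
#' passed -> tier 2, otherwise tier 4.
#'
#' @param tr One-row data frame from [evaluate_criteria()].
#' @param eqtl_available Override the record's `eqtl_available` flag.
#' @return Integer tier in 1..4.
#' @export
assign_tier <- function(tr, eqtl_available = NULL) {
  eqtl_available <- eqtl_available %||% tr$eqtl_available
  if (!eqtl_available) return(if (tr$c3) 2L else 4L)
  if (!tr$c5) return(4L)
  switch(as.character(tr$n_passed), "5" = 1L, "4" = 2L, "3" = 3L, 4L)
}

#' Classify a table of evidence records into tiers
#'
#' Vectorized wrapper: one row per protein x outcome with the
#' [evaluate_criteria()] input columns; returns criteria, pass count and
#' tier per row.
#'
#' @param evidence Data frame of evidence records.
#' @param thresholds A [tier_thresholds()].
#' @return Data frame with `c1`..`c5`, `n_passed`, `tier` per input row.
#' @export
classify_targets <- function(evidence, thresholds = tier_thresholds()) {
  rows <- lapply(seq_len(nrow(evidence)), function(i) {
    tr <- evaluate_criteria(evidence[i, ], thresholds)
    tr$tier <- assign_tier(tr)
    tr
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged example evidence table for twelve plasma-protein OA targets
#'
#' Loads the worked-example evidence table shipped with the package: twelve
#' plasma proteins with reported causal associations with knee and/or hip
#' osteoarthritis, carrying primary-MR and SMR odds ratios, SMR p-values,
#' HEIDI outcomes and colocalization posterior probabilities. The HEIDI
#' column is a synthetic indicator encoding (0.5 pass / 0.01 fail) because
#' only pass/fail outcomes are available for these proteins; rows with no
#' usable blood eQTL have `eqtl_available = FALSE`.
#'
#' @return Data frame of evidence records suitable for [classify_targets()].
#' @export
example_evidence <- function() {
  path <- system.file("extdata", "oa_evidence_example.tsv",
                      package = "protargetmr", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  x$eqtl_available <- as.logical(x$eqtl_available)
  x
}
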