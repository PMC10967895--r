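#' Filter a phenome outcome catalog by case count
#'
#' Retains outcomes with strictly more than `min_cases` cases, the usual
#' power filter before a phenome-wide MR screen.
#'
#' @param catalog Data frame with at least `trait_id` and `n_cases`.
#' @param min_cases Case-count threshold (default 500; strictly greater).
#' @return The retained subset.
#' @export
filter_outcomes <- function(catalog, min_cases = 500) {
  catalog[catalog$n_cases > min_cases, , drop = FALSE]
}

#' Phenome-wide MR screen of one exposure across an outcome catalog
#'
#' For each outcome: harmonize the instruments against the outcome summary
#' statistics, run the primary MR estimator (Wald ratio for one instrument,
#' IVW otherwise) with heterogeneity/pleiotropy diagnostics, then correct
#' across outcomes with BH-FDR (`q_corrected`; Bonferroni available).
#' Outcomes whose summary statistics cannot be loaded are skipped and
#' reported in the `"failures"` attribute. Results are sorted by `trait_id`
#' for deterministic output.
#'
#' @param instruments An `instrument_set` (from [select_instruments()]) with
#'   exposure-side pairs.
#' @param catalog Filtered outcome catalog: `trait_id`, `label`, `n_cases`,
#'   `n_controls` and either a `path` column (TSV per outcome) or a
#'   `sumstats` list-column of data frames.
#' @param exposure Exposure associations (canonical layout) used for
#'   harmonization; defaults to the exposure side of `instruments`.
#' @param correction `"fdr"` (default) or `"bonferroni"`.
#' @param alpha Significance threshold for the `significant` flag.
#' @return Data frame, one row per outcome, with the MR result columns plus
#'   `trait_id`, `label`, `q_corrected`, `significant`; attribute
#'   `"failures"` lists skipped outcomes.
#' @export
phewas_screen <- function(instruments, catalog, exposure = NULL,
                          correction = c("fdr", "bonferroni"), alpha = 0.05) {
  correction <- match.arg(correction)
  if (nrow(instruments$pairs) == 0L) stopf("instrument set is empty")
  exposure <- exposure %||% instrument_exposure(instruments)
  rows <- list(); fails <- list()
  for (i in seq_len(nrow(catalog))) {
    entry <- catalog[i, ]
    out_stats <- tryCatch({
      if (!is.null(catalog$sumstats)) catalog$sumstats[[i]]
      else read_sumstats(entry$path)
    }, error = function(e) e)
    if (inherits(out_stats, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        trait_id = entry$trait_id, error = conditionMessage(out_stats),
        stringsAsFactors = FALSE)
      next
    }
    h <- harmonize(exposure, out_stats)
    if (nrow(h) == 0L) {
      fails[[length(fails) + 1L]] <- data.frame(
        trait_id = entry$trait_id, error = "no harmonizable instruments",
        stringsAsFactors = FALSE)
      next
    }
    res <- mr_run(h, exposure_id = instruments$exposure_id,
                  outcome_id = entry$trait_id)
    res$trait_id <- entry$trait_id
    res$label <- entry$label %||% NA_character_
    rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait_id = character(), pvalue = numeric())
  if (nrow(out)) {
    out <- out[order(out$trait_id), , drop = FALSE]
    out$q_corrected <- if (correction == "fdr") bh_fdr(out$pvalue)
    else pmin(1, out$pvalue * nrow(out))
    out$significant <- out$q_corrected < alpha
    rownames(out) <- NULL
  }
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(trait_id = character(), error = character())
  out
}

# exposure-side canonical view of an instrument set (for re-harmonization)
instrument_exposure <- function(instruments) {
  p <- instruments$pairs
  data.frame(variant_id = p$variant_id, chrom = NA_character_, pos = NA_real_,
             effect_allele = p$effect_allele,
             other_allele = p$other_allele,
             eaf = p$eaf_exp, beta = p$beta_exp, se = p$se_exp,
             pvalue = pmax(2 * stats::pnorm(-abs(p$beta_exp / p$se_exp)),
                           .Machine$double.xmin),
             n = p$n_exp, stringsAsFactors = FALSE)
}

#' Flag instruments with known cross-trait associations
#'
#' Local phenotype scan: for each instrument, lists the traits in a supplied
#' variant-trait association table reaching genome-wide significance
#' (`p < 5e-8`), and flags the instrument as a pleiotropy suspect when any
#' such trait is a listed confounder of the outcome.
#'
#' @param instruments An `instrument_set`.
#' @param assoc_table Data frame with `variant_id`, `trait`, `pvalue`.
#' @param confounder_traits Character vector of known outcome risk factors.
#' @param p_max Genome-wide significance threshold (default 5e-8).
#' @return Data frame, one row per instrument: `variant_id`, `flags`
#'   (comma-joined trait list), `pleiotropy_suspect`.
#' @export
phenotype_scan <- function(instruments, assoc_table, confounder_traits,
                           p_max = 5e-8) {
  vids <- instruments$pairs$variant_id
  rows <- lapply(vids, function(v) {
    hits <- assoc_table[assoc_table$variant_id == v &
                          assoc_table$pvalue < p_max, , drop = FALSE]
    data.frame(variant_id = v,
               flags = paste(sort(unique(hits$trait)), collapse = ","),
               pleiotropy_suspect = any(hits$trait %in% confounder_traits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(variant_id = character(), flags = character(),
               pleiotropy_suspect = logical())
  out
}
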