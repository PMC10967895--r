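#' Canonical summary-statistics columns
#'
#' Every summary-statistics data frame handled by the package carries one row
#' per variant with the columns `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` and (for binary traits)
#' `n_cases`, `n_controls`. `beta` is the per-allele effect of the effect
#' allele: log-odds for binary traits, SD units for quantitative traits.
#'
#' @name sumstats-format
#' @keywords internal
NULL

SUMSTATS_REQUIRED <- c("variant_id", "chrom", "pos", "effect_allele",
                       "other_allele", "eaf", "beta", "se", "pvalue", "n")
SUMSTATS_OPTIONAL <- c("n_cases", "n_controls")

#' Read GWAS/pQTL/eQTL summary statistics from a tab-delimited file
#'
#' Parses a header-keyed TSV into the canonical summary-statistics layout
#' (see [sumstats-format]). Rows missing `beta`, `se` or either allele are
#' dropped and reported via the `"drops"` attribute, mirroring the usual
#' QC step of eliminating variants with missing data.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(variant_id = "SNP", beta = "b")`.
#'   Unmapped canonical names are looked up verbatim.
#' @return A data frame of variant associations; attribute `"drops"` holds a
#'   data frame (`line`, `variant_id`, `reason`) of eliminated rows.
#' @export
read_sumstats <- function(path, schema = NULL) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- stats::setNames(SUMSTATS_REQUIRED, SUMSTATS_REQUIRED)
  opt  <- stats::setNames(SUMSTATS_OPTIONAL, SUMSTATS_OPTIONAL)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL))
    if (length(bad)) stopf("unknown schema keys: %s", paste(bad, collapse = ", "))
    cols[names(schema)[names(schema) %in% SUMSTATS_REQUIRED]] <-
      schema[names(schema) %in% SUMSTATS_REQUIRED]
    opt[names(schema)[names(schema) %in% SUMSTATS_OPTIONAL]] <-
      schema[names(schema) %in% SUMSTATS_OPTIONAL]
  }
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stopf("required column(s) missing from %s: %s", path,
          paste(sprintf("%s (expected header '%s')", names(missing_cols),
                        missing_cols), collapse = ", "))

  out <- data.frame(
    variant_id    = raw[[cols["variant_id"]]],
    chrom         = as.character(raw[[cols["chrom"]]]),
    pos           = raw[[cols["pos"]]],
    effect_allele = toupper(raw[[cols["effect_allele"]]]),
    other_allele  = toupper(raw[[cols["other_allele"]]]),
    eaf           = raw[[cols["eaf"]]],
    beta          = raw[[cols["beta"]]],
    se            = raw[[cols["se"]]],
    pvalue        = raw[[cols["pvalue"]]],
    n             = raw[[cols["n"]]],
    stringsAsFactors = FALSE
  )
  for (oc in SUMSTATS_OPTIONAL)
    out[[oc]] <- if (opt[oc] %in% names(raw)) raw[[opt[oc]]] else NA_character_

  num_cols <- c("pos", "eaf", "beta", "se", "pvalue", "n", "n_cases", "n_controls")
  for (nc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[nc]]))
    unparsable <- !is.na(out[[nc]]) & nzchar(trimws(out[[nc]])) & is.na(v) &
      !(nc %in% SUMSTATS_OPTIONAL)
    if (any(unparsable))
      stopf("unparsable numeric in column '%s' at data line %d of %s",
            nc, which(unparsable)[1], path)
    out[[nc]] <- v
  }

  miss <- is.na(out$beta) | is.na(out$se) |
    !nzchar(out$effect_allele) | !nzchar(out$other_allele) |
    is.na(out$effect_allele) | is.na(out$other_allele)
  drops <- data.frame(line = which(miss) + 1L,
                      variant_id = out$variant_id[miss],
                      reason = rep("missing_data", sum(miss)),
                      stringsAsFactors = FALSE)
  out <- out[!miss, , drop = FALSE]
  rownames(out) <- NULL
  validate_sumstats(out)
  attr(out, "drops") <- drops
  out
}

#' Validate a summary-statistics data frame
#'
#' Checks the invariants of the canonical layout: positive SEs, allele
#' frequencies in `[0, 1]`, p-values in `(0, 1]`, single-character distinct
#' alleles.
#'
#' @param x Data frame in the canonical layout.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(SUMSTATS_REQUIRED, names(x))
  if (length(missing_cols))
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$se <= 0, na.rm = TRUE)) stopf("se must be > 0")
  if (any(x$eaf < 0 | x$eaf > 1, na.rm = TRUE)) stopf("eaf must lie in [0, 1]")
  if (any(x$pvalue <= 0 | x$pvalue > 1, na.rm = TRUE))
    stopf("pvalue must lie in (0, 1]")
  bad <- nchar(x$effect_allele) != 1L | nchar(x$other_allele) != 1L |
    x$effect_allele == x$other_allele
  if (any(bad))
    stopf("alleles must be single characters and distinct (variant %s)",
          x$variant_id[which(bad)[1]])
  invisible(x)
}

#' Write summary statistics to the canonical TSV layout
#'
#' @param x Data frame in the canonical layout.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x[, c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene/protein annotation table
#'
#' Tab-delimited with header `gene_id`, `chrom`, `start`, `end`
#' (1-based inclusive coordinates).
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with those four columns.
#' @export
read_gene_regions <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  need <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stopf("annotation file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (any(x$start > x$end)) stopf("gene region with start > end")
  x[, need]
}

#' Read a regional LD matrix
#'
#' Square whitespace-delimited matrix of pairwise LD correlations (r, signed)
#' preceded by a single header line of variant identifiers.
#'
#' @param path Path to the LD file.
#' @return An `ld_matrix`: a numeric matrix with variant ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  header <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  m <- as.matrix(utils::read.table(path, skip = 1, header = FALSE))
  ld_matrix(m, header)
}

#' Construct and validate an LD matrix
#'
#' @param r Square numeric matrix of pairwise correlations in `[-1, 1]`.
#' @param variant_ids Character vector naming rows/columns of `r`.
#' @return The validated matrix with dimnames set, class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stopf("LD matrix must be square")
  if (length(variant_ids) != nrow(r))
    stopf("LD header has %d ids for a %d x %d matrix",
          length(variant_ids), nrow(r), ncol(r))
  if (max(abs(r - t(r))) > 1e-8) stopf("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-6) stopf("LD matrix must have unit diagonal")
  if (any(r < -1 - 1e-8 | r > 1 + 1e-8)) stopf("LD values must lie in [-1, 1]")
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Write an LD matrix with its variant-ID header line
#'
#' @param ld An `ld_matrix` (or named square matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ld), collapse = " "), con)
  utils::write.table(format(unclass(ld), digits = 10, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Instrument strength F-statistic
#'
#' First-order approximation `(beta/se)^2`, the conventional per-variant
#' strength measure when per-SNP variance explained and exact sample sizes
#' are unavailable. Instruments with `F <= 10` are conventionally discarded
#' as weak.
#'
#' @param beta Per-allele effect estimate(s).
#' @param se Standard error(s), all `> 0`.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stopf("se must be > 0")
  (beta / se)^2
}

palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Align an outcome association to an exposure's effect allele
#'
#' If the outcome's alleles are swapped relative to the exposure, the outcome
#' beta is negated and its allele frequency complemented. Palindromic (A/T or
#' C/G) variants are unconditionally dropped when `drop_palindromic = TRUE`
#' because their strand cannot be resolved from summary data. Allele sets
#' that match neither directly nor after swapping are dropped as mismatches.
#'
#' @param exp_row,out_row Single-row data frames (or lists) in the canonical
#'   summary-statistics layout for the same variant.
#' @param drop_palindromic Drop A/T and C/G variants (default `TRUE`).
#' @return A one-row data frame with columns `variant_id`, `effect_allele`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `n_exp`, `n_out`; or a character scalar `"dropped(<reason>)"`.
#' @export
harmonize_pair <- function(exp_row, out_row, drop_palindromic = TRUE) {
  if (exp_row$variant_id != out_row$variant_id)
    stopf("variant_id mismatch: %s vs %s", exp_row$variant_id, out_row$variant_id)
  if (drop_palindromic && palindromic(exp_row$effect_allele, exp_row$other_allele))
    return("dropped(palindromic)")
  beta_out <- out_row$beta
  eaf_out <- out_row$eaf
  if (out_row$effect_allele == exp_row$effect_allele &&
      out_row$other_allele == exp_row$other_allele) {
    # already aligned
  } else if (out_row$effect_allele == exp_row$other_allele &&
             out_row$other_allele == exp_row$effect_allele) {
    beta_out <- -beta_out
    eaf_out <- 1 - eaf_out
  } else {
    return("dropped(allele_mismatch)")
  }
  data.frame(variant_id = exp_row$variant_id,
             effect_allele = exp_row$effect_allele,
             other_allele = exp_row$other_allele,
             beta_exp = exp_row$beta, se_exp = exp_row$se,
             beta_out = beta_out, se_out = out_row$se,
             eaf_exp = exp_row$eaf, eaf_out = eaf_out,
             n_exp = exp_row$n, n_out = out_row$n,
             stringsAsFactors = FALSE)
}

#' Harmonize exposure and outcome summary statistics by variant
#'
#' Applies [harmonize_pair()] across the intersection of variants and returns
#' the retained pairs plus a per-variant log of drops.
#'
#' @param exposure,outcome Data frames in the canonical layout.
#' @param drop_palindromic Drop strand-ambiguous variants (default `TRUE`).
#' @return Data frame of harmonized pairs; attribute `"drops"` records
#'   `variant_id` and `reason` for removed variants.
#' @export
harmonize <- function(exposure, outcome, drop_palindromic = TRUE) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  pairs <- list(); drops <- list()
  oi <- match(shared, outcome$variant_id)
  ei <- match(shared, exposure$variant_id)
  for (k in seq_along(shared)) {
    h <- harmonize_pair(exposure[ei[k], ], outcome[oi[k], ], drop_palindromic)
    if (is.character(h))
      drops[[length(drops) + 1L]] <- data.frame(
        variant_id = shared[k], reason = sub("^dropped\\((.*)\\)$", "\\1", h),
        stringsAsFactors = FALSE)
    else pairs[[length(pairs) + 1L]] <- h
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(variant_id = character(), effect_allele = character(),
               other_allele = character(),
               beta_exp = numeric(), se_exp = numeric(), beta_out = numeric(),
               se_out = numeric(), eaf_exp = numeric(), eaf_out = numeric(),
               n_exp = numeric(), n_out = numeric(), stringsAsFactors = FALSE)
  attr(out, "drops") <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Greedy LD clumping
#'
#' Sorts ascending by p-value (ties broken lexicographically by variant id),
#' keeps the best, discards every variant with `r^2 > r2_max` to any kept
#' variant, and repeats. The output is ordered by ascending p among kept
#' variants.
#'
#' @param assocs Data frame in the canonical layout.
#' @param ld An [ld_matrix()] covering every variant in `assocs`.
#' @param r2_max Squared-correlation threshold (default `0.001`).
#' @return The retained subset of `assocs`.
#' @export
ld_clump <- function(assocs, ld, r2_max = 0.001) {
  if (nrow(assocs) == 0L) return(assocs)
  absent <- setdiff(assocs$variant_id, colnames(ld))
  if (length(absent))
    stopf("variant(s) absent from LD matrix: %s", paste(absent, collapse = ", "))
  ord <- order(assocs$pvalue, assocs$variant_id)
  x <- assocs[ord, , drop = FALSE]
  r2 <- unclass(ld)[x$variant_id, x$variant_id, drop = FALSE]^2
  keep <- logical(nrow(x))
  alive <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[r2[i, ] > r2_max] <- FALSE
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-selection configuration
#'
#' Thresholds of the cis-instrument filter chain. Defaults are the
#' conventional values for plasma pQTL instruments: genome-wide significance
#' `p < 5e-8`, exclusion of the MHC (chr6, 29-33 Mb, closed interval), a
#' 1000 kb cis window around the gene body, LD clumping at `r^2 < 0.001`,
#' `F > 10`, and no MAF filter (`maf_min = 0`; set `0.01` for the eQTL stage).
#'
#' @param p_max Genome-wide significance threshold.
#' @param cis_window Cis window in bp added to both sides of the gene body.
#' @param mhc_chrom,mhc_start,mhc_end MHC exclusion interval.
#' @param r2_max LD clumping threshold.
#' @param f_min Minimum instrument F (strictly greater than).
#' @param maf_min Minimum minor-allele frequency (strictly greater than).
#' @param drop_palindromic Drop strand-ambiguous variants.
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(p_max = 5e-8, cis_window = 1e6,
                              mhc_chrom = "6", mhc_start = 29e6, mhc_end = 33e6,
                              r2_max = 0.001, f_min = 10, maf_min = 0,
                              drop_palindromic = TRUE) {
  structure(list(p_max = p_max, cis_window = cis_window, mhc_chrom = mhc_chrom,
                 mhc_start = mhc_start, mhc_end = mhc_end, r2_max = r2_max,
                 f_min = f_min, maf_min = maf_min,
                 drop_palindromic = drop_palindromic),
            class = "instrument_config")
}

#' Select cis instruments for one exposure
#'
#' Applies the filter chain in a fixed, logged order: genome-wide
#' significance, MHC exclusion, cis window, MAF, F-statistic, LD clumping,
#' then palindrome removal and (when an outcome is supplied) allele
#' harmonization. Each dropped variant is logged with the first filter that
#' removed it.
#'
#' @param exposure Data frame of exposure associations (canonical layout).
#' @param region One-row data frame/list with `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @param ld An [ld_matrix()] covering the candidate variants.
#' @param outcome Optional outcome associations to harmonize against.
#' @param cfg An [instrument_config()].
#' @return An `instrument_set`: list with `exposure_id`, `pairs` (harmonized
#'   pairs, or exposure-side pairs with `beta_out` absent when no outcome was
#'   given) and `selection_log` (variant_id, status).
#' @export
select_instruments <- function(exposure, region, ld, outcome = NULL,
                               cfg = instrument_config()) {
  validate_sumstats(exposure)
  log <- data.frame(variant_id = exposure$variant_id,
                    status = NA_character_, stringsAsFactors = FALSE)
  mark <- function(ids, reason) {
    sel <- log$variant_id %in% ids & is.na(log$status)
    log$status[sel] <<- reason
  }
  x <- exposure

  drop_if <- function(x, bad, reason) {
    mark(x$variant_id[bad], reason)
    x[!bad, , drop = FALSE]
  }
  x <- drop_if(x, !(x$pvalue < cfg$p_max), "not_significant")
  in_mhc <- x$chrom == cfg$mhc_chrom & x$pos >= cfg$mhc_start & x$pos <= cfg$mhc_end
  x <- drop_if(x, in_mhc, "mhc")
  lo <- region$start - cfg$cis_window; hi <- region$end + cfg$cis_window
  x <- drop_if(x, !(x$chrom == region$chrom & x$pos >= lo & x$pos <= hi), "not_cis")
  maf <- pmin(x$eaf, 1 - x$eaf)
  x <- drop_if(x, !(maf > cfg$maf_min), "low_maf")
  x <- drop_if(x, !(f_statistic(x$beta, x$se) > cfg$f_min), "weak_instrument")
  if (nrow(x) > 0L) {
    kept <- ld_clump(x, ld, cfg$r2_max)
    mark(setdiff(x$variant_id, kept$variant_id), "ld_clumped")
    x <- kept
  }
  if (!is.null(outcome)) {
    h <- harmonize(x, outcome, cfg$drop_palindromic)
    hd <- attr(h, "drops")
    if (nrow(hd)) mark(hd$variant_id, hd$reason)
    mark(setdiff(x$variant_id, c(h$variant_id, hd$variant_id)), "absent_in_outcome")
    pairs <- h
  } else {
    pal <- palindromic(x$effect_allele, x$other_allele) & cfg$drop_palindromic
    mark(x$variant_id[pal], "palindromic")
    x <- x[!pal, , drop = FALSE]
    nx <- nrow(x)
    pairs <- data.frame(variant_id = x$variant_id,
                        effect_allele = x$effect_allele,
                        other_allele = x$other_allele,
                        beta_exp = x$beta, se_exp = x$se,
                        beta_out = rep(NA_real_, nx), se_out = rep(NA_real_, nx),
                        eaf_exp = x$eaf, eaf_out = rep(NA_real_, nx),
                        n_exp = x$n, n_out = rep(NA_real_, nx),
                        stringsAsFactors = FALSE)
  }
  log$status[log$variant_id %in% pairs$variant_id] <- "kept"
  structure(list(exposure_id = region$gene_id, pairs = pairs,
                 selection_log = log, config = cfg),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instrument(s), %d candidate(s)\n",
              x$exposure_id, nrow(x$pairs), nrow(x$selection_log)))
  tab <- table(x$selection_log$status)
  for (nm in names(tab)) cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  invisible(x)
}
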