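test_that("read_sumstats parses well-formed files and drops missing data", {
  x <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                     se = c(0.01, 0.02, 0.01))
  path <- write_tsv(x)
  got <- read_sumstats(path)
  expect_equal(nrow(got), 3L)
  expect_equal(got$beta, x$beta)
  expect_equal(nrow(attr(got, "drops")), 0L)

  # empty beta field -> row eliminated and logged
  x2 <- x; x2$beta[2] <- NA
  got2 <- read_sumstats(write_tsv(x2))
  expect_equal(nrow(got2), 2L)
  expect_equal(attr(got2, "drops")$variant_id, "rs2")
  expect_equal(attr(got2, "drops")$reason, "missing_data")

  # shuffled column order parses identically (header-keyed)
  shuffled <- x[, rev(names(x))]
  expect_equal(read_sumstats(write_tsv(shuffled)), got,
               ignore_attr = TRUE)
})

test_that("read_sumstats errors name the missing column and bad line", {
  x <- make_sumstats("rs1", 0.1, 0.01)
  x$beta <- NULL
  expect_error(read_sumstats(write_tsv(x)), "beta")

  y <- make_sumstats(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.01))
  y$se <- as.character(y$se); y$se[2] <- "oops"
  expect_error(read_sumstats(write_tsv(y)), "line 2")
})

test_that("read_sumstats honours a column-mapping schema", {
  x <- make_sumstats(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.02))
  names(x)[names(x) == "variant_id"] <- "SNP"
  names(x)[names(x) == "beta"] <- "b"
  got <- read_sumstats(write_tsv(x), schema = c(variant_id = "SNP", beta = "b"))
  expect_equal(got$variant_id, c("rs1", "rs2"))
  expect_equal(got$beta, c(0.1, 0.2))
})

test_that("harmonize_pair flips swapped alleles and drops palindromes", {
  e <- list(variant_id = "rs1", effect_allele = "A", other_allele = "G",
            beta = 0.10, se = 0.01, eaf = 0.3, n = 1000)
  o_swap <- list(variant_id = "rs1", effect_allele = "G", other_allele = "A",
                 beta = -0.05, se = 0.02, eaf = 0.7, n = 2000)
  h <- harmonize_pair(e, o_swap)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$effect_allele, "A")

  pal_e <- modifyList(e, list(effect_allele = "A", other_allele = "T"))
  pal_o <- modifyList(o_swap, list(effect_allele = "A", other_allele = "T",
                                   beta = 0.02))
  expect_equal(harmonize_pair(pal_e, pal_o), "dropped(palindromic)")
  expect_s3_class(harmonize_pair(pal_e, pal_o, drop_palindromic = FALSE),
                  "data.frame")

  o_mis <- modifyList(o_swap, list(effect_allele = "C", other_allele = "A"))
  expect_equal(harmonize_pair(e, o_mis), "dropped(allele_mismatch)")
  expect_error(harmonize_pair(e, modifyList(o_swap, list(variant_id = "rs2"))),
               "mismatch")
})

test_that("harmonization is involutive on an aligned pair", {
  e <- list(variant_id = "rs1", effect_allele = "A", other_allele = "G",
            beta = 0.10, se = 0.01, eaf = 0.3, n = 1000)
  o <- list(variant_id = "rs1", effect_allele = "A", other_allele = "G",
            beta = 0.02, se = 0.02, eaf = 0.31, n = 2000)
  h1 <- harmonize_pair(e, o)
  expect_equal(h1$beta_out, o$beta)
  # re-harmonizing the harmonized outcome changes nothing
  o2 <- list(variant_id = "rs1", effect_allele = h1$effect_allele,
             other_allele = h1$other_allele, beta = h1$beta_out,
             se = h1$se_out, eaf = h1$eaf_out, n = h1$n_out)
  h2 <- harmonize_pair(e, o2)
  expect_equal(h2, h1)
})

test_that("f_statistic is (beta/se)^2 with strict threshold semantics", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.01), 0)
  expect_lt(f_statistic(0.0316, 0.01), 10)   # F ~ 9.99 -> excluded by F > 10
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("ld_clump follows the greedy-by-p rule", {
  ld <- ld_matrix(diag(2), c("a", "b"))
  one <- make_sumstats("a", 0.1, 0.01)
  expect_equal(ld_clump(one, ld_matrix(matrix(1), "a"))$variant_id, "a")

  r <- matrix(c(1, 1, 1, 1), 2)
  two <- make_sumstats(c("a", "b"), c(0.1, 0.1), c(0.01, 0.011),
                       pvalue = c(1e-12, 1e-9))
  kept <- ld_clump(two, ld_matrix(r, c("a", "b")))
  expect_equal(kept$variant_id, "a")

  r2 <- matrix(c(1, sqrt(5e-4), sqrt(5e-4), 1), 2)
  kept2 <- ld_clump(two, ld_matrix(r2, c("a", "b")))
  expect_equal(kept2$variant_id, c("a", "b"))  # r2 = 0.0005 < 0.001

  expect_error(ld_clump(two, ld_matrix(matrix(1), "a")), "b")
})

test_that("ld_clump matches the recursive oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    m <- sample(2:10, 1)
    ld <- simulate_ld(m, rho = runif(1, 0, 0.99),
                      variant_ids = sprintf("v%d", 1:m))
    assocs <- make_sumstats(sprintf("v%d", 1:m), rnorm(m, 0, 0.1),
                            rep(0.01, m),
                            pvalue = runif(m, 1e-12, 1))
    r2_max <- sample(c(0.001, 0.1, 0.5), 1)
    expect_equal(ld_clump(assocs, ld, r2_max)$variant_id,
                 clump_oracle(assocs, ld, r2_max))
  }
})

test_that("select_instruments applies the filter chain with logged reasons", {
  region <- data.frame(gene_id = "G", chrom = "6", start = 40e6, end = 40.1e6)
  x <- make_sumstats(
    c("mhc", "far", "weakp", "good", "weakF", "pal"),
    beta = c(0.5, 0.5, 0.5, 0.5, 0.02, 0.5),
    se   = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01),
    chrom = "6",
    pos = c(30e6, 41.2e6, 40e6, 40.05e6, 40.01e6, 40.02e6),
    pvalue = c(1e-20, 1e-20, 6e-8, 1e-20, 1e-20, 1e-20))
  x$effect_allele[x$variant_id == "pal"] <- "A"
  x$other_allele[x$variant_id == "pal"] <- "T"
  ld <- simulate_ld(6, rho = 0, variant_ids = x$variant_id)
  iset <- select_instruments(x, region, ld)
  log <- iset$selection_log
  expect_equal(log$status[log$variant_id == "mhc"], "mhc")
  expect_equal(log$status[log$variant_id == "far"], "not_cis")
  expect_equal(log$status[log$variant_id == "weakp"], "not_significant")
  expect_equal(log$status[log$variant_id == "weakF"], "weak_instrument")
  expect_equal(log$status[log$variant_id == "pal"], "palindromic")
  expect_equal(log$status[log$variant_id == "good"], "kept")
  expect_equal(iset$pairs$variant_id, "good")
  # boundary: 1,000,001 bp beyond region end is not cis; 1,000,000 is
  x$pos[x$variant_id == "far"] <- 40.1e6 + 1e6 + 1
  expect_equal(select_instruments(x, region, ld)$selection_log$status[
    x$variant_id == "far"], "not_cis")
  x$pos[x$variant_id == "far"] <- 40.1e6 + 1e6
  expect_equal(select_instruments(x, region, ld)$selection_log$status[
    x$variant_id == "far"], "kept")
})

test_that("every retained instrument satisfies all six criteria", {
  set.seed(3)
  cfg <- instrument_config(maf_min = 0.01)
  for (rep in 1:10) {
    m <- 30
    ld <- simulate_ld(m, rho = 0.7, variant_ids = sprintf("v%02d", 1:m))
    region <- data.frame(gene_id = "G", chrom = "6", start = 28.5e6, end = 28.6e6)
    x <- make_sumstats(sprintf("v%02d", 1:m),
                       beta = rnorm(m, 0, 0.2), se = rep(0.02, m),
                       chrom = "6",
                       pos = seq(27e6, 31e6, length.out = m),
                       eaf = runif(m, 0.001, 0.999))
    al <- sample(c("A", "C"), m, TRUE)
    x$effect_allele <- al
    x$other_allele <- ifelse(al == "A", sample(c("T", "G"), m, TRUE), "G")
    iset <- select_instruments(x, region, ld, cfg = cfg)
    p <- iset$pairs
    if (nrow(p) == 0) next
    sel <- x[match(p$variant_id, x$variant_id), ]
    expect_true(all(sel$pvalue < cfg$p_max))
    expect_true(all(!(sel$pos >= 29e6 & sel$pos <= 33e6)))
    expect_true(all(sel$pos >= region$start - 1e6 & sel$pos <= region$end + 1e6))
    expect_true(all(pmin(sel$eaf, 1 - sel$eaf) > cfg$maf_min))
    expect_true(all((sel$beta / sel$se)^2 > cfg$f_min))
    if (nrow(p) > 1) {
      r2 <- unclass(ld)[p$variant_id, p$variant_id]^2
      expect_true(all(r2[upper.tri(r2)] <= cfg$r2_max))
    }
    expect_false(any(paste0(sel$effect_allele, sel$other_allele) %in%
                       c("AT", "TA", "CG", "GC")))
  }
})

test_that("selection is deterministic: identical inputs, identical log", {
  set.seed(5)
  m <- 20
  ld <- simulate_ld(m, rho = 0.5, variant_ids = sprintf("v%02d", 1:m))
  region <- data.frame(gene_id = "G", chrom = "1", start = 1e6, end = 1.1e6)
  x <- make_sumstats(sprintf("v%02d", 1:m), rnorm(m, 0, 0.2), rep(0.02, m),
                     pos = seq(0.5e6, 2e6, length.out = m))
  a <- select_instruments(x, region, ld)
  b <- select_instruments(x, region, ld)
  expect_identical(a$selection_log, b$selection_log)
  expect_identical(a$pairs, b$pairs)
})

test_that("LD matrix round-trips through its text format", {
  ld <- simulate_ld(5, rho = 0.8)
  path <- tempfile(fileext = ".ld")
  write_ld_matrix(ld, path)
  got <- read_ld_matrix(path)
  expect_equal(colnames(got), colnames(ld))
  expect_equal(unclass(got), unclass(ld), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.4, 1), 2), c("a", "b")), "symmetric")
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.5, 2), 2), c("a", "b")), "diagonal")
})
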