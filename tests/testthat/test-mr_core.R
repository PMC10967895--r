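test_that("wald_ratio is the outcome/exposure ratio with delta-method SE", {
  wr <- wald_ratio(0.1, 0.01, 0.02, 0.01)
  expect_equal(wr$beta, 0.2)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(-0.1, 0.01, 0.02, 0.01)$beta, -0.2)
  expect_equal(wald_ratio(-0.1, 0.01, 0.02, 0.01)$se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.01), "degenerate")
  # second-order correction adds the exposure-uncertainty term
  wr2 <- wald_ratio(0.1, 0.01, 0.02, 0.01, second_order = TRUE)
  expect_equal(wr2$se^2, 0.01^2 / 0.1^2 + 0.02^2 * 0.01^2 / 0.1^4)
})

test_that("ivw pools ratios with inverse-variance weights", {
  # two identical estimates: same beta, se / sqrt(2)
  p <- make_pairs(c(0.1, 0.1), c(0.01, 0.01), c(0.02, 0.02), c(0.01, 0.01))
  iv <- ivw(p)
  expect_equal(iv$beta, 0.2)
  expect_equal(iv$se, 0.1 / sqrt(2))
  expect_equal(iv$method, "ivw_fixed")

  # equal weights: plain mean of ratio estimates
  p2 <- make_pairs(c(0.1, 0.1), c(0.01, 0.01), c(0.01, 0.03), c(0.01, 0.01))
  expect_equal(ivw(p2)$beta, 0.2)

  expect_error(ivw(p[1, ]), "wald_ratio")
})

test_that("ivw equals the WLS-through-origin oracle", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    p <- make_pairs(runif(k, 0.05, 0.3), runif(k, 0.005, 0.02),
                    rnorm(k, 0.05, 0.03), runif(k, 0.005, 0.03))
    iv <- ivw(p)
    # independent route: weighted regression of beta_out on beta_exp without
    # intercept, weights 1/se_out^2 (equivalent under first-order ratio SEs)
    fit <- lm(beta_out ~ beta_exp + 0, data = p,
              weights = 1 / p$se_out^2)
    expect_equal(iv$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("cochran_q measures dispersion around the pooled estimate", {
  expect_true(is.na(cochran_q(0.2, 0.1)$Q))
  q0 <- cochran_q(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.1))
  expect_equal(q0$Q, 0)
  expect_equal(q0$pvalue, 1)
  # k = 2, b = (0, 0.2), se = (0.1, 0.1): Q = 2 * 0.1^2 / 0.01 = 2
  q2 <- cochran_q(c(0, 0.2), c(0.1, 0.1))
  expect_equal(q2$Q, 2)
  expect_equal(q2$pvalue, pchisq(2, 1, lower.tail = FALSE))
  # recompute oracle under SE rescaling
  set.seed(8)
  b <- rnorm(5, 0.2, 0.1); se <- runif(5, 0.05, 0.2)
  for (c_scale in c(0.5, 2)) {
    q <- cochran_q(b, se * c_scale)
    w <- 1 / (se * c_scale)^2
    mu <- sum(w * b) / sum(w)
    expect_equal(q$Q, sum(w * (b - mu)^2))
  }
})

test_that("egger_intercept recovers exact fits and constant pleiotropy", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  p_exact <- make_pairs(bx, rep(0.01, 4), 0.3 * bx, rep(0.01, 4))
  e <- egger_intercept(p_exact)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$slope, 0.3, tolerance = 1e-12)
  expect_gt(e$pvalue, 0.99)

  p_pleio <- make_pairs(bx, rep(0.01, 4), 0.05 + 0.3 * bx, rep(0.01, 4))
  expect_equal(egger_intercept(p_pleio)$intercept, 0.05, tolerance = 1e-12)

  # orientation: flipping an instrument's signs leaves the fit unchanged
  p_flip <- p_pleio
  p_flip$beta_exp[2] <- -p_flip$beta_exp[2]
  p_flip$beta_out[2] <- -p_flip$beta_out[2]
  expect_equal(egger_intercept(p_flip)$intercept, 0.05, tolerance = 1e-12)

  expect_equal(egger_intercept(p_exact[1:2, ])$reason, "insufficient_snps")
})

test_that("steiger_filter orders variance explained correctly", {
  p_fwd <- make_pairs(c(0.3, 0.25), c(0.01, 0.01), c(0.02, 0.02), c(0.01, 0.01))
  st <- steiger_filter(p_fwd, n_exp = 10000, n_out = 10000)
  expect_true(st$direction)
  expect_lt(st$pvalue, 0.05)
  # equal r2: direction FALSE (strict), p = 1
  p_eq <- make_pairs(0.1, 0.01, 0.1, 0.01)
  st_eq <- steiger_filter(p_eq, n_exp = 5000, n_out = 5000)
  expect_false(st_eq$direction)
  expect_equal(st_eq$pvalue, 1)
  expect_error(steiger_filter(p_eq, n_exp = 2, n_out = 5000), "sample sizes")
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 0)), "p-values")
  set.seed(9)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
  }
})

test_that("classify_significance applies the FDR/nominal trichotomy", {
  expect_equal(classify_significance(1e-5, 0.01), "significant")
  expect_equal(classify_significance(0.01, 0.20), "suggestive")
  expect_equal(classify_significance(0.5, 0.9), "null")
  # boundaries: q exactly at alpha is not significant; p exactly at alpha not suggestive
  expect_equal(classify_significance(0.01, 0.05), "suggestive")
  expect_equal(classify_significance(0.05, 0.05), "null")
})

test_that("mr_run routes one instrument to the Wald ratio and reports OR/CI", {
  p1 <- make_pairs(0.1, 0.01, 0.02, 0.01)
  r1 <- mr_run(p1)
  expect_equal(r1$method, "wald_ratio")
  expect_equal(r1$n_snps, 1L)
  expect_equal(r1$or_, exp(0.2))
  expect_true(r1$ci_low < r1$or_ && r1$or_ < r1$ci_high)
  expect_true(is.na(r1$cochran_q))

  p3 <- make_pairs(c(0.1, 0.12, 0.2), rep(0.01, 3),
                   c(0.02, 0.03, 0.05), rep(0.01, 3))
  r3 <- mr_run(p3)
  expect_true(r3$method %in% c("ivw_fixed", "ivw_random"))
  expect_equal(r3$n_snps, 3L)
  expect_false(is.na(r3$egger_intercept))
})

test_that("fdr_correct fills q and significance per family", {
  res <- do.call(rbind, lapply(c(1e-6, 0.01, 0.2), function(p) {
    r <- mr_run(make_pairs(0.1, 0.01, 0.02, 0.01))
    r$pvalue <- p
    r
  }))
  out <- fdr_correct(res)
  expect_equal(out$q_fdr, bh_fdr(out$pvalue))
  expect_true(all(out$q_fdr >= out$pvalue))
  expect_equal(out$significance[1], "significant")
  expect_equal(out$significance[3], "null")
})

test_that("IVW recovers simulated causal effects (small-scale check)", {
  est <- numeric(50)
  for (r in 1:50) {
    sim <- simulate_region(sim_config(
      n_snps = 10, rho = 0, scenario = "exposure_only", theta = 0.3,
      causal_idx = 1:10, exposure_z = 12, n_exp = 1e5, n_out = 1e5,
      case_fraction = 0.5, seed = 5000 + r))
    est[r] <- ivw(harmonize(sim$exposure, sim$outcome))$beta
  }
  expect_lt(abs(mean(est) - 0.3), 0.03)
})
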