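ann1 <- data.frame(feature_id = "geneA", chrom = "1", tss = 1200,
                   kind = "gene", stringsAsFactors = FALSE)

test_that("select_instruments applies cis/FDR/p gates and LD pruning", {
  # two significant variants in perfect LD -> only the stronger survives
  ds <- make_dataset(n = 3, beta = c(0.30, 0.28, 0.01),
                     se = c(0.02, 0.02, 0.02), trait_kind = "expression")
  r <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3)
  # perfect LD is PSD but singular; nudge symmetric structure kept exact
  ld <- ld_matrix(r, ds$records$variant_id)
  inst <- select_instruments(ds, "geneA", ann1, ld)
  expect_equal(inst$variant_id, "rs01")

  # r2 and F formulas: z = 10, n = 31,684
  ds2 <- make_dataset(n = 1, beta = 0.1, se = 0.01, nn = 31684,
                      trait_kind = "expression")
  inst2 <- select_instruments(ds2, "geneA", ann1, NULL)
  expect_equal(inst2$r2_exp, 100 / 31782, tolerance = 1e-12)
  expect_equal(inst2$f_stat, (31684 - 2) * inst2$r2_exp / (1 - inst2$r2_exp))
  expect_equal(inst2$f_stat, 99.99, tolerance = 1e-3)

  # nothing below the p gate -> empty
  ds3 <- make_dataset(n = 4, beta = 0.02, se = 0.02,
                      trait_kind = "expression")
  expect_equal(nrow(select_instruments(ds3, "geneA", ann1, NULL)), 0)
  # unknown feature warns and returns empty
  expect_warning(out <- select_instruments(ds, "nope", ann1, NULL),
                 "absent")
  expect_equal(nrow(out), 0)
})

test_that("ivw_mr: Wald-ratio delta SE, ratio consistency, scale equivariance", {
  one <- data.frame(variant_id = "v1", beta_exp = 0.5, se_exp = 0,
                    beta_out = 0.1, se_out = 0.05)
  est <- ivw_mr(one)
  expect_equal(est$method, "wald_ratio")
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_true(est$or_ci95[1] < est$or_point && est$or_point < est$or_ci95[2])

  # identical ratios give exactly that ratio whatever the weights
  many <- data.frame(variant_id = c("a", "b", "c"),
                     beta_exp = c(0.2, 0.5, -0.4), se_exp = 0.01,
                     beta_out = c(0.06, 0.15, -0.12),
                     se_out = c(0.01, 0.03, 0.02))
  est2 <- ivw_mr(many)
  expect_equal(est2$method, "ivw")
  expect_equal(est2$beta, 0.3, tolerance = 1e-12)

  # multiplying all exposure betas by k divides the estimate by k
  scaled <- many
  scaled$beta_exp <- scaled$beta_exp * 2.5
  expect_equal(ivw_mr(scaled)$beta, est2$beta / 2.5, tolerance = 1e-12)

  # zero-beta instruments are dropped; all dropped is an error
  z <- data.frame(variant_id = "z", beta_exp = 0, se_exp = 0.1,
                  beta_out = 0.1, se_out = 0.1)
  expect_error(ivw_mr(z), "no usable instruments")
})

test_that("Wald-ratio SE agrees with a parametric bootstrap at strong instruments", {
  set.seed(21)
  for (i in 1:5) {
    be <- runif(1, 0.3, 0.8); se_e <- be / runif(1, 8, 20)
    bo <- runif(1, -0.2, 0.2); se_o <- runif(1, 0.01, 0.05)
    est <- ivw_mr(data.frame(variant_id = "v", beta_exp = be,
                             se_exp = se_e, beta_out = bo, se_out = se_o))
    boot <- rnorm(40000, bo, se_o) / rnorm(40000, be, se_e)
    expect_equal(est$se, sd(boot), tolerance = 0.1)
  }
})

test_that("steiger_filter passes only when exposure variance dominates", {
  inst <- data.frame(r2_exp = c(3.15e-3, 1e-3, 1e-3, NA),
                     r2_out = c(2.79e-5, 1e-3, 2e-3, 1e-3))
  expect_equal(steiger_filter(inst), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("reverse-causation loci fail Steiger filtering at strong effects", {
  fails <- vapply(1:60, function(s) {
    loc <- simulate_locus("reverse", seed = s)
    inst <- select_instruments(loc$eqtl, "gene1", loc$annotation, loc$ld)
    if (!nrow(inst)) return(NA)
    gwas_h <- harmonize_datasets(loc$eqtl, loc$gwas)
    inst <- attach_outcome(inst, gwas_h)
    all(!steiger_filter(inst))
  }, logical(1))
  expect_gte(mean(fails, na.rm = TRUE), 0.9)
})

test_that("MR q-values are calibrated under the simulator's null (c = 0)", {
  cfg <- scenario_config("mediated", c = 0, m_snps = 20L)
  ps <- vapply(1:1000, function(s) {
    loc <- simulate_locus(cfg, seed = 40000 + s)
    inst <- select_instruments(loc$eqtl, "gene1", loc$annotation, loc$ld)
    if (!nrow(inst)) return(NA_real_)
    inst <- attach_outcome(inst, harmonize_datasets(loc$eqtl, loc$gwas))
    ivw_mr(inst)$p
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  q <- bh_fdr(ps)
  frac <- mean(q < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("IVW-MR recovers the mediated expression-to-disease effect", {
  est <- vapply(1:60, function(s) {
    loc <- simulate_locus("mediated", seed = 7000 + s)
    inst <- select_instruments(loc$eqtl, "gene1", loc$annotation, loc$ld)
    inst <- attach_outcome(inst, harmonize_datasets(loc$eqtl, loc$gwas))
    ivw_mr(inst)$beta
  }, numeric(1))
  expect_lt(abs(median(est) - 0.3) / 0.3, 0.1)
})
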