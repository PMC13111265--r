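test_that("read_sumstats parses the default header, drops bad rows, and maps dialects", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  ds0 <- make_dataset(n = 3)
  write_sumstats(ds0, tmp)
  ds <- read_sumstats(tmp, trait_kind = "disease")
  expect_equal(nrow(ds$records), 3)
  expect_equal(nrow(attr(ds, "qc_log")), 0)
  expect_equal(ds$records$beta, ds0$records$beta)

  # a row with se = NA must be dropped and counted
  lines <- readLines(tmp)
  lines[2] <- sub("\t0.05\t", "\tNA\t", lines[2])
  writeLines(lines, tmp)
  ds2 <- read_sumstats(tmp)
  expect_equal(nrow(ds2$records), 2)
  qc <- attr(ds2, "qc_log")
  expect_equal(nrow(qc), 1)
  expect_equal(qc$action, "drop_bad_se")

  # swapped A1/A2 column names resolved via dialect give the same dataset
  tab <- read.table(tmp, header = TRUE)
  names(tab)[names(tab) == "A1"] <- "EA"
  names(tab)[names(tab) == "A2"] <- "OA"
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tmp2, sep = "\t", quote = FALSE, row.names = FALSE)
  ds3 <- read_sumstats(tmp2, dialect = c(effect_allele = "EA",
                                         other_allele = "OA"))
  expect_equal(ds3$records$effect_allele, ds2$records$effect_allele)
  expect_equal(ds3$records$beta, ds2$records$beta)

  # missing required column is a hard error naming the column
  tab$EA <- NULL
  write.table(tab, tmp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(tmp2), "A1")
  # empty file is a hard error
  writeLines(character(0), tmp2)
  expect_error(read_sumstats(tmp2))
})

test_that("discordant printed p-values are recomputed and flagged", {
  rec <- make_records(n = 2, beta = c(1.9560, 3.9869), se = c(0.1322, 0.4730))
  rec$p <- c(4.47e-12, 3.49e-17)  # first is far from 2*pnorm(-|z|)
  ds <- sumstats_dataset(rec, check = TRUE)
  expect_true(ds$records$p_discordant[1])
  expect_false(ds$records$p_discordant[2])
  expect_equal(ds$records$p_reported[1], 4.47e-12)
  expect_equal(ds$records$p[1], wald_p(1.9560, 0.1322))
})

test_that("harmonize_pair covers same/flip/strand/palindromic/mismatch and is involutive", {
  exp_rec <- list(variant_id = "rs1", effect_allele = "A",
                  other_allele = "G", beta = 0.2, eaf = 0.3)
  out_same <- list(variant_id = "rs1", effect_allele = "A",
                   other_allele = "G", beta = 0.3, eaf = 0.4)
  h <- harmonize_pair(exp_rec, out_same)
  expect_equal(h$action, "same")
  expect_equal(h$record$beta, 0.3)

  out_swap <- modifyList(out_same, list(effect_allele = "G",
                                        other_allele = "A"))
  h <- harmonize_pair(exp_rec, out_swap)
  expect_equal(h$action, "flip")
  expect_equal(h$record$beta, -0.3)
  expect_equal(h$record$eaf, 1 - 0.4)
  # involution: harmonizing the flipped record again returns the original
  h2 <- harmonize_pair(exp_rec, harmonize_pair(exp_rec, h$record)$record)
  expect_equal(h2$record$beta, h$record$beta)
  expect_equal(h2$record$eaf, h$record$eaf)

  # strand complement: T/C on the other strand is A/G on this one
  out_strand <- modifyList(out_same, list(effect_allele = "T",
                                          other_allele = "C"))
  expect_equal(harmonize_pair(exp_rec, out_strand)$action, "strand")

  # palindromic A/T with eaf near 0.5 is dropped
  pal <- list(variant_id = "rs1", effect_allele = "A", other_allele = "T",
              beta = 0.1, eaf = 0.49)
  expect_equal(harmonize_pair(pal, pal)$action, "drop_palindromic")
  # palindromic with informative eaf is kept
  pal2 <- modifyList(pal, list(eaf = 0.2))
  expect_equal(harmonize_pair(pal2, pal2)$action, "same")

  out_bad <- modifyList(out_same, list(effect_allele = "A",
                                       other_allele = "C"))
  expect_equal(harmonize_pair(exp_rec, out_bad)$action, "drop_mismatch")
})

test_that("filter_by_maf folds eaf, keeps unknowns flagged, and is idempotent", {
  ds <- make_dataset(n = 4, eaf = c(0.004, 0.996, 0.30, NA))
  out <- filter_by_maf(ds, 0.005)
  expect_setequal(out$records$variant_id, c("rs03", "rs04"))
  qc <- attr(out, "qc_log")
  expect_equal(qc$action[qc$variant_id == "rs04"], "maf_unknown")
  expect_equal(sum(qc$action == "drop_maf"), 2)
  # subset of input and idempotent
  expect_true(all(out$records$variant_id %in% ds$records$variant_id))
  again <- filter_by_maf(out, 0.005)
  expect_equal(again$records, out$records)
})

test_that("wald_p matches the normal survival function and stays accurate far out", {
  expect_equal(wald_p(0, 1), 1)
  expect_equal(wald_p(1.96, 1), 0.04999579, tolerance = 1e-6)
  expect_error(wald_p(1, 0), "se")
  # strictly decreasing in |z| (log scale stays strict far beyond the
  # point where the linear-scale p underflows)
  z <- seq(0, 37, by = 0.5)
  expect_true(all(diff(wald_p(z, 1)) < 0))
  z2 <- seq(0, 60, by = 0.5)
  expect_true(all(diff(wald_p(z2, 1, log.p = TRUE)) < 0))
  # no catastrophic underflow below |z| ~ 37; log scale exact vs the
  # asymptotic series log p ~ log(2 phi(z)/z) + log(1 - 1/z^2 + 3/z^4)
  for (zz in c(37, 45, 60)) {
    lp <- wald_p(zz, 1, log.p = TRUE)
    expect_true(is.finite(lp + zz^2 / 2))
    series <- log(2) - 0.5 * log(2 * pi) - log(zz) - zz^2 / 2 +
      log1p(-1 / zz^2 + 3 / zz^4)
    expect_equal(lp, series, tolerance = 1e-4)
  }
  expect_gt(wald_p(38, 1), 0)
})

test_that("bh_fdr equals the hand example and dominates p elementwise", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(numeric(0)))
  expect_error(bh_fdr(c(0.5, 0)))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(10)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})
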