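test_that("ivw_meta reproduces closed forms and pooling invariants", {
  # single-study identity
  m1 <- ivw_meta(0.5, 0.1)
  expect_equal(m1$pooled_beta, 0.5)
  expect_equal(m1$pooled_se, 0.1)
  # two-study hand example
  m2 <- ivw_meta(c(0.4, 0.6), c(0.2, 0.1))
  expect_equal(m2$pooled_beta, 0.56, tolerance = 1e-12)
  expect_equal(m2$pooled_se, 1 / sqrt(125), tolerance = 1e-12)
  # equal-weight symmetry
  m3 <- ivw_meta(c(0.4, 0.6), c(0.2, 0.2))
  expect_equal(m3$pooled_beta, 0.5)
  expect_equal(m3$pooled_se, 0.2 / sqrt(2))
  # k identical studies: beta unchanged, se/sqrt(k), Q = 0
  m4 <- ivw_meta(rep(0.3, 4), rep(0.12, 4))
  expect_equal(m4$pooled_beta, 0.3)
  expect_equal(m4$pooled_se, 0.12 / 2)
  expect_equal(m4$q_het, 0)
  expect_equal(m4$i2, 0)
  # order invariance and merge associativity on precision summaries
  set.seed(3)
  b <- rnorm(3); s <- runif(3, 0.05, 0.2)
  ma <- ivw_meta(b, s)
  mb <- ivw_meta(rev(b), rev(s))
  expect_equal(ma$pooled_beta, mb$pooled_beta)
  mab <- ivw_meta(b[1:2], s[1:2])
  mrg <- ivw_meta(c(mab$pooled_beta, b[3]), c(mab$pooled_se, s[3]))
  expect_equal(mrg$pooled_beta, ma$pooled_beta, tolerance = 1e-12)
  expect_equal(mrg$pooled_se, ma$pooled_se, tolerance = 1e-12)
  # pooled se never exceeds the best component
  expect_lte(ma$pooled_se, min(s))
  expect_error(ivw_meta(numeric(0), numeric(0)))
})

test_that("define_loci clumps by distance with deterministic tie-breaking", {
  rec <- data.frame(
    variant_id = c("a", "b", "c"), chrom = "1",
    pos = c(1.0e6, 1.3e6, 2.5e6), p = c(1e-10, 1e-9, 1e-12),
    stringsAsFactors = FALSE
  )
  loci <- define_loci(rec, p_sig = 5e-8, window = 500000)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$index_variant, c("c", "a"))
  expect_equal(loci$n_members[loci$index_variant == "a"], 2)
  # no significant variant -> zero loci
  rec$p <- rep(0.5, 3)
  expect_equal(nrow(define_loci(rec)), 0)
  # one significant variant indexes itself
  rec$p <- c(1e-9, 0.5, 0.5)
  l1 <- define_loci(rec)
  expect_equal(l1$index_variant, "a")
  expect_equal(l1$member_variants, "a")
  # every significant variant lands in exactly one locus, and count is
  # non-increasing in window size
  set.seed(8)
  rec2 <- data.frame(variant_id = sprintf("v%02d", 1:40), chrom = "2",
                     pos = sort(sample.int(5e6, 40)),
                     p = 10^runif(40, -12, -4), stringsAsFactors = FALSE)
  for (w in c(1e5, 5e5, 2e6)) {
    ll <- define_loci(rec2, 5e-8, w)
    members <- unlist(strsplit(ll$member_variants, ","))
    expect_equal(sort(members),
                 sort(rec2$variant_id[rec2$p < 5e-8]))
  }
  n_by_w <- vapply(c(1e5, 5e5, 2e6),
                   function(w) nrow(define_loci(rec2, 5e-8, w)), numeric(1))
  expect_true(all(diff(n_by_w) <= 0))
})

test_that("replication concordance harmonizes orientation before comparing signs", {
  disc <- make_dataset(n = 2, beta = c(0.2, 0.1), se = c(0.04, 0.05))
  rep_rec <- make_records(n = 2, beta = c(-0.15, 0), se = c(0.05, 0.05),
                          a1 = "G", a2 = "A")  # alleles swapped
  rep_rec$p <- wald_p(pmax(abs(rep_rec$beta), 1e-12), rep_rec$se)
  rep_ds <- sumstats_dataset(rep_rec, label = "rep", trait_kind = "disease",
                             check = FALSE)
  rc <- replication_concordance(disc, rep_ds, c("rs01", "rs02", "rs99"))
  pv <- rc$per_variant
  # swapped alleles flip -0.15 to +0.15: consistent and nominal
  expect_true(pv$direction_consistent[pv$variant_id == "rs01"])
  expect_true(pv$nominal[pv$variant_id == "rs01"])
  # beta exactly zero is ambiguous, counted inconsistent
  expect_false(pv$direction_consistent[pv$variant_id == "rs02"])
  expect_true(pv$ambiguous[pv$variant_id == "rs02"])
  expect_false(pv$present[pv$variant_id == "rs99"])
  expect_equal(unname(rc$summary["n_total"]), 2)
})

test_that("replication drawn from the same truth is directionally consistent", {
  # two GWAS realizations of the same strong mediated locus
  hits <- vapply(1:40, function(s) {
    l1 <- simulate_locus("mediated", seed = s)
    l2 <- simulate_locus("mediated", seed = s + 50000)
    # same panel: replication genotyped on the discovery orientation
    rep_gwas <- l2$gwas
    rep_gwas$records$effect_allele <- l1$gwas$records$effect_allele
    rep_gwas$records$other_allele <- l1$gwas$records$other_allele
    top <- l1$gwas$records$variant_id[which.min(l1$gwas$records$p)]
    rc <- replication_concordance(l1$gwas, rep_gwas, top)
    rc$per_variant$direction_consistent[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("meta_analyze pools shared variants across harmonized studies", {
  d1 <- make_dataset(n = 3, beta = c(0.4, 0.2, -0.1), se = c(0.2, 0.1, 0.1))
  rec2 <- make_records(n = 3, beta = c(-0.6, 0.25, -0.05),
                       se = c(0.1, 0.1, 0.1), a1 = "G", a2 = "A")
  rec2$p <- wald_p(rec2$beta, rec2$se)
  d2 <- sumstats_dataset(rec2, label = "s2", trait_kind = "disease",
                         check = FALSE)
  mm <- meta_analyze(list(d1, d2))
  r1 <- mm$records[mm$records$variant_id == "rs01", ]
  # study 2 is flipped to +0.6 before pooling -> the 0.56 hand example
  expect_equal(r1$beta, 0.56, tolerance = 1e-12)
  expect_equal(r1$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(r1$k_studies, 2)
})
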