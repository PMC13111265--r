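# quick constructors for hand-built summary-statistics fixtures

make_records <- function(n = 3, chrom = "1", pos = NULL, beta = NULL,
                         se = NULL, eaf = NULL, nn = 10000,
                         a1 = "A", a2 = "G",
                         ids = sprintf("rs%02d", seq_len(n))) {
  data.frame(
    variant_id = ids,
    chrom = chrom,
    pos = pos %||% (1000 + seq_len(n) * 100),
    effect_allele = rep_len(a1, n),
    other_allele = rep_len(a2, n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta %||% rep(0.1, n),
    se = se %||% rep(0.05, n),
    p = NA_real_,
    n = rep_len(nn, n),
    stringsAsFactors = FALSE
  )
}

make_dataset <- function(..., label = "ds", trait_kind = "disease") {
  rec <- make_records(...)
  rec$p <- smrtriad::wald_p(rec$beta, rec$se)
  smrtriad::sumstats_dataset(rec, label = label, trait_kind = trait_kind,
                             check = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(m^2) BH step-up: q(i) = min over ranks >= rank(i) of m*p/rank
bh_bruteforce <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq_len(m), function(j) {
      if (rank(p, ties.method = "first")[j] >= r[i]) {
        m * p[j] / rank(p, ties.method = "first")[j]
      } else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# run the full triangulation on one simulated locus
run_locus <- function(loc, config = smrtriad::triad_config()) {
  smrtriad::run_three_step(loc$eqtl, loc$mqtl, loc$gwas, loc$ld,
                           loc$annotation, "gene1", config)
}
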