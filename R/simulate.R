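#' Scenario defaults for the locus simulator
#'
#' Returns the full ground-truth configuration (`LocusTruth`) for one of
#' the five causal topologies over an AR(1) LD block:
#' \describe{
#'   \item{mediated}{SNP -> methylation -> expression -> disease:
#'     `alpha = 0.15, gamma = 0.5, c = 0.3, pi = 0`.}
#'   \item{pleiotropy}{the causal SNP drives methylation/expression and
#'     disease directly (`pi = 0.05`) with no expression->disease effect.}
#'   \item{linkage}{methylation/expression causal at one SNP, disease at a
#'     second SNP 5 positions away (LD r = rho^5, ~0.59 at the default
#'     rho = 0.9 used for this scenario).}
#'   \item{null}{no effects anywhere.}
#'   \item{reverse}{disease causal (`pi = 0.15`); expression marginals are
#'     an attenuated (0.5x) readout of the disease signal, so instruments
#'     explain less variance in expression than in disease and Steiger
#'     filtering must fail.}
#' }
#' Sample sizes default to 20,000 (mQTL), 20,000 (eQTL) and 200,000
#' (GWAS); the panel is 100 SNPs spaced 2 kb apart with AR(1) rho = 0.8
#' (0.9 for linkage so the two causal variants sit at LD r ~ 0.6).
#'
#' @param scenario one of `"mediated", "pleiotropy", "linkage", "null",
#'   "reverse"`.
#' @param ... overrides for any field (`alpha, gamma, c, pi, rho, m_snps,
#'   n_m, n_e, n_g, causal_index, causal_index2, reverse_atten`).
#' @return named list (`LocusTruth` configuration).
#' @export
scenario_config <- function(scenario = c("mediated", "pleiotropy", "linkage",
                                         "null", "reverse"), ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario,
    m_snps = 100L, rho = 0.8,
    alpha = 0, gamma = 0, c = 0, pi = 0,
    n_m = 20000, n_e = 20000, n_g = 200000,
    causal_index = 50L, causal_index2 = 55L,
    reverse_atten = 0.5
  )
  cfg <- switch(scenario,
    mediated   = modifyList(cfg, list(alpha = 0.15, gamma = 0.5, c = 0.3)),
    pleiotropy = modifyList(cfg, list(alpha = 0.15, gamma = 0.5, pi = 0.05)),
    linkage    = modifyList(cfg, list(alpha = 0.2, gamma = 0.5, pi = 0.05,
                                      rho = 0.9)),
    null       = cfg,
    reverse    = modifyList(cfg, list(pi = 0.15))
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  # keep causal indices inside the panel when m_snps shrinks
  if (!("causal_index" %in% names(over))) {
    cfg$causal_index <- as.integer(ceiling(cfg$m_snps / 2))
  }
  if (!("causal_index2" %in% names(over))) {
    cfg$causal_index2 <- as.integer(min(cfg$m_snps, cfg$causal_index + 5))
  }
  cfg
}

# one MVN draw with covariance R given its Cholesky factor (upper)
.rmvn1 <- function(mu, chol_R) {
  mu + drop(crossprod(chol_R, rnorm(length(mu))))
}

#' Simulate coupled mQTL / eQTL / GWAS summary statistics at one locus
#'
#' Summary statistics are generated directly on the standardized scale:
#' per-layer total per-SNP effects are `b_m = alpha * e_causal` on
#' methylation, `b_e = gamma * b_m (+ direct term for linkage)` on
#' expression and `b_g = c * b_e + pi * e_direct` on disease; marginal
#' effects are `R %*% b`; the observed z-vector of each layer is drawn
#' from `MVN(sqrt(n) * R %*% b, R)` independently across layers, and
#' reported as `beta = z/sqrt(n), se = 1/sqrt(n)`. EAFs are
#' Uniform(0.05, 0.5) and allele pairs are non-palindromic (A/G or C/T)
#' so harmonization never drops simulated variants. Output is
#' bit-reproducible given `(seed, config)`.
#'
#' @param config a [scenario_config()] list (or scenario name).
#' @param seed master seed; per-layer child seeds are derived
#'   deterministically from it.
#' @param ld optional user-supplied `ld_matrix` replacing the AR(1)
#'   default (must match `m_snps`).
#' @return list (`SimulatedLocus`): `mqtl, eqtl, gwas`
#'   (`sumstats_dataset`s), `ld` (`ld_matrix`), `annotation` (data.frame
#'   with the gene and the CpG probe), `truth` (config plus per-layer
#'   causal indices and true step effects).
#' @export
simulate_locus <- function(config = "mediated", seed = 1L, ld = NULL) {
  if (is.character(config)) config <- scenario_config(config)
  m <- as.integer(config$m_snps)
  if (m < 2) stop("m_snps must be >= 2")
  if (abs(config$rho) >= 1) stop("|rho| must be < 1 (non-PSD LD otherwise)")
  for (nn in c("n_m", "n_e", "n_g")) {
    if (config[[nn]] < 50) stop("sample sizes must be >= 50")
  }
  ids <- sprintf("snp%03d", seq_len(m))
  R <- if (is.null(ld)) ar1_ld(m, config$rho, ids) else {
    if (nrow(ld) != m) stop("user LD matrix does not match m_snps")
    ids <- rownames(ld)
    ld
  }
  j1 <- as.integer(config$causal_index)
  j2 <- as.integer(config$causal_index2)
  stopifnot(j1 >= 1, j1 <= m, j2 >= 1, j2 <= m)

  e1 <- numeric(m); e1[j1] <- 1
  e2 <- numeric(m); e2[j2] <- 1

  b_m <- config$alpha * e1
  b_e <- config$gamma * b_m
  b_g <- config$c * b_e
  if (config$scenario == "pleiotropy") b_g <- b_g + config$pi * e1
  if (config$scenario == "linkage")    b_g <- b_g + config$pi * e2
  if (config$scenario == "reverse") {
    b_g <- config$pi * e1
    b_e <- config$reverse_atten * b_g
    b_m <- numeric(m)
  }

  Rm <- unclass(R)
  chol_R <- chol(Rm)
  seeds <- derive_seeds(seed, 4L)

  layer <- function(b, n, label, trait_kind, lseed, eaf, alleles) {
    set.seed(lseed)
    z <- .rmvn1(sqrt(n) * drop(Rm %*% b), chol_R)
    beta <- z / sqrt(n)
    se <- rep(1 / sqrt(n), m)
    rec <- data.frame(
      variant_id = ids, chrom = "1",
      pos = 1e6 + (seq_len(m) - 1) * 2000,
      effect_allele = alleles$a1, other_allele = alleles$a2,
      eaf = eaf, beta = beta, se = se,
      p = wald_p(beta, se), n = n, stringsAsFactors = FALSE
    )
    sumstats_dataset(rec, label = label, trait_kind = trait_kind,
                     check = FALSE)
  }

  set.seed(seeds[4])
  eaf <- runif(m, 0.05, 0.5)
  pick <- sample(c(TRUE, FALSE), m, replace = TRUE)
  alleles <- list(a1 = ifelse(pick, "A", "C"), a2 = ifelse(pick, "G", "T"))

  mqtl <- layer(b_m, config$n_m, "mqtl", "methylation", seeds[1], eaf, alleles)
  eqtl <- layer(b_e, config$n_e, "eqtl", "expression", seeds[2], eaf, alleles)
  gwas <- layer(b_g, config$n_g, "gwas", "disease", seeds[3], eaf, alleles)

  center <- 1e6 + (j1 - 1) * 2000
  annotation <- data.frame(
    feature_id = c("gene1", "cpg1"),
    chrom = "1",
    tss = c(center + 10000, center - 4000),
    kind = c("gene", "probe"),
    stringsAsFactors = FALSE
  )

  truth <- config
  truth$seed <- seed
  truth$causal_indices <- list(
    methylation = if (any(b_m != 0)) j1 else integer(0),
    expression = if (any(b_e != 0)) j1 else integer(0),
    disease = if (any(b_g != 0)) {
      if (config$scenario == "linkage") j2 else j1
    } else integer(0)
  )
  # true step effects the pipeline should recover
  truth$true_step3 <- if (config$alpha != 0) config$gamma else NA_real_
  truth$true_step1 <- if (config$scenario == "mediated") config$c else NA_real_
  truth$true_step2 <- if (config$scenario == "mediated") {
    config$gamma * config$c
  } else NA_real_

  structure(list(mqtl = mqtl, eqtl = eqtl, gwas = gwas, ld = R,
                 annotation = annotation, truth = truth),
            class = "simulated_locus")
}

#' @export
print.simulated_locus <- function(x, ...) {
  cat(sprintf("<simulated_locus> scenario=%s m=%d rho=%.2f seed=%s\n",
              x$truth$scenario, x$truth$m_snps, x$truth$rho,
              format(x$truth$seed)))
  invisible(x)
}

#' Write a simulated locus to plain-text files
#'
#' Emits the three sumstats TSVs, the LD TSV, the annotation TSV and a
#' key-value truth file into `dir`.
#'
#' @param locus a `simulated_locus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_locus <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(locus$mqtl, file.path(dir, "mqtl.tsv"))
  write_sumstats(locus$eqtl, file.path(dir, "eqtl.tsv"))
  write_sumstats(locus$gwas, file.path(dir, "gwas.tsv"))
  write_ld(locus$ld, file.path(dir, "ld.tsv"))
  write.table(locus$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- locus$truth
  scal <- tr[vapply(tr, function(x) is.atomic(x) && length(x) == 1, logical(1))]
  writeLines(paste(names(scal), vapply(scal, format, character(1)),
                   sep = "\t"),
             file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Evaluate pipeline recovery against simulator ground truth
#'
#' Summarizes, per scenario, how the three-step candidates relate to the
#' simulated truth: detection rate (the true (probe, gene) pair is among
#' the candidates; only scenarios whose truth is a mediated chain count),
#' false-candidate rate (any candidate emitted where the truth has no
#' mediated chain), median relative bias of the step-1 (`c`) and step-3
#' (`gamma`) estimates, HEIDI rejection rate at `heidi_alpha`, and the
#' median coloc PP.H4.
#'
#' @param batch list of `simulated_locus`.
#' @param results list of per-locus [run_three_step()] outputs, same
#'   length/order.
#' @param heidi_alpha HEIDI rejection level (default 0.05).
#' @return data.frame keyed by scenario.
#' @export
evaluate_recovery <- function(batch, results, heidi_alpha = 0.05) {
  if (length(batch) != length(results)) {
    stop("batch and results must have the same length")
  }
  per <- lapply(seq_along(batch), function(i) {
    tr <- batch[[i]]$truth
    res <- results[[i]]
    chains <- res$chains
    s1 <- res$step1[res$step1$exposure_id == "gene1", , drop = FALSE]
    s3 <- res$step3[res$step3$gene_id == "gene1", , drop = FALSE]
    cand <- chains[which(chains$candidate), , drop = FALSE]
    truth_pair <- tr$scenario == "mediated"
    detected <- truth_pair && nrow(cand) > 0 &&
      any(cand$gene_id == "gene1" & cand$probe_id == "cpg1")
    data.frame(
      scenario = tr$scenario,
      detected = if (truth_pair) detected else NA,
      false_candidate = if (!truth_pair) nrow(cand) > 0 else NA,
      c_hat = if (nrow(s1)) s1$b_smr[1] else NA_real_,
      gamma_hat = if (nrow(s3)) s3$b_smr[1] else NA_real_,
      step2_hat = if (nrow(chains)) chains$b_step2[1] else NA_real_,
      true_c = tr$true_step1 %||% NA_real_,
      true_gamma = tr$true_step3 %||% NA_real_,
      true_step2 = tr$true_step2 %||% NA_real_,
      heidi_reject = if (nrow(s1) && !is.na(s1$p_heidi[1])) {
        s1$p_heidi[1] < heidi_alpha
      } else NA,
      pph4 = if (nrow(s1)) s1$pph4[1] else NA_real_,
      pph3 = if (nrow(s1)) s1$pph3[1] else NA_real_,
      sign_consistent = if (nrow(cand)) all(cand$sign_consistent) else NA,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  agg <- lapply(split(per, per$scenario), function(g) {
    data.frame(
      scenario = g$scenario[1],
      n = nrow(g),
      detection_rate = mean(g$detected, na.rm = TRUE),
      false_candidate_rate = mean(g$false_candidate, na.rm = TRUE),
      c_median_rel_err = stats::median(
        abs(g$c_hat - g$true_c) / abs(g$true_c), na.rm = TRUE),
      gamma_median_rel_err = stats::median(
        abs(g$gamma_hat - g$true_gamma) / abs(g$true_gamma), na.rm = TRUE),
      step2_median_rel_err = stats::median(
        abs(g$step2_hat - g$true_step2) / abs(g$true_step2), na.rm = TRUE),
      heidi_rejection_rate = mean(g$heidi_reject, na.rm = TRUE),
      pph4_median = stats::median(g$pph4, na.rm = TRUE),
      pph3_median = stats::median(g$pph3, na.rm = TRUE),
      sign_consistency_rate = mean(g$sign_consistent, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "per_locus") <- per
  out
}
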