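#' Default pipeline configuration
#'
#' Collates every tunable threshold of the triangulation pipeline. The
#' defaults mirror the analysis conventions: MAF >= 0.5\%, genome-wide
#' significance 5e-8 with 500-kb loci, 1-Mb cis windows, instrument gate
#' p < 1e-5, per-step BH-FDR < 0.05, HEIDI pass at p > 0.05 (eligibility
#' p < 1.57e-3, r^2 in [0.05, 0.9], <= 20 SNPs, >= 3), coloc priors
#' p1 = p2 = 1e-4, p12 = 1e-5 with effect-prior SDs 0.2 (molecular) /
#' 0.15 (case-control), and a PP.H4 > 0.5 colocalization gate.
#'
#' @param ... overrides for any field.
#' @return named list of class `triad_config`.
#' @export
triad_config <- function(...) {
  cfg <- list(
    maf_min = 0.005,
    p_sig = 5e-8,
    locus_window = 500000,
    cis_window = 1e6,
    instr_p = 1e-5,
    instr_fdr = 0.05,
    prune_r2 = 0.1,
    step_fdr = 0.05,
    heidi_alpha = 0.05,
    heidi_p_exp_max = 1.57e-3,
    heidi_r2_range = c(0.05, 0.9),
    heidi_max_snps = 20,
    heidi_min_snps = 3,
    heidi_untestable_pass = TRUE,
    coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
    coloc_sd_molecular = 0.2, coloc_sd_disease = 0.15,
    pph4_gate = 0.5,
    coloc_gate_on = TRUE,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  probs <- c("maf_min", "p_sig", "instr_p", "instr_fdr", "prune_r2",
             "step_fdr", "heidi_alpha", "heidi_p_exp_max",
             "coloc_p1", "coloc_p2", "pph4_gate")
  for (f in probs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop("config field '", f, "' must be a probability in [0, 1)")
    }
  }
  if (cfg$cis_window <= 0 || cfg$locus_window <= 0) {
    stop("windows must be > 0")
  }
  structure(cfg, class = c("triad_config", "list"))
}

# SMR + FDR over a set of features for one exposure/outcome pair
.smr_step <- function(exposure, outcome, features, annotation, ld, cfg) {
  rows <- lapply(features, function(f) {
    smr_feature(exposure, outcome, f, annotation, ld,
                cis_window = cfg$cis_window, p_max = cfg$instr_p,
                p_exp_max = cfg$heidi_p_exp_max,
                r2_range = cfg$heidi_r2_range,
                max_snps = cfg$heidi_max_snps,
                min_snps = cfg$heidi_min_snps)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(exposure_id = character(), outcome_id = character(),
                      top_variant = character(), p_exp_top = numeric(),
                      p_out_top = numeric(), b_smr = numeric(),
                      se_smr = numeric(), p_smr = numeric(),
                      p_heidi = numeric(), n_heidi_snps = integer(),
                      heidi_status = character(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_smr)
  out
}

# HEIDI gate for one p_heidi value under the configured NA policy
.heidi_ok <- function(p_heidi, cfg) {
  if (is.na(p_heidi)) cfg$heidi_untestable_pass else p_heidi > cfg$heidi_alpha
}

#' Run the three-step SMR triangulation with gating and colocalization
#'
#' Step 1 tests each gene in `gene_filter` as exposure (eQTL) against the
#' disease GWAS; step 2 tests each methylation probe (mQTL) against the
#' GWAS; step 3 tests methylation against expression, but only for
#' (probe, gene) pairs significant in both earlier steps and with the
#' probe inside the gene's cis window. BH-FDR is applied within each step
#' across the tests actually performed. A (probe, gene) chain is a
#' candidate when it passes: `fdr_all3` (q < step_fdr three times),
#' `p_all_datasets` (top-instrument p < instr_p in eQTL, mQTL and GWAS),
#' `heidi_all3` (every computable HEIDI p > heidi_alpha; untestable
#' passes with a flag by default) and, when enabled, the colocalization
#' gate (eQTL vs GWAS PP.H4 > pph4_gate). Sign consistency checks
#' `sign(step2) == sign(step1) * sign(step3)`.
#'
#' @param eqtl,mqtl,gwas `sumstats_dataset`s (expression, methylation,
#'   disease). mqtl/gwas are harmonized to the eQTL orientation
#'   internally.
#' @param ld `ld_matrix` over the locus panel, or NULL (HEIDI untestable
#'   throughout).
#' @param annotation data.frame with `feature_id, chrom, tss, kind`
#'   (kind: "gene" or "probe").
#' @param gene_filter non-empty character vector of gene ids admitted to
#'   step 1 (the immune-response differential gene list role).
#' @param config a [triad_config()].
#' @return list with per-step tables `step1, step2, step3` (each with
#'   `q`), and `chains` — one row per tested (probe, gene) pair with gate
#'   flags, coloc posteriors, `sign_consistent` and `candidate`.
#' @export
run_three_step <- function(eqtl, mqtl, gwas, ld, annotation, gene_filter,
                           config = triad_config()) {
  if (!length(gene_filter)) stop("gene_filter must be non-empty")
  cfg <- config
  genes <- intersect(gene_filter,
                     annotation$feature_id[annotation$kind == "gene"])
  probes <- annotation$feature_id[annotation$kind == "probe"]

  gwas_h <- harmonize_datasets(eqtl, gwas)
  mqtl_h <- harmonize_datasets(eqtl, mqtl)

  step1 <- .smr_step(eqtl, gwas_h, genes, annotation, ld, cfg)
  step2 <- .smr_step(mqtl_h, gwas_h, probes, annotation, ld, cfg)

  # coloc per step-1 gene: eQTL vs GWAS over the gene's cis panel
  if (nrow(step1)) {
    cc <- lapply(step1$exposure_id, function(g) {
      ann <- annotation[annotation$feature_id == g, ][1, ]
      rec <- eqtl$records
      ids <- rec$variant_id[
        normalize_chrom(rec$chrom) == normalize_chrom(ann$chrom) &
          abs(rec$pos - ann$tss) <= cfg$cis_window]
      ids <- intersect(ids, gwas_h$records$variant_id)
      e <- rec[match(ids, rec$variant_id), ]
      o <- gwas_h$records[match(ids, gwas_h$records$variant_id), ]
      r <- coloc_abf(e$beta / e$se, e$se, o$beta / o$se, o$se,
                     p1 = cfg$coloc_p1, p2 = cfg$coloc_p2,
                     p12 = cfg$coloc_p12,
                     prior_sd1 = cfg$coloc_sd_molecular,
                     prior_sd2 = cfg$coloc_sd_disease)
      r$pp
    })
    pp <- do.call(rbind, cc)
    step1$pph3 <- pp[, "H3"]
    step1$pph4 <- pp[, "H4"]
  } else {
    step1$pph3 <- numeric(0)
    step1$pph4 <- numeric(0)
  }

  sig1 <- step1[step1$q < cfg$step_fdr, , drop = FALSE]
  sig2 <- step2[step2$q < cfg$step_fdr, , drop = FALSE]

  # step-3 pairs: probe within the gene's cis window
  pairs <- list()
  gene_ann <- annotation[annotation$kind == "gene", ]
  probe_ann <- annotation[annotation$kind == "probe", ]
  for (g in sig1$exposure_id) {
    ga <- gene_ann[gene_ann$feature_id == g, ][1, ]
    for (pr in sig2$exposure_id) {
      pa <- probe_ann[probe_ann$feature_id == pr, ][1, ]
      if (normalize_chrom(pa$chrom) == normalize_chrom(ga$chrom) &&
          abs(pa$tss - ga$tss) <= cfg$cis_window) {
        pairs[[length(pairs) + 1]] <- c(probe = pr, gene = g)
      }
    }
  }

  step3 <- if (length(pairs)) {
    rows <- lapply(pairs, function(pg) {
      r <- smr_feature(mqtl_h, eqtl, pg[["probe"]], annotation, ld,
                       cis_window = cfg$cis_window, p_max = cfg$instr_p,
                       p_exp_max = cfg$heidi_p_exp_max,
                       r2_range = cfg$heidi_r2_range,
                       max_snps = cfg$heidi_max_snps,
                       min_snps = cfg$heidi_min_snps)
      if (is.null(r)) return(NULL)
      r$gene_id <- pg[["gene"]]
      r
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      s3 <- do.call(rbind, rows)
      s3$q <- bh_fdr(s3$p_smr)
      s3
    } else NULL
  } else NULL
  if (is.null(step3)) {
    step3 <- data.frame(exposure_id = character(), outcome_id = character(),
                        top_variant = character(), p_exp_top = numeric(),
                        p_out_top = numeric(), b_smr = numeric(),
                        se_smr = numeric(), p_smr = numeric(),
                        p_heidi = numeric(), n_heidi_snps = integer(),
                        heidi_status = character(), gene_id = character(),
                        q = numeric(), stringsAsFactors = FALSE)
  }

  chains <- lapply(seq_len(nrow(step3)), function(i) {
    s3 <- step3[i, ]
    pr <- s3$exposure_id; g <- s3$gene_id
    s1 <- step1[step1$exposure_id == g, ][1, ]
    s2 <- step2[step2$exposure_id == pr, ][1, ]
    # top-instrument p < instr_p in each of the three datasets; the GWAS
    # gate is checked at whichever top SNP (step 1's or step 2's) is
    # stronger in the GWAS
    p_gwas_top <- min(s1$p_out_top, s2$p_out_top)
    gate_fdr <- s1$q < cfg$step_fdr && s2$q < cfg$step_fdr &&
      s3$q < cfg$step_fdr
    gate_p <- s1$p_exp_top < cfg$instr_p && s2$p_exp_top < cfg$instr_p &&
      p_gwas_top < cfg$instr_p
    gate_heidi <- .heidi_ok(s1$p_heidi, cfg) && .heidi_ok(s2$p_heidi, cfg) &&
      .heidi_ok(s3$p_heidi, cfg)
    gate_coloc <- !cfg$coloc_gate_on || (!is.na(s1$pph4) &&
                                           s1$pph4 > cfg$pph4_gate)
    sign_ok <- sign(s2$b_smr) == sign(s1$b_smr) * sign(s3$b_smr)
    data.frame(
      probe_id = pr, gene_id = g,
      b_step1 = s1$b_smr, se_step1 = s1$se_smr, q_step1 = s1$q,
      b_step2 = s2$b_smr, se_step2 = s2$se_smr, q_step2 = s2$q,
      b_step3 = s3$b_smr, se_step3 = s3$se_smr, q_step3 = s3$q,
      p_heidi_step1 = s1$p_heidi, p_heidi_step2 = s2$p_heidi,
      p_heidi_step3 = s3$p_heidi,
      coloc_pph3 = s1$pph3, coloc_pph4 = s1$pph4,
      gate_fdr_all3 = gate_fdr, gate_p_all_datasets = gate_p,
      gate_heidi_all3 = gate_heidi, gate_coloc = gate_coloc,
      heidi_untestable = is.na(s1$p_heidi) || is.na(s2$p_heidi) ||
        is.na(s3$p_heidi),
      sign_consistent = sign_ok,
      candidate = gate_fdr && gate_p && gate_heidi && gate_coloc,
      stringsAsFactors = FALSE
    )
  })
  chains <- if (length(chains)) do.call(rbind, chains) else data.frame(
    probe_id = character(), gene_id = character(),
    b_step1 = numeric(), se_step1 = numeric(), q_step1 = numeric(),
    b_step2 = numeric(), se_step2 = numeric(), q_step2 = numeric(),
    b_step3 = numeric(), se_step3 = numeric(), q_step3 = numeric(),
    p_heidi_step1 = numeric(), p_heidi_step2 = numeric(),
    p_heidi_step3 = numeric(),
    coloc_pph3 = numeric(), coloc_pph4 = numeric(),
    gate_fdr_all3 = logical(), gate_p_all_datasets = logical(),
    gate_heidi_all3 = logical(), gate_coloc = logical(),
    heidi_untestable = logical(), sign_consistent = logical(),
    candidate = logical(), stringsAsFactors = FALSE)

  list(step1 = step1, step2 = step2, step3 = step3, chains = chains,
       config = cfg)
}

#' Interpret a causal chain's effect directions
#'
#' Each edge's direction is the sign of its SMR ratio (OR > 1 means a
#' positive log-effect). The chain is consistent when the direct
#' methylation-to-disease direction equals the product of the
#' methylation-to-expression and expression-to-disease directions.
#'
#' @param b_step1 expression -> disease log-effect.
#' @param b_step2 methylation -> disease log-effect.
#' @param b_step3 methylation -> expression log-effect.
#' @return list with `consistent` (logical) and `statement` (readable
#'   chain, e.g. "methylation -| expression -> disease => methylation
#'   protective").
#' @export
infer_sign_chain <- function(b_step1, b_step2, b_step3) {
  stopifnot(is.finite(b_step1), is.finite(b_step2), is.finite(b_step3))
  consistent <- sign(b_step2) == sign(b_step1) * sign(b_step3)
  edge <- function(b, up, down) if (b > 0) up else down
  statement <- paste0(
    "methylation ", edge(b_step3, "->", "-|"), " expression ",
    edge(b_step1, "->", "-|"), " disease => methylation ",
    if (sign(b_step3) * sign(b_step1) > 0) "risk-increasing" else "protective",
    if (consistent) " (direct edge concordant)" else " (direct edge discordant)"
  )
  list(consistent = consistent, statement = statement)
}
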