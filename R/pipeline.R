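#' Run the end-to-end triangulation pipeline from files
#'
#' Reads the input tables, optionally pools multiple GWAS by
#' inverse-variance meta-analysis, applies the MAF filter, runs the
#' three-step SMR with HEIDI and colocalization gating, and writes the
#' per-step tables, the candidate chains, the forest-style report and a
#' run log into `out_dir`. Every gate decision is logged with the
#' threshold that triggered it; all outputs are tab-delimited text and
#' deterministic given the inputs and config.
#'
#' @param eqtl_path,mqtl_path path(s) to molecular sumstats TSVs.
#' @param gwas_paths character vector of one or more GWAS sumstats TSVs;
#'   more than one triggers meta-analysis first.
#' @param ld_path LD matrix TSV (header = variant ids), or NULL.
#' @param annotation_path annotation TSV (`feature_id chrom tss kind`).
#' @param gene_filter character vector of gene ids admitted to step 1, or
#'   a path to a one-column text file of ids.
#' @param out_dir output directory.
#' @param config a [triad_config()].
#' @param skip_triad only run the meta-analysis / locus definition stage.
#' @return invisibly, the [run_three_step()] result (or the meta dataset
#'   when `skip_triad`).
#' @export
run_pipeline <- function(eqtl_path, mqtl_path, gwas_paths, ld_path,
                         annotation_path, gene_filter, out_dir,
                         config = triad_config(), skip_triad = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)
  logf("config: %s",
       paste(names(config), vapply(config, function(x)
         paste(format(x), collapse = ","), character(1)),
         sep = "=", collapse = " "))

  gwas_list <- lapply(gwas_paths, read_sumstats, trait_kind = "disease")
  gwas <- if (length(gwas_list) > 1) {
    logf("meta-analysis of %d GWAS inputs", length(gwas_list))
    meta_analyze(gwas_list)
  } else gwas_list[[1]]
  gwas <- filter_by_maf(gwas, config$maf_min)
  qc <- attr(gwas, "qc_log")
  logf("MAF filter (maf_min=%g): %d dropped, %d unknown-eaf retained",
       config$maf_min, sum(qc$action == "drop_maf"),
       sum(qc$action == "maf_unknown"))
  write_sumstats(gwas, file.path(out_dir, "gwas_meta.tsv"))
  loci <- define_loci(gwas, config$p_sig, config$locus_window)
  write.table(loci, file.path(out_dir, "loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  logf("locus definition (p<%g, window %d bp): %d loci",
       config$p_sig, as.integer(config$locus_window), nrow(loci))
  if (skip_triad) return(invisible(gwas))

  eqtl <- read_sumstats(eqtl_path, trait_kind = "expression")
  mqtl <- read_sumstats(mqtl_path, trait_kind = "methylation")
  ld <- if (!is.null(ld_path)) read_ld(ld_path) else NULL
  annotation <- read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (length(gene_filter) == 1 && file.exists(gene_filter)) {
    gene_filter <- readLines(gene_filter)
    gene_filter <- gene_filter[nzchar(gene_filter)]
  }
  res <- run_three_step(eqtl, mqtl, gwas, ld, annotation, gene_filter,
                        config)
  for (nm in c("step1", "step2", "step3", "chains")) {
    write.table(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (i in seq_len(nrow(res$chains))) {
    ch <- res$chains[i, ]
    logf("chain %s/%s: fdr_all3=%s (q<%g) p_all=%s (p<%g) heidi=%s (p>%g) coloc=%s (PP.H4>%g) candidate=%s",
         ch$probe_id, ch$gene_id, ch$gate_fdr_all3, config$step_fdr,
         ch$gate_p_all_datasets, config$instr_p, ch$gate_heidi_all3,
         config$heidi_alpha, ch$gate_coloc, config$pph4_gate, ch$candidate)
  }
  report <- write_report(res$chains,
                         path = file.path(out_dir, "forest.tsv"))
  logf("%d candidate chain(s); report written", sum(res$chains$candidate))
  invisible(res)
}

#' Forest-style report of candidate chains
#'
#' One row per chain with OR = exp(b) and 95\% CI exp(b +/- 1.96 se) for
#' each step, q-values, HEIDI p-values, PP.H4 and the sign-chain
#' statement, in a fixed column order. An empty chain table produces a
#' header-only TSV and a "no candidates" summary line.
#'
#' @param chains the `chains` table from [run_three_step()].
#' @param path optional TSV output path.
#' @param digits significant digits for the printed OR/CI (default 3).
#' @return the report data.frame (attribute `"summary"` holds the
#'   human-readable lines), invisibly when `path` is given.
#' @export
write_report <- function(chains, path = NULL, digits = 3) {
  orci <- function(b, se) {
    lo <- exp(b - 1.96 * se); hi <- exp(b + 1.96 * se)
    sprintf(paste0("%.", digits - 1, "f [%.", digits - 1, "f-%.",
                   digits - 1, "f]"), exp(b), lo, hi)
  }
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    sc <- infer_sign_chain(ch$b_step1, ch$b_step2, ch$b_step3)
    data.frame(
      probe_id = ch$probe_id, gene_id = ch$gene_id,
      or_step1 = orci(ch$b_step1, ch$se_step1),
      or_step2 = orci(ch$b_step2, ch$se_step2),
      or_step3 = orci(ch$b_step3, ch$se_step3),
      q_step1 = ch$q_step1, q_step2 = ch$q_step2, q_step3 = ch$q_step3,
      p_heidi_step1 = ch$p_heidi_step1,
      p_heidi_step2 = ch$p_heidi_step2,
      p_heidi_step3 = ch$p_heidi_step3,
      pph4 = ch$coloc_pph4,
      sign_chain = sc$statement,
      sign_consistent = sc$consistent,
      candidate = ch$candidate,
      stringsAsFactors = FALSE
    )
  })
  report <- if (length(rows)) do.call(rbind, rows) else data.frame(
    probe_id = character(), gene_id = character(),
    or_step1 = character(), or_step2 = character(), or_step3 = character(),
    q_step1 = numeric(), q_step2 = numeric(), q_step3 = numeric(),
    p_heidi_step1 = numeric(), p_heidi_step2 = numeric(),
    p_heidi_step3 = numeric(), pph4 = numeric(),
    sign_chain = character(), sign_consistent = logical(),
    candidate = logical(), stringsAsFactors = FALSE)
  summary_lines <- if (!nrow(report)) {
    "no candidates"
  } else {
    vapply(seq_len(nrow(report)), function(i) {
      sprintf("%s -> %s: step1 OR %s, step2 OR %s, step3 OR %s; %s%s",
              report$probe_id[i], report$gene_id[i], report$or_step1[i],
              report$or_step2[i], report$or_step3[i], report$sign_chain[i],
              if (report$candidate[i]) " [candidate]" else "")
    }, character(1))
  }
  attr(report, "summary") <- summary_lines
  if (!is.null(path)) {
    write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(summary_lines, sub("\\.tsv$", "_summary.txt", path))
    return(invisible(report))
  }
  report
}
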