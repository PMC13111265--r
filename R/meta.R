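#' Fixed-effects inverse-variance-weighted meta-analysis of one variant
#'
#' METAL-style effect/SE scheme: weights `w_i = 1/se_i^2`, pooled beta
#' `sum(w*b)/sum(w)`, pooled SE `1/sqrt(sum(w))`. Cochran's Q and I^2 are
#' reported for heterogeneity inspection but never used for gating.
#'
#' @param beta,se numeric vectors of per-study estimates (harmonized to a
#'   common effect allele) and standard errors (> 0).
#' @return list with `pooled_beta, pooled_se, z, p, k_studies, direction,
#'   q_het, i2`.
#' @export
ivw_meta <- function(beta, se) {
  if (!length(beta)) stop("ivw_meta: no studies supplied")
  stopifnot(length(beta) == length(se))
  if (any(se <= 0)) stop("ivw_meta: se must be > 0")
  w <- 1 / se^2
  pooled_beta <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - pooled_beta)^2)
  k <- length(beta)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  list(
    pooled_beta = pooled_beta,
    pooled_se = pooled_se,
    z = pooled_beta / pooled_se,
    p = wald_p(pooled_beta, pooled_se),
    k_studies = k,
    direction = paste(ifelse(beta > 0, "+", ifelse(beta < 0, "-", "?")),
                      collapse = ""),
    q_het = q,
    i2 = i2
  )
}

#' Meta-analyze several harmonized GWAS datasets variant-by-variant
#'
#' Studies are joined on variant id; each variant is pooled across the
#' studies in which it appears. Allele orientation is harmonized to the
#' first study before pooling.
#'
#' @param studies list of `sumstats_dataset` (disease GWAS).
#' @param min_studies drop variants present in fewer studies (default 1).
#' @return a `sumstats_dataset` of pooled results (label "meta"), with
#'   extra columns `k_studies, direction, q_het, i2` in its records.
#' @export
meta_analyze <- function(studies, min_studies = 1L) {
  stopifnot(length(studies) >= 1)
  if (length(studies) > 1) {
    ref <- studies[[1]]
    studies <- c(list(ref), lapply(studies[-1], function(s) {
      h <- harmonize_datasets(ref, s)
      # keep the reference's variants only where harmonizable
      h
    }))
  }
  ids <- unique(unlist(lapply(studies, function(s) s$records$variant_id)))
  rows <- lapply(ids, function(id) {
    per <- lapply(studies, function(s) {
      r <- s$records[s$records$variant_id == id, , drop = FALSE]
      if (nrow(r)) r else NULL
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (length(per) < min_studies) return(NULL)
    b <- vapply(per, function(r) r$beta, numeric(1))
    se <- vapply(per, function(r) r$se, numeric(1))
    m <- ivw_meta(b, se)
    first <- per[[1]]
    data.frame(
      variant_id = id, chrom = first$chrom, pos = first$pos,
      effect_allele = first$effect_allele, other_allele = first$other_allele,
      eaf = mean(vapply(per, function(r) r$eaf, numeric(1)), na.rm = TRUE),
      beta = m$pooled_beta, se = m$pooled_se, p = m$p,
      n = sum(vapply(per, function(r) r$n, numeric(1))),
      k_studies = m$k_studies, direction = m$direction,
      q_het = m$q_het, i2 = m$i2,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rec <- do.call(rbind, rows)
  sumstats_dataset(rec, label = "meta", trait_kind = "disease", check = FALSE)
}

#' Greedy distance-based locus definition (clumping)
#'
#' Repeatedly takes the smallest-p unassigned genome-wide-significant
#' variant as an index and absorbs every significant variant on the same
#' chromosome within `window` bp. Ties in minimum p are broken by
#' (chrom, pos) order for determinism.
#'
#' @param records data.frame with `variant_id, chrom, pos, p`.
#' @param p_sig genome-wide significance threshold (default 5e-8).
#' @param window half-width of the locus window in bp (default 500000).
#' @return data.frame of loci: `index_variant, chrom, pos, p,
#'   window_start, window_end, n_members, member_variants` (the last a
#'   comma-separated id list); zero rows when nothing is significant.
#' @export
define_loci <- function(records, p_sig = 5e-8, window = 500000) {
  stopifnot(window > 0)
  if (inherits(records, "sumstats_dataset")) records <- records$records
  sig <- records[!is.na(records$p) & records$p < p_sig, , drop = FALSE]
  sig <- sig[order(sig$p, normalize_chrom(sig$chrom), sig$pos), ]
  loci <- list()
  while (nrow(sig)) {
    idx <- sig[1, ]
    member <- normalize_chrom(sig$chrom) == normalize_chrom(idx$chrom) &
      abs(sig$pos - idx$pos) <= window
    loci[[length(loci) + 1]] <- data.frame(
      index_variant = idx$variant_id, chrom = idx$chrom, pos = idx$pos,
      p = idx$p,
      window_start = max(1, idx$pos - window), window_end = idx$pos + window,
      n_members = sum(member),
      member_variants = paste(sig$variant_id[member], collapse = ","),
      stringsAsFactors = FALSE
    )
    sig <- sig[!member, , drop = FALSE]
  }
  if (!length(loci)) {
    return(data.frame(index_variant = character(), chrom = character(),
                      pos = numeric(), p = numeric(),
                      window_start = numeric(), window_end = numeric(),
                      n_members = integer(), member_variants = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, loci)
}

#' Replication concordance of index variants in an independent cohort
#'
#' After harmonizing the replication record to the discovery orientation,
#' an index variant is directionally consistent when the two betas share a
#' sign, and nominally replicated when the replication p < `p_nominal`.
#' A replication beta of exactly zero is flagged ambiguous and counted as
#' inconsistent.
#'
#' @param discovery,replication `sumstats_dataset` objects.
#' @param index_variants character vector of variant ids to check.
#' @param p_nominal nominal replication threshold (default 0.05).
#' @return list with `per_variant` (data.frame: variant_id, present,
#'   direction_consistent, ambiguous, p_replication, nominal) and `summary`
#'   (n_consistent, n_nominal, n_total).
#' @export
replication_concordance <- function(discovery, replication, index_variants,
                                    p_nominal = 0.05) {
  rep_h <- harmonize_datasets(discovery, replication)
  rows <- lapply(index_variants, function(id) {
    d <- discovery$records[discovery$records$variant_id == id, , drop = FALSE]
    r <- rep_h$records[rep_h$records$variant_id == id, , drop = FALSE]
    if (!nrow(d) || !nrow(r)) {
      return(data.frame(variant_id = id, present = FALSE,
                        direction_consistent = NA, ambiguous = NA,
                        p_replication = NA_real_, nominal = NA,
                        stringsAsFactors = FALSE))
    }
    amb <- r$beta == 0
    data.frame(
      variant_id = id, present = TRUE,
      direction_consistent = !amb && sign(d$beta) == sign(r$beta),
      ambiguous = amb,
      p_replication = r$p,
      nominal = r$p < p_nominal,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, rows)
  list(
    per_variant = per,
    summary = c(
      n_consistent = sum(per$direction_consistent, na.rm = TRUE),
      n_nominal = sum(per$nominal, na.rm = TRUE),
      n_total = sum(per$present)
    )
  )
}
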