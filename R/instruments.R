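#' Select cis instruments for a molecular exposure
#'
#' Retains cis variants (|pos - tss| <= `cis_window`) that pass both the
#' within-feature BH-FDR gate (q < `fdr_max`) and the hard p-value gate
#' (p < `p_max`), then greedily LD-prunes strongest-first so retained
#' instruments are mutually independent at r^2 < `prune_r2`. Variance
#' explained is the z-score approximation `r2 = z^2 / (z^2 + n - 2)` and
#' the instrument F-statistic is `(n - 2) * r2 / (1 - r2)`; for binary
#' outcomes the same observed-scale approximation is used.
#'
#' @param exposure a molecular `sumstats_dataset`.
#' @param feature_id feature (gene/probe) to instrument.
#' @param annotation data.frame with `feature_id, chrom, tss`.
#' @param ld optional `ld_matrix` covering the candidates; when absent,
#'   pruning falls back to distance (`prune_dist` bp).
#' @param cis_window cis window in bp (default 1e6).
#' @param p_max instrument p-value threshold (default 1e-5).
#' @param fdr_max within-feature BH-FDR threshold (default 0.05).
#' @param prune_r2 LD-pruning threshold on r^2 (default 0.1).
#' @param prune_dist fallback distance in bp when `ld` is NULL (default 1e5).
#' @return data.frame of instruments (`variant_id, beta_exp, se_exp, p_exp,
#'   n_exp, r2_exp, f_stat`), strongest first; zero rows when none qualify.
#' @export
select_instruments <- function(exposure, feature_id, annotation, ld = NULL,
                               cis_window = 1e6, p_max = 1e-5,
                               fdr_max = 0.05, prune_r2 = 0.1,
                               prune_dist = 1e5) {
  ann <- annotation[annotation$feature_id == feature_id, , drop = FALSE]
  empty <- data.frame(variant_id = character(), beta_exp = numeric(),
                      se_exp = numeric(), p_exp = numeric(),
                      n_exp = numeric(), r2_exp = numeric(),
                      f_stat = numeric(), stringsAsFactors = FALSE)
  if (!nrow(ann)) {
    warning("feature '", feature_id, "' absent from annotation; skipped")
    return(empty)
  }
  rec <- exposure$records
  cis <- rec[normalize_chrom(rec$chrom) == normalize_chrom(ann$chrom[1]) &
               abs(rec$pos - ann$tss[1]) <= cis_window, , drop = FALSE]
  if (!nrow(cis)) return(empty)
  q <- bh_fdr(cis$p)
  cis <- cis[q < fdr_max & cis$p < p_max, , drop = FALSE]
  if (!nrow(cis)) return(empty)
  cis <- cis[order(cis$p, cis$variant_id), , drop = FALSE]

  # greedy strongest-first pruning
  kept <- character(0)
  for (id in cis$variant_id) {
    ok <- if (!length(kept)) {
      TRUE
    } else if (!is.null(ld) && id %in% rownames(ld) &&
               all(kept %in% rownames(ld))) {
      all(unclass(ld)[id, kept]^2 < prune_r2)
    } else {
      pos_id <- cis$pos[cis$variant_id == id]
      pos_kept <- cis$pos[match(kept, cis$variant_id)]
      all(abs(pos_id - pos_kept) > prune_dist)
    }
    if (ok) kept <- c(kept, id)
  }
  cis <- cis[match(kept, cis$variant_id), , drop = FALSE]
  z2 <- (cis$beta / cis$se)^2
  r2 <- z2 / (z2 + cis$n - 2)
  data.frame(
    variant_id = cis$variant_id,
    beta_exp = cis$beta, se_exp = cis$se, p_exp = cis$p, n_exp = cis$n,
    r2_exp = r2, f_stat = (cis$n - 2) * r2 / (1 - r2),
    stringsAsFactors = FALSE
  )
}

#' Wald-ratio / IVW two-sample MR estimate for one feature
#'
#' One instrument gives the Wald ratio `b_out/b_exp` with the first-order
#' delta-method SE `sqrt(se_out^2/b_exp^2 + b_out^2 se_exp^2 / b_exp^4)`;
#' two or more give the fixed-effect IVW combination of per-instrument
#' ratios with weights `b_exp^2 / se_out^2` (the first-order inverse
#' variance treating the exposure as measured). Instruments with
#' `beta_exp == 0` are dropped.
#'
#' @param instruments data.frame with `variant_id, beta_exp, se_exp` and
#'   outcome columns `beta_out, se_out` (add them with
#'   [attach_outcome()]).
#' @return list (`MrResult` core): `method, beta, se, p, or_point,
#'   or_ci95, n_instruments`.
#' @export
ivw_mr <- function(instruments) {
  inst <- instruments[instruments$beta_exp != 0, , drop = FALSE]
  if (!nrow(inst)) stop("no usable instruments")
  if (nrow(inst) == 1) {
    b <- inst$beta_out / inst$beta_exp
    se <- sqrt(inst$se_out^2 / inst$beta_exp^2 +
                 inst$beta_out^2 * inst$se_exp^2 / inst$beta_exp^4)
    method <- "wald_ratio"
  } else {
    ratio <- inst$beta_out / inst$beta_exp
    w <- inst$beta_exp^2 / inst$se_out^2
    b <- sum(w * ratio) / sum(w)
    se <- 1 / sqrt(sum(w))
    method <- "ivw"
  }
  list(
    method = method, beta = b, se = se, p = wald_p(b, se),
    or_point = exp(b),
    or_ci95 = exp(b + c(-1, 1) * 1.96 * se),
    n_instruments = nrow(inst)
  )
}

#' Attach harmonized outcome statistics to an instrument table
#'
#' @param instruments instrument data.frame from [select_instruments()].
#' @param outcome a `sumstats_dataset` already harmonized to the exposure
#'   orientation (see [harmonize_datasets()]).
#' @return instruments with `beta_out, se_out, p_out, n_out, r2_out`
#'   columns; instruments absent from the outcome are dropped.
#' @export
attach_outcome <- function(instruments, outcome) {
  idx <- match(instruments$variant_id, outcome$records$variant_id)
  keep <- !is.na(idx)
  inst <- instruments[keep, , drop = FALSE]
  orec <- outcome$records[idx[keep], , drop = FALSE]
  inst$beta_out <- orec$beta
  inst$se_out <- orec$se
  inst$p_out <- orec$p
  inst$n_out <- orec$n
  z2 <- (orec$beta / orec$se)^2
  inst$r2_out <- z2 / (z2 + orec$n - 2)
  inst
}

#' Steiger directionality filter
#'
#' Passes when the instrument explains more variance in the exposure than
#' in the outcome (`r2_exp > r2_out`); equality fails (conservative), and
#' a missing sample size makes the instrument untestable, also treated as
#' a fail.
#'
#' @param instruments instrument data.frame with `r2_exp` and `r2_out`.
#' @return logical vector, one element per instrument.
#' @export
steiger_filter <- function(instruments) {
  r2e <- instruments$r2_exp
  r2o <- instruments$r2_out
  pass <- !is.na(r2e) & !is.na(r2o) & r2e > r2o
  pass
}
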