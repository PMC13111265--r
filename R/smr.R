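#' SMR test at the top cis-QTL instrument
#'
#' With `z_exp = b_exp/se_exp` and `z_out = b_out/se_out`, the SMR
#' statistic is `T = z_exp^2 z_out^2 / (z_exp^2 + z_out^2)`, referred to a
#' chi-square with 1 df; the ratio estimate is `b_smr = b_out/b_exp` with
#' `se_smr = |b_smr| / sqrt(T)`.
#'
#' @param beta_exp,se_exp,beta_out,se_out harmonized top-SNP statistics.
#' @return list with `b_smr, se_smr, p_smr, t_smr`.
#' @export
smr_test <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("degenerate instrument: beta_exp == 0")
  stopifnot(se_exp > 0, se_out > 0)
  z_exp2 <- (beta_exp / se_exp)^2
  z_out2 <- (beta_out / se_out)^2
  t_smr <- if (z_out2 == 0) 0 else z_exp2 * z_out2 / (z_exp2 + z_out2)
  b_smr <- beta_out / beta_exp
  list(
    b_smr = b_smr,
    se_smr = if (t_smr > 0) abs(b_smr) / sqrt(t_smr) else NA_real_,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE),
    t_smr = t_smr
  )
}

#' Tail probability of a positive linear combination of chi-square(1)
#' variables by three-moment (Liu-type) matching
#'
#' Approximates `P(sum_k lambda_k chi2_1k > q)` by matching the first
#' three (and partially the fourth) cumulants to a noncentral chi-square.
#'
#' @param q observed statistic.
#' @param lambda eigenvalue weights (non-negative up to tolerance).
#' @return upper-tail probability in [0, 1].
#' @export
pchisqsum_liu <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(1)
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (q <= 0) return(1)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  tstar <- (q - mu_q) / sigma_q
  pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

#' HEIDI heterogeneity-in-dependent-instruments test
#'
#' Compares the ratio estimate at every eligible cis SNP with the ratio at
#' the top SNP. Eligibility: exposure p below `p_exp_max`, LD r^2 with the
#' top SNP inside `r2_range`, capped at the `max_snps` smallest exposure
#' p-values (the top SNP itself is excluded from the difference set).
#' For each eligible SNP `i`, `d_i = b_i - b_top`; the covariance of the
#' d-vector follows from the first-order delta method with within-dataset
#' SNP-SNP covariances `Cov(b_hat_i, b_hat_j) = r_ij se_i se_j` and
#' independence across the exposure and outcome datasets. The statistic
#' `T = sum (d_i / sd_i)^2` is referred to the matched weighted chi-square
#' tail ([pchisqsum_liu()]) with weights the eigenvalues of the
#' correlation matrix of the standardized d's. Homogeneous (all ratios
#' identical) input gives T = 0 and p = 1.
#'
#' @param cis_exposure,cis_outcome data.frames of harmonized cis records
#'   (`variant_id, beta, se, p`) over a shared panel.
#' @param ld `ld_matrix` covering the panel (signed r, exposure
#'   orientation).
#' @param top variant id of the top (instrument) SNP.
#' @param p_exp_max exposure eligibility threshold (default 1.57e-3).
#' @param r2_range LD eligibility window on r^2 with the top SNP
#'   (default c(0.05, 0.9)).
#' @param max_snps cap on eligible SNPs, smallest exposure p first
#'   (default 20).
#' @param min_snps minimum eligible SNPs for a testable HEIDI
#'   (default 3); fewer returns `p_heidi = NA` with status
#'   `"heidi_untestable"`.
#' @return list: `p_heidi, n_snps_used, t_heidi, lambda, d_cor, status`.
#' @export
heidi_test <- function(cis_exposure, cis_outcome, ld, top,
                       p_exp_max = 1.57e-3, r2_range = c(0.05, 0.9),
                       max_snps = 20, min_snps = 3) {
  untestable <- function(n) list(p_heidi = NA_real_, n_snps_used = n,
                                 t_heidi = NA_real_, lambda = NULL,
                                 d_cor = NULL, status = "heidi_untestable")
  shared <- Reduce(intersect, list(cis_exposure$variant_id,
                                   cis_outcome$variant_id, rownames(ld)))
  if (!(top %in% shared)) return(untestable(0L))
  ex <- cis_exposure[match(shared, cis_exposure$variant_id), ]
  ou <- cis_outcome[match(shared, cis_outcome$variant_id), ]
  r_top <- unclass(ld)[shared, top]
  eligible <- shared != top &
    ex$p < p_exp_max &
    r_top^2 >= r2_range[1] & r_top^2 <= r2_range[2] &
    ex$beta != 0
  if (sum(eligible) > max_snps) {
    ord <- order(ex$p)
    keep_ids <- shared[ord][eligible[ord]][seq_len(max_snps)]
    eligible <- shared %in% keep_ids
  }
  m <- sum(eligible)
  if (m < min_snps) return(untestable(m))

  panel <- c(shared[eligible], top)          # top last
  ex_p <- ex[match(panel, shared), ]
  ou_p <- ou[match(panel, shared), ]
  R <- unclass(ld)[panel, panel]
  k <- length(panel)

  b <- ou_p$beta / ex_p$beta                 # ratio per SNP
  d <- b[-k] - b[k]

  # delta method: d depends on (beta_exp, beta_out) over the panel.
  # J_out[i, j] = d d_i / d beta_out_j ; J_exp likewise.
  J_out <- matrix(0, m, k)
  J_exp <- matrix(0, m, k)
  for (i in seq_len(m)) {
    J_out[i, i] <- 1 / ex_p$beta[i]
    J_out[i, k] <- -1 / ex_p$beta[k]
    J_exp[i, i] <- -ou_p$beta[i] / ex_p$beta[i]^2
    J_exp[i, k] <- ou_p$beta[k] / ex_p$beta[k]^2
  }
  S_exp <- R * tcrossprod(ex_p$se)
  S_out <- R * tcrossprod(ou_p$se)
  V <- J_out %*% S_out %*% t(J_out) + J_exp %*% S_exp %*% t(J_exp)
  sd_d <- sqrt(pmax(diag(V), 0))
  if (any(sd_d <= 0)) return(untestable(m))

  t_heidi <- sum((d / sd_d)^2)
  C <- V / tcrossprod(sd_d)
  lambda <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  p <- pchisqsum_liu(t_heidi, lambda)
  list(p_heidi = min(max(p, 0), 1), n_snps_used = m, t_heidi = t_heidi,
       lambda = lambda, d_cor = C, status = "ok")
}

#' Run the SMR + HEIDI test for one feature
#'
#' Picks the minimum-p cis variant of the exposure as the instrument
#' (requiring `p < p_max`), computes the SMR ratio test against the
#' outcome, and runs HEIDI over the cis window.
#'
#' @param exposure,outcome `sumstats_dataset`s (outcome already
#'   harmonized to the exposure orientation, e.g. via
#'   [harmonize_datasets()]).
#' @param feature_id feature to test (must be in `annotation`).
#' @param annotation data.frame with `feature_id, chrom, tss`.
#' @param ld `ld_matrix` or NULL (HEIDI untestable without it).
#' @param cis_window cis window in bp (default 1e6).
#' @param p_max top-instrument exposure p gate (default 1e-5).
#' @param ... passed to [heidi_test()].
#' @return one-row data.frame (`SmrResult`): `exposure_id, outcome_id,
#'   top_variant, p_exp_top, p_out_top, b_smr, se_smr, p_smr, p_heidi,
#'   n_heidi_snps, heidi_status`; NULL when no cis variant passes the gate.
#' @export
smr_feature <- function(exposure, outcome, feature_id, annotation, ld,
                        cis_window = 1e6, p_max = 1e-5, ...) {
  ann <- annotation[annotation$feature_id == feature_id, , drop = FALSE]
  if (!nrow(ann)) return(NULL)
  rec <- exposure$records
  cis_ids <- rec$variant_id[
    normalize_chrom(rec$chrom) == normalize_chrom(ann$chrom[1]) &
      abs(rec$pos - ann$tss[1]) <= cis_window]
  cis_ids <- intersect(cis_ids, outcome$records$variant_id)
  if (!length(cis_ids)) return(NULL)
  ex <- rec[match(cis_ids, rec$variant_id), ]
  ou <- outcome$records[match(cis_ids, outcome$records$variant_id), ]
  top_i <- which.min(ex$p)
  if (ex$p[top_i] >= p_max) return(NULL)
  top <- ex$variant_id[top_i]
  s <- smr_test(ex$beta[top_i], ex$se[top_i], ou$beta[top_i], ou$se[top_i])
  h <- if (is.null(ld)) {
    list(p_heidi = NA_real_, n_snps_used = 0L, status = "heidi_untestable")
  } else {
    heidi_test(ex, ou, ld, top, ...)
  }
  data.frame(
    exposure_id = feature_id, outcome_id = outcome$label,
    top_variant = top, p_exp_top = ex$p[top_i], p_out_top = ou$p[top_i],
    b_smr = s$b_smr, se_smr = s$se_smr, p_smr = s$p_smr,
    p_heidi = h$p_heidi, n_heidi_snps = h$n_snps_used,
    heidi_status = h$status, stringsAsFactors = FALSE
  )
}
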