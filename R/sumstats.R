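#' @importFrom stats pnorm pchisq p.adjust rnorm runif median
#' @importFrom utils read.table write.table modifyList
NULL

# canonical column set for a summary-statistics table
.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "p", "n")

# default dialect: GCTA-COJO ".ma"-style header plus CHR/POS
.DEFAULT_DIALECT <- c(
  variant_id = "SNP", chrom = "CHR", pos = "POS",
  effect_allele = "A1", other_allele = "A2",
  eaf = "freq", beta = "b", se = "se", p = "p", n = "N"
)

#' Construct a summary-statistics dataset
#'
#' A dataset is a label, a trait kind and a table of per-variant marginal
#' associations (one row per variant: id, chromosome, 1-based position,
#' effect/other allele, effect-allele frequency, beta, SE, p, sample size).
#' Betas are on the dataset's native scale: log-odds for a case-control
#' disease trait, SD units for molecular traits.
#'
#' @param records data.frame with columns `variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, n`.
#' @param label dataset label used in logs and outputs.
#' @param trait_kind one of `"disease"`, `"expression"`, `"methylation"`.
#' @param n_cases,n_controls optional case/control counts (disease only).
#' @param check recompute p from beta/se and flag rows whose printed p
#'   disagrees by more than `p_tol` relative (default TRUE). Discordant rows
#'   are kept with `p` recomputed and the printed value stored in
#'   `p_reported`, so that beta, se and p are internally consistent for all
#'   downstream tests.
#' @param p_tol relative tolerance for the beta/se/p concordance flag
#'   (default 0.05, reflecting inputs rounded to 4-5 significant figures).
#' @return object of class `sumstats_dataset`.
#' @export
sumstats_dataset <- function(records, label = "dataset",
                             trait_kind = c("disease", "expression", "methylation"),
                             n_cases = NA_integer_, n_controls = NA_integer_,
                             check = TRUE, p_tol = 0.05) {
  trait_kind <- match.arg(trait_kind)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.SUMSTATS_COLS, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, union(.SUMSTATS_COLS, names(records))]
  if (anyDuplicated(records$variant_id)) {
    stop("duplicate variant_id within dataset '", label, "'")
  }
  if (any(records$se <= 0, na.rm = TRUE)) stop("all se must be > 0")
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  if (any(bad_eaf)) stop("eaf outside [0, 1]")
  records$chrom <- normalize_chrom(records$chrom)
  if (check) {
    p_wald <- wald_p(records$beta, records$se)
    has_p <- !is.na(records$p)
    # flag discordant printed p; replace with the internally consistent value
    rel <- abs(records$p - p_wald) / pmax(p_wald, .Machine$double.xmin)
    discord <- has_p & rel > p_tol
    records$p_reported <- ifelse(discord, records$p, NA_real_)
    records$p_discordant <- discord
    records$p <- p_wald
  }
  structure(
    list(label = label, trait_kind = trait_kind, records = records,
         n_cases = n_cases, n_controls = n_controls),
    class = "sumstats_dataset"
  )
}

#' @export
print.sumstats_dataset <- function(x, ...) {
  cat(sprintf("<sumstats_dataset> '%s' (%s): %d variants\n",
              x$label, x$trait_kind, nrow(x$records)))
  invisible(x)
}

#' Read summary statistics from a delimited text file
#'
#' Reads a tab- or whitespace-delimited file with a header row. The default
#' column names follow the GCTA-COJO ".ma" convention (`SNP A1 A2 freq b se
#' p N`) plus `CHR`/`POS`; other headers are mapped via `dialect`. Rows that
#' fail type checks (non-numeric beta/se/p/n, se <= 0, p outside (0,1],
#' eaf outside [0,1]) are dropped and counted in the attached QC log.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical field names
#'   (`variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
#'   p, n`) to the file's column names; unspecified entries fall back to the
#'   default dialect.
#' @inheritParams sumstats_dataset
#' @return a `sumstats_dataset`; attribute `"qc_log"` holds a data.frame of
#'   dropped rows (`variant_id`, `action`).
#' @export
read_sumstats <- function(path, dialect = NULL, label = basename(path),
                          trait_kind = "disease", check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
               colClasses = "character", check.names = FALSE,
               comment.char = ""),
    error = function(e) stop("cannot parse '", path, "': ", conditionMessage(e))
  )
  if (!nrow(raw) || !ncol(raw)) stop("empty file: ", path)

  map <- .DEFAULT_DIALECT
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), names(map))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    map[names(dialect)] <- dialect
  }
  missing_cols <- map[!(map %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing required column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "))
  }

  df <- data.frame(
    variant_id    = raw[[map["variant_id"]]],
    chrom         = raw[[map["chrom"]]],
    pos           = suppressWarnings(as.numeric(raw[[map["pos"]]])),
    effect_allele = toupper(raw[[map["effect_allele"]]]),
    other_allele  = toupper(raw[[map["other_allele"]]]),
    eaf           = suppressWarnings(as.numeric(raw[[map["eaf"]]])),
    beta          = suppressWarnings(as.numeric(raw[[map["beta"]]])),
    se            = suppressWarnings(as.numeric(raw[[map["se"]]])),
    p             = suppressWarnings(as.numeric(raw[[map["p"]]])),
    n             = suppressWarnings(as.numeric(raw[[map["n"]]])),
    stringsAsFactors = FALSE
  )

  action <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    action[is.na(action) & cond] <<- why
  }
  bad(is.na(df$beta), "drop_bad_beta")
  bad(is.na(df$se) | df$se <= 0, "drop_bad_se")
  bad(!is.na(df$p) & (df$p <= 0 | df$p > 1), "drop_bad_p")
  bad(is.na(df$n) | df$n <= 0, "drop_bad_n")
  bad(is.na(df$pos) | df$pos < 1, "drop_bad_pos")
  bad(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "drop_bad_eaf")
  bad(!grepl("^[ACGT]+$|^[DI]$", df$effect_allele) |
        !grepl("^[ACGT]+$|^[DI]$", df$other_allele), "drop_bad_allele")

  qc <- data.frame(variant_id = df$variant_id[!is.na(action)],
                   action = action[!is.na(action)],
                   stringsAsFactors = FALSE)
  ds <- sumstats_dataset(df[is.na(action), , drop = FALSE], label = label,
                         trait_kind = trait_kind, check = check)
  attr(ds, "qc_log") <- qc
  ds
}

#' Write a dataset back to the canonical tab-delimited format
#'
#' @param ds a `sumstats_dataset`.
#' @param path output file path.
#' @export
write_sumstats <- function(ds, path) {
  stopifnot(inherits(ds, "sumstats_dataset"))
  out <- ds$records[, .SUMSTATS_COLS]
  names(out) <- c("SNP", "CHR", "POS", "A1", "A2", "freq", "b", "se", "p", "N")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

strand_flip <- function(allele) {
  vapply(strsplit(allele, ""), function(ch) {
    if (all(ch %in% names(.COMPLEMENT))) paste(.COMPLEMENT[ch], collapse = "")
    else paste(ch, collapse = "")
  }, character(1))
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize an outcome record to the exposure's allele orientation
#'
#' Aligns an outcome association to the exposure's effect allele. Alleles
#' already matching are left unchanged; swapped alleles flip the outcome
#' beta sign and fold eaf to 1-eaf; strand-complement pairs are resolved
#' first and then treated the same way. Palindromic variants (A/T or C/G)
#' whose eaf is within `palindromic_eaf_band` of 0.5 cannot be oriented
#' reliably and are dropped, as are irreconcilable allele pairs.
#'
#' @param exposure,outcome single-row data.frames (or lists) with
#'   `effect_allele, other_allele, beta, eaf` (and the same `variant_id`).
#' @param palindromic_eaf_band half-width of the ambiguity band around 0.5
#'   (default 0.08).
#' @return list with `record` (harmonized outcome, or NULL when dropped)
#'   and `action` in `same | flip | strand | strand_flip | drop_palindromic
#'   | drop_mismatch`.
#' @export
harmonize_pair <- function(exposure, outcome, palindromic_eaf_band = 0.08) {
  if (!is.null(exposure$variant_id) && !is.null(outcome$variant_id) &&
      exposure$variant_id != outcome$variant_id) {
    stop("harmonize_pair: variant_id mismatch")
  }
  e1 <- toupper(exposure$effect_allele); e2 <- toupper(exposure$other_allele)
  o1 <- toupper(outcome$effect_allele); o2 <- toupper(outcome$other_allele)

  if (is_palindromic(o1, o2)) {
    eaf <- outcome$eaf
    if (is.na(eaf %||% NA_real_) || abs(eaf - 0.5) <= palindromic_eaf_band) {
      return(list(record = NULL, action = "drop_palindromic"))
    }
  }

  flip_record <- function(rec) {
    rec$beta <- -rec$beta
    tmp <- rec$effect_allele
    rec$effect_allele <- rec$other_allele
    rec$other_allele <- tmp
    if (!is.null(rec$eaf) && !is.na(rec$eaf)) rec$eaf <- 1 - rec$eaf
    rec
  }

  if (o1 == e1 && o2 == e2) return(list(record = outcome, action = "same"))
  if (o1 == e2 && o2 == e1) return(list(record = flip_record(outcome), action = "flip"))

  # try the opposite strand
  s1 <- strand_flip(o1); s2 <- strand_flip(o2)
  if (s1 == e1 && s2 == e2) {
    outcome$effect_allele <- s1; outcome$other_allele <- s2
    return(list(record = outcome, action = "strand"))
  }
  if (s1 == e2 && s2 == e1) {
    outcome$effect_allele <- s1; outcome$other_allele <- s2
    return(list(record = flip_record(outcome), action = "strand_flip"))
  }
  list(record = NULL, action = "drop_mismatch")
}

#' Harmonize a whole outcome dataset against an exposure dataset
#'
#' Merges by variant id and applies [harmonize_pair()] row-wise; dropped
#' variants are recorded in the attached QC log.
#'
#' @param exposure,outcome `sumstats_dataset` objects sharing variant ids.
#' @inheritParams harmonize_pair
#' @return the outcome dataset restricted to harmonizable shared variants,
#'   oriented to the exposure's effect alleles; attribute `"qc_log"` lists
#'   per-variant actions.
#' @export
harmonize_datasets <- function(exposure, outcome, palindromic_eaf_band = 0.08) {
  stopifnot(inherits(exposure, "sumstats_dataset"),
            inherits(outcome, "sumstats_dataset"))
  shared <- intersect(exposure$records$variant_id, outcome$records$variant_id)
  erec <- exposure$records[match(shared, exposure$records$variant_id), ]
  orec <- outcome$records[match(shared, outcome$records$variant_id), ]
  out_rows <- vector("list", length(shared))
  actions <- character(length(shared))
  for (i in seq_along(shared)) {
    h <- harmonize_pair(erec[i, ], orec[i, ], palindromic_eaf_band)
    actions[i] <- h$action
    out_rows[[i]] <- h$record
  }
  keep <- !vapply(out_rows, is.null, logical(1))
  rec <- if (any(keep)) do.call(rbind, out_rows[keep]) else orec[0, ]
  ds <- sumstats_dataset(rec, label = outcome$label,
                         trait_kind = outcome$trait_kind,
                         n_cases = outcome$n_cases,
                         n_controls = outcome$n_controls, check = FALSE)
  attr(ds, "qc_log") <- data.frame(variant_id = shared, action = actions,
                                   stringsAsFactors = FALSE)
  ds
}

#' Filter a dataset by minor-allele frequency
#'
#' Retains records whose folded frequency `min(eaf, 1-eaf)` is at least
#' `maf_min`. Records with missing eaf are retained and flagged
#' `maf_unknown` in the QC log rather than discarded.
#'
#' @param ds a `sumstats_dataset`.
#' @param maf_min minimum minor-allele frequency in `[0, 0.5]`
#'   (default 0.005, i.e. MAF < 0.5\% excluded).
#' @return filtered `sumstats_dataset` with attribute `"qc_log"`.
#' @export
filter_by_maf <- function(ds, maf_min = 0.005) {
  stopifnot(inherits(ds, "sumstats_dataset"),
            maf_min >= 0, maf_min <= 0.5)
  eaf <- ds$records$eaf
  maf <- pmin(eaf, 1 - eaf)
  keep <- is.na(maf) | maf >= maf_min
  qc <- data.frame(
    variant_id = ds$records$variant_id,
    action = ifelse(is.na(maf), "maf_unknown",
                    ifelse(keep, "keep", "drop_maf")),
    stringsAsFactors = FALSE
  )
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  attr(out, "qc_log") <- qc
  out
}

#' Two-sided Wald p-value
#'
#' `p = 2 * Phi(-|beta/se|)`, evaluated through the log-scale normal
#' survival function so extreme z-scores do not underflow prematurely
#' (accurate well beyond |z| = 37; with `log.p = TRUE` the log p-value is
#' returned and stays finite for arbitrarily large |z|).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), all > 0.
#' @param log.p return log(p) instead of p.
#' @return p-values in (0, 1] (or their logs).
#' @export
wald_p <- function(beta, se, log.p = FALSE) {
  if (any(se <= 0, na.rm = TRUE)) stop("wald_p: se must be > 0")
  z <- abs(beta / se)
  lp <- pnorm(z, lower.tail = FALSE, log.p = TRUE) + log(2)
  lp <- pmin(lp, 0)  # beta == 0 -> p exactly 1
  if (log.p) lp else exp(lp)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment: `q(i) = min_{j: rank(j) >= rank(i)} m * p(j) /
#' rank(j)`, capped at 1, returned in input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values aligned with the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) stop("bh_fdr: empty p-value vector")
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
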