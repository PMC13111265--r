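#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values (may contain `-Inf`).
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log of a difference of exponentials, log(exp(a) - exp(b)), a >= b
#'
#' Small negative arguments arising from rounding (a slightly below b) are
#' clamped to -Inf with a warning; this occurs for single-SNP or degenerate
#' panels where the pairwise evidence is numerically indistinguishable from
#' the joint evidence.
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b > a) {
    if (b - a > 1e-6) {
      warning("logdiffexp: negative difference clamped to -Inf")
    }
    return(-Inf)
  }
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Normalize chromosome labels
#'
#' Strips a leading "chr"/"Chr" prefix so "chr8" and "8" compare equal.
#' @param chrom character vector of chromosome labels.
#' @return character vector without the prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seeds (kept < 2^31) from one master seed
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
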