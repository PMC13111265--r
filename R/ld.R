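#' Construct / validate an LD correlation matrix
#'
#' A square matrix of pairwise allelic correlations (signed r, not r^2)
#' keyed by variant id through its dimnames. Signs must follow the same
#' allele orientation as the harmonized summary statistics.
#'
#' @param r square numeric matrix with unit diagonal.
#' @param variant_ids optional ids (taken from dimnames when absent).
#' @param tol eigenvalue tolerance for the PSD check (default 1e-8).
#' @return the matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids = NULL, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(variant_ids)) variant_ids <- rownames(r)
  if (is.null(variant_ids)) stop("LD matrix needs variant ids (dimnames)")
  if (length(variant_ids) != nrow(r)) stop("variant_ids length mismatch")
  dimnames(r) <- list(variant_ids, variant_ids)
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix must have unit diagonal")
  if (any(abs(r) > 1 + 1e-8)) stop("LD correlations must lie in [-1, 1]")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) stop("LD matrix is not positive semi-definite")
  structure(r, class = c("ld_matrix", "matrix"))
}

#' AR(1) LD matrix, r_jk = rho^|j-k|
#'
#' @param m number of variants.
#' @param rho first-order autocorrelation, |rho| < 1.
#' @param variant_ids ids for the panel (default snp001..).
#' @export
ar1_ld <- function(m, rho, variant_ids = sprintf("snp%03d", seq_len(m))) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  r <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  ld_matrix(r, variant_ids)
}

#' Read / write an LD matrix as TSV (header = variant ids, square body)
#' @param path file path.
#' @rdname ld_io
#' @export
read_ld <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, row.names = NULL))
  ld_matrix(m, colnames(m))
}

#' @param ld an `ld_matrix`.
#' @rdname ld_io
#' @export
write_ld <- function(ld, path) {
  write.table(format(unclass(ld), digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# subset an LD matrix to a panel of ids, preserving class
ld_subset <- function(ld, ids) {
  stopifnot(all(ids %in% rownames(ld)))
  r <- unclass(ld)[ids, ids, drop = FALSE]
  structure(r, class = c("ld_matrix", "matrix"))
}
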