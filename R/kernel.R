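# exponentiated-BLOSUM table used by every kernel entry point; memoised
# because it only depends on beta
kernel_exp_table <- function(beta = 0.11387) {
  key <- paste0("E_", format(beta, digits = 12))
  if (is.null(.icorerf_env[[key]])) {
    .icorerf_env[[key]] <- exp(beta * blosum62())
  }
  .icorerf_env[[key]]
}

#' BLOSUM62 k-mer peptide kernel similarity
#'
#' Normalised string-kernel similarity between two peptides. The raw
#' kernel sums, over window lengths `kmin..kmax` (3-8 by default) and
#' over every pair of equal-length windows (one from each peptide), a
#' match score formed as the product over aligned positions of
#' `exp(beta * BLOSUM62[x, y])`. The reported similarity is
#' `K(a,b) / sqrt(K(a,a) * K(b,b))`, so it lies in (0, 1], equals 1 for
#' identical peptides, and is symmetric. By construction the central
#' residues take part in more windows than the termini, so the centre
#' of the peptide dominates the score.
#'
#' This one similarity serves both the self-similarity feature
#' (mutant vs wild-type ICORE) and the redundancy scan used to build
#' leakage-free cross-validation folds.
#'
#' @param a,b Character vectors of peptides (recycled to equal length).
#'   Both must be at least `kmin` residues long.
#' @param beta Kernel inverse temperature applied to BLOSUM62 scores
#'   (default 0.11387, the published constant of the kernel).
#' @param kmin,kmax Window length range (defaults 3 and 8).
#' @return Numeric vector of similarities in (0, 1].
#' @export
#' @examples
#' kernel_similarity("SLLMWITQV", "SLLMWITQC")
#' kernel_similarity("SLLMWITQV", "SLLMWITQV")
kernel_similarity <- function(a, b, beta = 0.11387, kmin = 3L, kmax = 8L) {
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
  }
  if (any(nchar(a) < kmin) || any(nchar(b) < kmin)) {
    stop("kernel_similarity: peptides must have at least ", kmin, " residues")
  }
  cpp_kernel_elementwise(pep_encode(a), pep_encode(b),
                         kernel_exp_table(beta), as.integer(kmin),
                         as.integer(kmax))
}

#' Pairwise kernel similarity matrix
#'
#' All-pairs version of [kernel_similarity()], used for leakage audits
#' and brute-force checks.
#'
#' @inheritParams kernel_similarity
#' @param x,y Character vectors of peptides; `y` defaults to `x`.
#' @return A `length(x)` by `length(y)` numeric matrix.
#' @export
kernel_matrix <- function(x, y = x, beta = 0.11387, kmin = 3L, kmax = 8L) {
  if (any(nchar(c(x, y)) < kmin)) {
    stop("kernel_matrix: peptides must have at least ", kmin, " residues")
  }
  m <- cpp_kernel_matrix(pep_encode(x), pep_encode(y),
                         kernel_exp_table(beta), as.integer(kmin),
                         as.integer(kmax))
  dimnames(m) <- list(x, y)
  m
}
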