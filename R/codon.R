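# Standard genetic code, vendored as a named vector (codon -> one-letter
# residue, "*" = stop) so the codon mutation score has no external data
# dependency.
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # residues listed in textbook codon-table order: second base slowest,
  # then first base, then third (TTT TTC TTA TTG, CTT ... GTG, TCT ...)
  aas <- c(
    "F", "F", "L", "L", "L", "L", "L", "L", "I", "I", "I", "M",
    "V", "V", "V", "V", "S", "S", "S", "S", "P", "P", "P", "P",
    "T", "T", "T", "T", "A", "A", "A", "A", "Y", "Y", "*", "*",
    "H", "H", "Q", "Q", "N", "N", "K", "K", "D", "D", "E", "E",
    "C", "C", "*", "W", "R", "R", "R", "R", "S", "S", "R", "R",
    "G", "G", "G", "G"
  )
  codons <- character(64)
  k <- 0L
  for (b2 in bases) for (b1 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
}

#' Codon single-nucleotide mutation probability matrix
#'
#' For an ordered residue pair (wt, mut), the probability that a single
#' nucleotide substitution of a codon encoding `wt` yields a codon
#' encoding `mut`, averaged uniformly over the synonymous `wt` codons.
#' Each codon has 9 single-nucleotide neighbours (3 positions x 3
#' alternative bases), all taken as equally likely; neighbours that are
#' stop codons count as non-matching. No codon-usage weighting is
#' applied.
#'
#' @return A 20 x 20 numeric matrix, rows = wild-type residue, columns =
#'   mutant residue, entries in \[0, 1\]. Memoised after the first call.
#' @export
#' @examples
#' codon_mutation_matrix()["A", "V"] # 1/9: one of nine substitutions of
#'                                   # any GCN codon reaches valine
codon_mutation_matrix <- function() {
  if (!is.null(.icorerf_env$codon_matrix)) {
    return(.icorerf_env$codon_matrix)
  }
  gc <- genetic_code()
  aa <- aa_alphabet()
  bases <- c("T", "C", "A", "G")
  m <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (wt in aa) {
    wt_codons <- names(gc)[gc == wt]
    probs <- setNames(numeric(20), aa)
    for (codon in wt_codons) {
      hits <- setNames(numeric(20), aa)
      nt <- strsplit(codon, "")[[1]]
      for (pos in 1:3) {
        for (b in setdiff(bases, nt[pos])) {
          neigh <- nt
          neigh[pos] <- b
          res <- gc[[paste0(neigh, collapse = "")]]
          if (res != "*") hits[res] <- hits[res] + 1
        }
      }
      probs <- probs + hits / 9
    }
    m[wt, ] <- probs / length(wt_codons)
  }
  .icorerf_env$codon_matrix <- m
  m
}
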