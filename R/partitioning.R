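#' Hobohm-1 redundancy scan
#'
#' Greedy scan of the peptides in input order under the BLOSUM62 k-mer
#' kernel similarity: a peptide joins the cluster of the
#' maximum-similarity representative among those whose similarity
#' exceeds the threshold, otherwise it becomes a new representative.
#' The retained representative set is therefore pairwise at or below
#' the threshold. Input order is the scan order, which keeps the
#' procedure reproducible from the raw file.
#'
#' @param peptides Character vector of peptides (length >= 3 each).
#' @param threshold Similarity threshold (default 0.9).
#' @param beta Kernel inverse temperature (see [kernel_similarity()]).
#' @return A list with `representatives` (indices into `peptides`),
#'   `assignment` (per peptide, the index of its representative; its
#'   own index for representatives), `similarity` (similarity to the
#'   assigned representative; 1 for representatives), and `clusters`
#'   (list mapping each representative index to its member indices).
#' @export
hobohm1 <- function(peptides, threshold = 0.9, beta = 0.11387) {
  stopifnot(length(peptides) > 0L)
  res <- cpp_hobohm1(pep_encode(peptides), kernel_exp_table(beta),
                     3L, 8L, threshold)
  assignment <- res$rep
  reps <- which(assignment == seq_along(peptides))
  members <- which(assignment != seq_along(peptides))
  clusters <- split(members, assignment[members])
  list(representatives = reps, assignment = assignment,
       similarity = res$sim, clusters = clusters)
}

#' Similarity-aware fold assignment
#'
#' Builds a leakage-free `k`-fold partition plan: redundant peptides
#' are first set aside by [hobohm1()], the dissimilar representatives
#' are shuffled with the seed and dealt round-robin into `k` folds
#' (balanced to within one before reinsertion), and each held-out
#' peptide is then reinserted into the fold of its maximum-similarity
#' representative — exact duplicates land in their duplicate's fold.
#' Similarity is computed on the full mutant peptides, not the ICOREs.
#'
#' @param records A record data frame with a `mutant_peptide` column.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the representative shuffle.
#' @param threshold Kernel similarity threshold (default 0.9).
#' @return A list of class `partition_plan` with `fold` (0-based fold
#'   id per record), `hobohm` (the scan result), `k`, `seed`,
#'   `threshold`.
#' @export
make_partitions <- function(records, k = 10L, seed = 1L, threshold = 0.9) {
  hb <- hobohm1(records$mutant_peptide, threshold = threshold)
  reps <- hb$representatives
  if (length(reps) < k) {
    stop("make_partitions: only ", length(reps),
         " dissimilar representatives for ", k, " folds")
  }
  fold <- rep(NA_integer_, nrow(records))
  shuffled <- with_seed(derive_seed(seed, "partition"),
                        sample(reps, length(reps)))
  fold[shuffled] <- (seq_along(shuffled) - 1L) %% k
  # reinsertion: held-out similar peptides follow their representative
  members <- which(hb$assignment != seq_along(fold))
  fold[members] <- fold[hb$assignment[members]]
  structure(
    list(fold = fold, hobohm = hb, k = as.integer(k), seed = seed,
         threshold = threshold),
    class = "partition_plan"
  )
}

#' Cross-fold similarity leakage audit
#'
#' Brute-force all-pairs check that no two peptides assigned to
#' different folds exceed the similarity threshold. Quadratic; intended
#' for test-scale data and training-time sanity logs.
#'
#' @param peptides Character vector of peptides.
#' @param fold Integer fold id per peptide.
#' @param threshold Similarity threshold (default 0.9).
#' @return A list with `max_cross_fold_similarity` and `n_violations`.
#' @export
audit_partitions <- function(peptides, fold, threshold = 0.9) {
  m <- kernel_matrix(peptides)
  diff_fold <- outer(fold, fold, "!=")
  upper <- upper.tri(m)
  cross <- m[diff_fold & upper]
  list(max_cross_fold_similarity = if (length(cross)) max(cross) else 0,
       n_violations = sum(cross > threshold))
}
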