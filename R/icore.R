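#' Extract the ICORE of a mutant peptide
#'
#' Scores every contiguous sub-window of lengths 8 to `min(12, L)` of
#' the peptide with the rank predictor and returns the window with the
#' best (lowest) predicted percentile rank — the ICORE, i.e. the
#' sub-peptide predicted to actually be presented. Ties are broken
#' towards the longer window, then the smaller offset, so extraction is
#' fully reproducible.
#'
#' @inheritParams predict_rank
#' @param peptide A single peptide of length >= 8.
#' @return A list with `icore`, `offset` (0-based start), `length`,
#'   `rank`.
#' @export
#' @examples
#' \dontrun{
#' extract_icore("SLLMWITQVAK", "HLA-A*02:01", predictor)
#' }
extract_icore <- function(peptide, allele, predictor) {
  stopifnot(length(peptide) == 1L)
  L <- nchar(peptide)
  if (L < 8L) stop("extract_icore: peptide shorter than 8 residues")
  cand <- icore_candidates(peptide)
  cand$rank <- NA_real_
  for (wl in unique(cand$length)) {
    sel <- cand$length == wl
    cand$rank[sel] <- predict_rank(predictor, cand$icore[sel], allele)
  }
  best <- pick_best_window(cand)
  as.list(best[c("icore", "offset", "length", "rank")])
}

# all contiguous sub-windows of lengths 8..min(12, L)
icore_candidates <- function(peptide) {
  L <- nchar(peptide)
  out <- list()
  for (wl in 8:min(12L, L)) {
    offs <- 0:(L - wl)
    out[[length(out) + 1L]] <- data.frame(
      icore = substring(peptide, offs + 1L, offs + wl),
      offset = offs, length = wl, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# argmin rank, ties -> longer window, then smaller offset
pick_best_window <- function(cand) {
  ord <- order(cand$rank, -cand$length, cand$offset)
  cand[ord[1L], , drop = FALSE]
}

#' Align the wild-type ICORE and complete an ICORE pair
#'
#' The wild-type ICORE is the substring of the wild-type peptide at the
#' mutant ICORE's (offset, length); its percentile rank is predicted on
#' the same allele. The two full peptides must have equal length
#' (frameshifted pairs are filtered upstream).
#'
#' @inheritParams predict_rank
#' @param icore Result of [extract_icore()].
#' @param wt_peptide Wild-type peptide, same length as the mutant.
#' @return A list of class `icore_pair` with `mut_icore`, `wt_icore`,
#'   `offset`, `length`, `mut_rank`, `wt_rank`, `allele`.
#' @export
align_wt_icore <- function(icore, wt_peptide, allele, predictor) {
  wt_icore <- substr(wt_peptide, icore$offset + 1L,
                     icore$offset + icore$length)
  if (nchar(wt_icore) != icore$length) {
    stop("align_wt_icore: wild-type peptide shorter than the mutant ",
         "(length mismatch should have been filtered upstream)")
  }
  structure(
    list(mut_icore = icore$icore, wt_icore = wt_icore,
         offset = icore$offset, length = icore$length,
         mut_rank = icore$rank,
         wt_rank = predict_rank(predictor, wt_icore, allele),
         allele = allele),
    class = "icore_pair"
  )
}

# Hamming mismatch positions (1-based) between equal-length strings
mismatch_positions <- function(a, b) {
  which(aa_split(a) != aa_split(b))
}

#' Locate and classify the mutations of an ICORE pair
#'
#' Mutation positions are the Hamming mismatches between the mutant and
#' wild-type ICOREs (1-based within the ICORE). Each is flagged as an
#' anchor mutation when it falls on an anchor position of the allele's
#' profile for that ICORE length. The `any_mutation_outside_icore` flag
#' is computed on the full peptide pair: it is `TRUE` when at least one
#' full-peptide mismatch is not covered by the ICORE span.
#'
#' @param pair An `icore_pair` from [align_wt_icore()].
#' @param mut_peptide,wt_peptide The full peptide pair.
#' @param profile The `anchor_profile` for (allele, ICORE length).
#' @param anchor_threshold IC threshold defining anchors (default 0.2).
#' @return A list with `positions` (integer, 1-based in the ICORE),
#'   `anchor_flags` (logical, per mutation),
#'   `any_mutation_outside_icore` (logical scalar).
#' @export
mutation_profile <- function(pair, mut_peptide, wt_peptide, profile,
                             anchor_threshold = 0.2) {
  pos <- mismatch_positions(pair$mut_icore, pair$wt_icore)
  anchors <- anchor_positions(profile, anchor_threshold)
  full_pos <- mismatch_positions(mut_peptide, wt_peptide)
  span <- (pair$offset + 1L):(pair$offset + pair$length)
  list(
    positions = pos,
    anchor_flags = pos %in% anchors,
    any_mutation_outside_icore = !all(full_pos %in% span)
  )
}

#' Extract ICORE pairs for a whole dataset
#'
#' Vectorised driver used by the pipeline: for each record, extracts
#' the mutant ICORE, aligns the wild-type ICORE and predicts both
#' ranks. Predictions are batched per (allele, window length) so large
#' datasets stay fast.
#'
#' @inheritParams predict_rank
#' @param records A neo-epitope data frame with columns
#'   `mutant_peptide`, `wt_peptide`, `allele`.
#' @return `records` with appended columns `icore_mut`, `icore_wt`,
#'   `icore_offset` (0-based), `icore_len`, `rank_mut`, `rank_wt`,
#'   `n_icore_mismatches`.
#' @export
extract_icores <- function(records, predictor) {
  n <- nrow(records)
  cands <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- icore_candidates(records$mutant_peptide[i])
    ci$row <- i
    cands[[i]] <- ci
  }
  all_cand <- do.call(rbind, cands)
  all_cand$allele <- records$allele[all_cand$row]
  all_cand$rank <- NA_real_
  for (al in unique(all_cand$allele)) {
    for (wl in unique(all_cand$length)) {
      sel <- all_cand$allele == al & all_cand$length == wl
      if (!any(sel)) next
      all_cand$rank[sel] <- predict_rank(predictor, all_cand$icore[sel], al)
    }
  }
  best <- do.call(rbind, lapply(split(all_cand, all_cand$row),
                                pick_best_window))
  best <- best[order(best$row), ]
  records$icore_mut <- best$icore
  records$icore_offset <- best$offset
  records$icore_len <- best$length
  records$rank_mut <- best$rank
  records$icore_wt <- substr(records$wt_peptide, best$offset + 1L,
                             best$offset + best$length)
  records$rank_wt <- NA_real_
  for (al in unique(records$allele)) {
    sel <- records$allele == al
    records$rank_wt[sel] <- predict_rank(predictor,
                                         records$icore_wt[sel], al)
  }
  records$n_icore_mismatches <- mapply(
    function(a, b) length(mismatch_positions(a, b)),
    records$icore_mut, records$icore_wt, USE.NAMES = FALSE)
  records
}
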