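#' Predict eluted-ligand percentile ranks
#'
#' Generic contract for pluggable MHC presentation predictors: given
#' peptides and one HLA-I allele, return the eluted-ligand percentile
#' rank, a value in \[0, 100\] where lower means stronger predicted
#' presentation. Implementations must be deterministic and defined for
#' peptide lengths 8-12 on every allele they advertise.
#'
#' Two implementations ship with the package: a deterministic
#' motif-PSSM surrogate ([surrogate_predictor()]) so the whole pipeline
#' runs without external binaries, and a lookup table over pre-computed
#' NetMHCpan-4.1 output ([table_predictor()]).
#'
#' @param predictor A predictor object.
#' @param peptides Character vector of peptides, lengths 8-12.
#' @param allele A single canonical HLA-I allele name.
#' @return Numeric vector of percentile ranks in \[0, 100\].
#' @export
predict_rank <- function(predictor, peptides, allele) {
  UseMethod("predict_rank")
}

#' Alleles covered by a rank predictor
#' @param predictor A predictor object.
#' @return Character vector of canonical allele names.
#' @export
predictor_alleles <- function(predictor) UseMethod("predictor_alleles")

check_peptide_lengths <- function(peptides, lengths = 8:12) {
  bad <- !(nchar(peptides) %in% lengths)
  if (any(bad)) {
    stop("predict_rank: peptide length outside 8-12: ",
         paste(head(peptides[bad], 3), collapse = ", "))
  }
}

# ---------------------------------------------------------------------------
# Surrogate motif predictor

#' Build a surrogate HLA allele
#'
#' A desk-scale stand-in for a neural MHC presentation predictor. Each
#' allele carries, per peptide length 8-12, a position-specific residue
#' preference table with concentrated preferences at its anchor
#' positions (position 2 and the C-terminal position, plus optionally
#' one more), and a sorted background sample of raw scores of seeded
#' random peptides. The raw score of a peptide is the sum of
#' per-position log-preference values (log of preference over the
#' uniform 1/20 background); its percentile rank is
#' `100 * fraction of background scores >= raw score`, mirroring
#' eluted-ligand \%Rank semantics (lower = stronger).
#'
#' @param name Canonical allele name, e.g. `"HLA-A*02:01"`.
#' @param seed Integer seed; the allele is fully determined by it.
#' @param extra_anchor If `TRUE` a third anchor position is added.
#' @param background_size Background sample size per length
#'   (default 10000).
#' @return An object of class `surrogate_allele`.
#' @export
surrogate_allele <- function(name, seed, extra_anchor = FALSE,
                             background_size = 10000L) {
  aa <- aa_alphabet()
  lengths <- 8:12
  with_seed(seed, {
    prefs <- list()
    anchors <- list()
    for (L in lengths) {
      anc <- c(2L, L)
      if (extra_anchor) anc <- sort(unique(c(anc, sample(3:(L - 1), 1L))))
      p <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, aa))
      for (pos in seq_len(L)) {
        if (pos %in% anc) {
          fav <- sample(20L, 2L)
          v <- rep((1 - 0.45 - 0.25) / 18, 20)
          v[fav[1]] <- 0.45
          v[fav[2]] <- 0.25
        } else {
          # near-uniform: Dirichlet with high concentration
          g <- rgamma(20, shape = 60)
          v <- g / sum(g)
        }
        p[pos, ] <- v
      }
      prefs[[as.character(L)]] <- p
      anchors[[as.character(L)]] <- anc
    }
    # background raw scores from uniform random peptides
    bg <- list()
    for (L in lengths) {
      idx <- matrix(sample.int(20L, background_size * L, replace = TRUE),
                    nrow = background_size)
      lp <- log(prefs[[as.character(L)]] / (1 / 20))
      sc <- numeric(background_size)
      for (pos in seq_len(L)) sc <- sc + lp[pos, ][idx[, pos]]
      bg[[as.character(L)]] <- sort(sc)
    }
    structure(
      list(name = name, prefs = prefs, anchors = anchors,
           background = bg, seed = seed),
      class = "surrogate_allele"
    )
  })
}

surrogate_raw_score <- function(allele_obj, peptides) {
  L <- nchar(peptides[1])
  lp <- log(allele_obj$prefs[[as.character(L)]] / (1 / 20))
  idx <- do.call(rbind, pep_encode(peptides))
  sc <- numeric(length(peptides))
  for (pos in seq_len(L)) sc <- sc + lp[pos, ][idx[, pos]]
  sc
}

#' Surrogate rank predictor over a set of surrogate alleles
#'
#' @param alleles A list of [surrogate_allele()] objects.
#' @return An object of classes `surrogate_predictor`, `rank_predictor`.
#' @export
surrogate_predictor <- function(alleles) {
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  structure(list(alleles = alleles),
            class = c("surrogate_predictor", "rank_predictor"))
}

#' @export
predictor_alleles.surrogate_predictor <- function(predictor) {
  names(predictor$alleles)
}

#' @export
predict_rank.surrogate_predictor <- function(predictor, peptides, allele) {
  stopifnot(length(allele) == 1L)
  obj <- predictor$alleles[[allele]]
  if (is.null(obj)) stop("predict_rank: unknown allele: ", allele)
  check_peptide_lengths(peptides)
  out <- numeric(length(peptides))
  for (L in unique(nchar(peptides))) {
    sel <- nchar(peptides) == L
    sc <- surrogate_raw_score(obj, peptides[sel])
    bg <- obj$background[[as.character(L)]]
    # count of background scores >= query score, via binary search
    n_lt <- findInterval(sc, bg, left.open = TRUE)
    out[sel] <- 100 * (length(bg) - n_lt) / length(bg)
  }
  out
}

# ---------------------------------------------------------------------------
# Lookup-table predictor over pre-computed output

#' Rank predictor backed by a table of pre-computed ranks
#'
#' Wraps a `(peptide, allele, rank_el)` table, e.g. the result of
#' [parse_netmhcpan_output()], as a [predict_rank()] implementation.
#' Every (peptide, allele) query must be present in the table; for
#' ICORE extraction this means all 8-12-mer sub-windows of each input
#' peptide must have been scored.
#'
#' @param ranks A data frame with columns `peptide`, `allele`,
#'   `rank_el`.
#' @return An object of classes `table_predictor`, `rank_predictor`.
#' @export
table_predictor <- function(ranks) {
  stopifnot(all(c("peptide", "allele", "rank_el") %in% names(ranks)))
  key <- paste(ranks$peptide, ranks$allele, sep = "|")
  structure(list(ranks = setNames(ranks$rank_el, key),
                 alleles = unique(ranks$allele)),
            class = c("table_predictor", "rank_predictor"))
}

#' @export
predictor_alleles.table_predictor <- function(predictor) predictor$alleles

#' @export
predict_rank.table_predictor <- function(predictor, peptides, allele) {
  stopifnot(length(allele) == 1L)
  if (!allele %in% predictor$alleles) {
    stop("predict_rank: unknown allele: ", allele)
  }
  check_peptide_lengths(peptides)
  r <- predictor$ranks[paste(peptides, allele, sep = "|")]
  if (anyNA(r)) {
    miss <- peptides[is.na(r)]
    stop("predict_rank: no pre-computed rank for ",
         paste(head(miss, 3), collapse = ", "), " on ", allele)
  }
  unname(r)
}

# ---------------------------------------------------------------------------
# NetMHCpan-4.1 output parser

#' Parse NetMHCpan-4.1 textual output
#'
#' Reads the whitespace-aligned score table emitted by NetMHCpan-4.1 in
#' eluted-ligand mode (peptide-list or fasta input; possibly several
#' allele blocks per file) and returns one row per scored line. Header,
#' separator and summary lines are skipped; column positions are taken
#' from the header line so differing column spacing is tolerated.
#'
#' @param path Path to a NetMHCpan-4.1 output text file.
#' @return A data frame with columns `peptide`, `allele`, `rank_el`.
#' @export
parse_netmhcpan_output <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  # locate the most recent header to map column names to fields
  header_cols <- NULL
  rows <- list()
  for (ln in lines) {
    t <- trimws(ln)
    if (t == "" || startsWith(t, "#") || grepl("^-+$", t)) next
    fields <- strsplit(t, "\\s+")[[1]]
    if ("Peptide" %in% fields && any(grepl("%Rank", fields, fixed = TRUE))) {
      header_cols <- fields
      next
    }
    if (is.null(header_cols)) next
    if (!grepl("^[0-9]+$", fields[1])) next # summary/footer lines
    pep_i <- match("Peptide", header_cols)
    mhc_i <- match("MHC", header_cols)
    rank_i <- which(header_cols %in% c("%Rank_EL", "%Rank"))[1]
    if (is.na(pep_i) || is.na(mhc_i) || is.na(rank_i)) next
    # binder lines carry extra "<= SB" annotations and non-binder lines
    # may omit the trailing BindLevel column; only the left-anchored
    # fields up to the rank column are required
    if (length(fields) < max(pep_i, mhc_i, rank_i)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = fields[pep_i],
      allele = normalize_hla(fields[mhc_i]),
      rank_el = as.numeric(fields[rank_i]),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    stop("parse_netmhcpan_output: no scored lines found in ", path)
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Strong-binder sampling

# propose candidate peptides for rejection sampling; surrogate alleles
# propose from their own preference profile (high acceptance), anything
# else proposes uniform random peptides
propose_peptides <- function(predictor, allele, length, m) {
  obj <- if (inherits(predictor, "surrogate_predictor")) {
    predictor$alleles[[allele]]
  } else NULL
  aa <- aa_alphabet()
  if (!is.null(obj)) {
    p <- obj$prefs[[as.character(length)]]
    cols <- vapply(seq_len(length), function(pos) {
      sample(aa, m, replace = TRUE, prob = p[pos, ])
    }, character(m))
  } else {
    cols <- matrix(sample(aa, m * length, replace = TRUE), nrow = m)
  }
  apply(cols, 1, paste0, collapse = "")
}

#' Sample predicted strong binders for an allele
#'
#' Draws peptides of one length whose predicted percentile rank is at or
#' below `rank_threshold` (default 0.25, the strong-binder cut used to
#' build anchor profiles), by rejection sampling from a seeded peptide
#' stream. For surrogate alleles the proposal follows the allele's own
#' positional preferences, which keeps the acceptance rate high; for
#' other predictors the proposal is uniform.
#'
#' @inheritParams predict_rank
#' @param length Peptide length, 8-12.
#' @param n Number of binders to return.
#' @param rank_threshold Maximum percentile rank (default 0.25).
#' @param seed Integer seed for the peptide stream.
#' @param max_batches Bounded number of proposal batches before giving
#'   up with an error suggesting a looser threshold.
#' @return Character vector of `n` peptides, each re-scoring at or
#'   below the threshold.
#' @export
sample_strong_binders <- function(predictor, allele, length, n,
                                  rank_threshold = 0.25, seed = 42L,
                                  max_batches = 200L) {
  stopifnot(n >= 1L)
  with_seed(derive_seed(seed, paste0(allele, "_", length)), {
    kept <- character(0)
    batch <- max(1000L, 2L * n)
    for (i in seq_len(max_batches)) {
      cand <- propose_peptides(predictor, allele, length, batch)
      r <- predict_rank(predictor, cand, allele)
      kept <- c(kept, cand[r <= rank_threshold])
      if (length(kept) >= n) return(kept[seq_len(n)])
    }
    stop("sample_strong_binders: acceptance rate too low for ", allele,
         " at threshold ", rank_threshold,
         "; consider a looser rank_threshold")
  })
}
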