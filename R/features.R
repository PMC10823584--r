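# ---------------------------------------------------------------------------
# physico-chemical scales (vendored)

# Kyte-Doolittle hydropathy
kd_scale <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

# Boman residue contributions: negated water->cyclohexane transfer free
# energies (kcal/mol); proline, unmeasured, is set to 0 as in common
# implementations
boman_scale <- function() {
  c(A = -1.81, C = -1.28, D = 8.72, E = 6.81, F = -2.98, G = -0.94,
    H = 4.66, I = -4.92, K = 5.55, L = -4.92, M = -2.35, N = 6.64,
    P = 0, Q = 5.54, R = 14.92, S = 3.40, T = 2.57, V = -4.04,
    W = -2.33, Y = 0.14)
}

# EMBOSS pKa set for net-charge / isoelectric point
emboss_pka <- function() {
  list(nterm = 8.6, cterm = 3.6,
       positive = c(K = 10.8, R = 12.5, H = 6.5),
       negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))
}

peptide_net_charge <- function(counts, ph) {
  pka <- emboss_pka()
  pos <- 1 / (1 + 10^(ph - pka$nterm)) +
    sum(counts[names(pka$positive)] / (1 + 10^(ph - pka$positive)))
  neg <- 1 / (1 + 10^(pka$cterm - ph)) +
    sum(counts[names(pka$negative)] / (1 + 10^(pka$negative - ph)))
  pos - neg
}

#' Physico-chemical descriptors of a peptide
#'
#' Four descriptors used as optional model features:
#' * aliphatic index (Ikai): `100 * (xA + 2.9 xV + 3.9 (xI + xL))` on
#'   mole fractions — the relative volume occupied by aliphatic side
#'   chains;
#' * hydrophobicity: mean Kyte-Doolittle hydropathy (GRAVY);
#' * isoelectric point: pH of zero net charge, found by bisection on
#'   the Henderson-Hasselbalch net charge with the EMBOSS pKa set
#'   (free termini included);
#' * Boman index: mean negated water-to-cyclohexane transfer free
#'   energy, higher for peptides prone to protein-protein interaction.
#'
#' @param seq Character vector of peptides (canonical alphabet).
#' @return A data frame with columns `aliphatic_index`,
#'   `hydrophobicity`, `isoelectric_point`, `boman_index`.
#' @export
physchem <- function(seq) {
  stopifnot(all(is_canonical_peptide(seq)))
  kd <- kd_scale()
  bo <- boman_scale()
  out <- data.frame(aliphatic_index = numeric(length(seq)),
                    hydrophobicity = numeric(length(seq)),
                    isoelectric_point = numeric(length(seq)),
                    boman_index = numeric(length(seq)))
  for (i in seq_along(seq)) {
    ch <- aa_split(seq[i])
    counts <- table(factor(ch, levels = aa_alphabet()))
    x <- counts / length(ch)
    out$aliphatic_index[i] <-
      100 * (x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
    out$hydrophobicity[i] <- mean(kd[ch])
    out$boman_index[i] <- mean(bo[ch])
    out$isoelectric_point[i] <- uniroot(
      function(ph) peptide_net_charge(counts, ph),
      interval = c(0, 14), tol = 1e-6)$root
  }
  out
}

# ---------------------------------------------------------------------------
# composition and mutation features

#' Weighted amino-acid composition of a peptide
#'
#' Encodes a peptide positionally (one-hot or BLOSUM62 rows), applies a
#' per-position weight vector, and averages:
#' `result = sum_p w_p * enc(seq_p) / sum_p w_p`. Under one-hot
#' encoding the result is a probability vector over the 20 residues;
#' under BLOSUM62 encoding it is the weighted mean substitution
#' profile. An all-zero weight vector (a fully masked peptide) falls
#' back to uniform weights with a warning, so every record still yields
#' a defined composition.
#'
#' @param seq A single peptide.
#' @param weights Numeric vector, one non-negative weight per position.
#' @param encoding `"onehot"` (default) or `"blosum62"`.
#' @return Named numeric vector of length 20 in [aa_alphabet()] order.
#' @export
weighted_composition <- function(seq, weights,
                                 encoding = c("onehot", "blosum62")) {
  encoding <- match.arg(encoding)
  idx <- pep_encode(seq)[[1]]
  if (anyNA(idx)) stop("weighted_composition: non-canonical residue in ", seq)
  if (length(weights) != length(idx)) {
    stop("weighted_composition: weights length must equal peptide length")
  }
  if (all(weights == 0)) {
    warning("weighted_composition: all-zero weight vector; ",
            "falling back to uniform weights")
    weights <- rep(1, length(idx))
  }
  w <- weights / sum(weights)
  out <- setNames(numeric(20), aa_alphabet())
  if (encoding == "onehot") {
    for (p in seq_along(idx)) out[idx[p]] <- out[idx[p]] + w[p]
  } else {
    b <- blosum62()
    for (p in seq_along(idx)) out <- out + w[p] * b[idx[p], ]
  }
  out
}

#' Scaled rank-based agretopicity
#'
#' `scaled = |rank_mut - rank_wt| * rank_mut / rank_wt`. The plain
#' mutant/wild-type rank ratio treats a (0.1, 1) pair — a strong binder
#' gained by mutation — the same as a (10, 100) pair of two
#' non-binders; the absolute-difference scaling separates them while
#' keeping the score low for immunogenic-like peptides. The unscaled
#' ratio is returned alongside for comparison work.
#'
#' @param rank_mut,rank_wt Numeric vectors of percentile ranks (> 0).
#' @param floor Ranks of 0 (possible with empirical percentile tables)
#'   are clamped to this floor with a warning (default 1e-3).
#' @return A data frame with columns `scaled` and `ratio`.
#' @export
#' @examples
#' scaled_agretopicity(c(0.1, 10), c(1, 100))
scaled_agretopicity <- function(rank_mut, rank_wt, floor = 1e-3) {
  stopifnot(length(rank_mut) == length(rank_wt))
  if (any(rank_mut < 0) || any(rank_wt < 0)) {
    stop("scaled_agretopicity: ranks must be non-negative")
  }
  if (any(rank_wt == 0) || any(rank_mut == 0)) {
    warning("scaled_agretopicity: zero rank clamped to floor ", floor)
    rank_wt <- pmax(rank_wt, floor)
    rank_mut <- pmax(rank_mut, floor)
  }
  ratio <- rank_mut / rank_wt
  data.frame(scaled = abs(rank_mut - rank_wt) * ratio, ratio = ratio)
}

#' BLOSUM and codon mutation scores of an aligned pair
#'
#' Sums, over the mismatch positions of two aligned equal-length
#' sequences (typically the mutant ICORE and its aligned wild-type
#' ICORE), the BLOSUM62 log-odds of the wild-type to mutant
#' substitution, and the codon single-nucleotide mutation probability
#' from [codon_mutation_matrix()]. Identical sequences score (0, 0).
#'
#' @param mut,wt Character vectors of aligned sequences (element-wise
#'   pairs, equal lengths).
#' @return A data frame with columns `blosum_score`, `codon_score`.
#' @export
mutation_scores <- function(mut, wt) {
  stopifnot(length(mut) == length(wt))
  if (any(nchar(mut) != nchar(wt))) {
    stop("mutation_scores: aligned sequences must have equal length")
  }
  b <- blosum62()
  cm <- codon_mutation_matrix()
  out <- data.frame(blosum_score = numeric(length(mut)),
                    codon_score = numeric(length(mut)))
  for (i in seq_along(mut)) {
    a <- aa_split(mut[i])
    w <- aa_split(wt[i])
    mism <- which(a != w)
    if (length(mism)) {
      out$blosum_score[i] <- sum(b[cbind(w[mism], a[mism])])
      out$codon_score[i] <- sum(cm[cbind(w[mism], a[mism])])
    }
  }
  out
}

# ---------------------------------------------------------------------------
# feature assembly

# fixed order of the optional features appended after the 21-dim base
# block; serialised with every trained model
optional_feature_order <- function() {
  c("rank_wt", "scaled_agretopicity", "blosum_mutation_score",
    "codon_mutation_score", "self_similarity", "aliphatic_index",
    "hydrophobicity", "isoelectric_point", "boman_index",
    "expression_tpm", "foreignness")
}

#' Feature configuration
#'
#' Bundles the choices that define a model's input: positional
#' weighting scheme, sequence encoding, the optional features appended
#' to the 21-dimensional base block (20 composition values + mutant
#' ICORE \%Rank), and imputation settings. The default configuration is
#' the consensus model's: anchor masking, one-hot encoding, BLOSUM
#' mutation score and antigen expression as extra features.
#'
#' @param scheme Positional weighting scheme (see [make_weights()]).
#' @param encoding `"onehot"` or `"blosum62"`.
#' @param features Character vector of optional features, any of
#'   `rank_wt`, `scaled_agretopicity`, `blosum_mutation_score`,
#'   `codon_mutation_score`, `self_similarity`, `aliphatic_index`,
#'   `hydrophobicity`, `isoelectric_point`, `boman_index`,
#'   `expression_tpm`, `foreignness`; the shorthand `"physchem"`
#'   expands to the four physico-chemical descriptors.
#' @param source `"icore"` (default) or `"full"` — the sequence the
#'   composition and physico-chemical features are computed from.
#' @param anchor_threshold IC threshold for masking schemes.
#' @param rank_floor Clamp for zero wild-type ranks in agretopicity.
#' @param tpm_median Median TPM used to impute missing expression
#'   values (set at training time from the calibration background).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(scheme = "NormalMask",
                           encoding = c("onehot", "blosum62"),
                           features = c("blosum_mutation_score",
                                        "expression_tpm"),
                           source = c("icore", "full"),
                           anchor_threshold = 0.2, rank_floor = 1e-3,
                           tpm_median = NULL) {
  encoding <- match.arg(encoding)
  source <- match.arg(source)
  if ("physchem" %in% features) {
    features <- union(setdiff(features, "physchem"),
                      c("aliphatic_index", "hydrophobicity",
                        "isoelectric_point", "boman_index"))
  }
  bad <- setdiff(features, optional_feature_order())
  if (length(bad)) stop("feature_config: unknown features: ",
                        paste(bad, collapse = ", "))
  structure(
    list(scheme = scheme, encoding = encoding,
         features = intersect(optional_feature_order(), features),
         source = source, anchor_threshold = anchor_threshold,
         rank_floor = rank_floor, tpm_median = tpm_median),
    class = "feature_config"
  )
}

#' Feature schema of a configuration
#'
#' @param config A [feature_config()].
#' @return Character vector naming every feature column in order:
#'   `comp_A` .. `comp_Y`, `rank_mut`, then the selected optional
#'   features.
#' @export
feature_schema <- function(config) {
  c(paste0("comp_", aa_alphabet()), "rank_mut", config$features)
}

#' Assemble the model feature matrix
#'
#' Computes, for every record carrying ICORE columns (see
#' [extract_icores()]), the weighted amino-acid composition of the
#' source sequence, appends the mutant ICORE \%Rank, and then the
#' optional features selected in the configuration. Missing expression
#' values are imputed with the configured median TPM (or the in-sample
#' median when none is configured and at least one value is present).
#'
#' @param records Data frame with ICORE columns, plus `expression_tpm`
#'   / `foreignness` when those features are requested.
#' @param profiles Anchor profiles from [build_anchor_profiles()],
#'   covering every (allele, ICORE length) present.
#' @param config A [feature_config()].
#' @return Numeric matrix, one row per record, with an attribute
#'   `schema` equal to [feature_schema()] of the configuration.
#' @export
assemble_features <- function(records, profiles, config = feature_config()) {
  n <- nrow(records)
  seqs <- if (config$source == "icore") records$icore_mut
          else records$mutant_peptide
  comp <- matrix(0, nrow = n, ncol = 20,
                 dimnames = list(NULL, paste0("comp_", aa_alphabet())))
  for (i in seq_len(n)) {
    key <- profile_key(records$allele[i], nchar(seqs[i]))
    prof <- profiles[[key]]
    if (is.null(prof)) {
      stop("assemble_features: no anchor profile for ", key)
    }
    w <- make_weights(prof, config$scheme, config$anchor_threshold)
    comp[i, ] <- weighted_composition(seqs[i], w, config$encoding)
  }
  X <- cbind(comp, rank_mut = records$rank_mut)
  feats <- config$features
  if ("rank_wt" %in% feats) X <- cbind(X, rank_wt = records$rank_wt)
  if ("scaled_agretopicity" %in% feats) {
    X <- cbind(X, scaled_agretopicity = scaled_agretopicity(
      records$rank_mut, records$rank_wt, config$rank_floor)$scaled)
  }
  if (any(c("blosum_mutation_score", "codon_mutation_score") %in% feats)) {
    ms <- mutation_scores(records$icore_mut, records$icore_wt)
    if ("blosum_mutation_score" %in% feats) {
      X <- cbind(X, blosum_mutation_score = ms$blosum_score)
    }
    if ("codon_mutation_score" %in% feats) {
      X <- cbind(X, codon_mutation_score = ms$codon_score)
    }
  }
  if ("self_similarity" %in% feats) {
    X <- cbind(X, self_similarity = kernel_similarity(records$icore_mut,
                                                      records$icore_wt))
  }
  pc_feats <- intersect(c("aliphatic_index", "hydrophobicity",
                          "isoelectric_point", "boman_index"), feats)
  if (length(pc_feats)) {
    pc <- physchem(seqs)
    for (f in pc_feats) X <- cbind(X, setNames(list(pc[[f]]), f)[[1]])
    colnames(X)[(ncol(X) - length(pc_feats) + 1L):ncol(X)] <- pc_feats
  }
  if ("expression_tpm" %in% feats) {
    tpm <- records$expression_tpm
    if (is.null(tpm)) tpm <- rep(NA_real_, n)
    if (anyNA(tpm)) {
      med <- config$tpm_median %||%
        (if (all(is.na(tpm))) NULL else median(tpm, na.rm = TRUE))
      if (is.null(med)) {
        stop("assemble_features: expression feature requested but no TPM ",
             "values and no imputation median configured")
      }
      tpm[is.na(tpm)] <- med
    }
    X <- cbind(X, expression_tpm = tpm)
  }
  if ("foreignness" %in% feats) {
    if (is.null(records$foreignness) || anyNA(records$foreignness)) {
      stop("assemble_features: foreignness feature requested but column ",
           "missing or incomplete (it is a precomputed pass-through input)")
    }
    X <- cbind(X, foreignness = records$foreignness)
  }
  schema <- feature_schema(config)
  X <- X[, schema, drop = FALSE]
  attr(X, "schema") <- schema
  X
}
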