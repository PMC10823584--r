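#' Position-specific frequency profile from strong binders
#'
#' Builds per-position residue frequencies from a set of equal-length
#' predicted strong binders, with a low-count (pseudo-count) correction
#' blending observed frequencies with a background distribution:
#' `freq[p, a] = (n * f_obs[p, a] + beta * q[a]) / (n + beta)`,
#' where `n` is the binder count and `beta` the correction weight
#' (default 20). No sequence weighting is applied. With `beta > 0` all
#' frequencies are strictly positive, so Kullback-Leibler terms are
#' always defined.
#'
#' @param binders Character vector of equal-length peptides.
#' @param beta Low-count correction weight (default 20).
#' @param background Background residue distribution `q` (default
#'   uniform 1/20), a length-20 numeric vector in [aa_alphabet()]
#'   order.
#' @return A `length x 20` matrix of frequencies; rows sum to 1.
#' @export
build_frequency_profile <- function(binders, beta = 20,
                                    background = rep(1 / 20, 20)) {
  if (length(binders) == 0L) {
    stop("build_frequency_profile: empty binder set")
  }
  stopifnot(beta >= 0, length(background) == 20L,
            abs(sum(background) - 1) < 1e-9)
  L <- nchar(binders[1])
  if (!all(nchar(binders) == L)) {
    stop("build_frequency_profile: binders must all have the same length")
  }
  idx <- do.call(rbind, pep_encode(binders))
  n <- length(binders)
  freq <- matrix(0, nrow = L, ncol = 20,
                 dimnames = list(NULL, aa_alphabet()))
  for (pos in seq_len(L)) {
    counts <- tabulate(idx[, pos], nbins = 20L)
    freq[pos, ] <- (counts + beta * background) / (n + beta)
  }
  freq
}

#' Per-position information content of a frequency profile
#'
#' Computes the position-specific information content of a profile,
#' normalised to \[0, 1\] by dividing by `log2(20)` (the maximum
#' attainable against a uniform background), so that the anchor
#' threshold of 0.2 and the `(1 - IC)` weighting are well defined.
#'
#' `kind = "KL"` uses the Kullback-Leibler divergence from the
#' background: `ic_raw[p] = sum_a freq[p,a] * log2(freq[p,a] / q[a])`.
#' `kind = "Shannon"` uses `log2(20) - H(freq[p, ])`. The two coincide
#' for a uniform background. Values are clamped at 0 from below (KL
#' against a non-uniform background can otherwise dip negative after
#' normalisation rounding).
#'
#' @param freq A `length x 20` frequency matrix
#'   (see [build_frequency_profile()]).
#' @param kind `"KL"` (default) or `"Shannon"`.
#' @param background Background distribution used by the KL form.
#' @return Numeric vector of per-position IC values in \[0, 1\].
#' @export
information_content <- function(freq, kind = c("KL", "Shannon"),
                                background = rep(1 / 20, 20)) {
  kind <- match.arg(kind)
  f <- pmax(freq, .Machine$double.xmin)
  ic_raw <- if (kind == "KL") {
    rowSums(f * log2(sweep(f, 2, background, "/")))
  } else {
    log2(20) + rowSums(f * log2(f))
  }
  pmin(pmax(ic_raw / log2(20), 0), 1)
}

#' Anchor profile for one (allele, length)
#'
#' Convenience constructor running [sample_strong_binders()],
#' [build_frequency_profile()] and [information_content()] end to end.
#'
#' @inheritParams sample_strong_binders
#' @param n_binders Number of strong binders to sample (default 1000).
#' @param beta Low-count correction weight (default 20).
#' @param kind IC flavour, `"KL"` (default) or `"Shannon"`.
#' @return An object of class `anchor_profile` with fields `allele`,
#'   `length`, `freq`, `ic`, `n_binders`, `beta`.
#' @export
build_anchor_profile <- function(predictor, allele, length,
                                 n_binders = 1000L, beta = 20,
                                 rank_threshold = 0.25, kind = "KL",
                                 seed = 42L) {
  binders <- sample_strong_binders(predictor, allele, length, n_binders,
                                   rank_threshold = rank_threshold,
                                   seed = seed)
  freq <- build_frequency_profile(binders, beta = beta)
  structure(
    list(allele = allele, length = length, freq = freq,
         ic = information_content(freq, kind = kind),
         n_binders = n_binders, beta = beta, kind = kind),
    class = "anchor_profile"
  )
}

#' Anchor profiles for all (allele, length) combinations
#'
#' @inheritParams build_anchor_profile
#' @param alleles Character vector of allele names.
#' @param lengths Peptide lengths to cover (default 8:12).
#' @return A named list of `anchor_profile` objects keyed
#'   `"<allele>|<length>"`.
#' @export
build_anchor_profiles <- function(predictor, alleles = NULL,
                                  lengths = 8:12, n_binders = 1000L,
                                  beta = 20, rank_threshold = 0.25,
                                  kind = "KL", seed = 42L) {
  alleles <- alleles %||% predictor_alleles(predictor)
  out <- list()
  for (al in alleles) {
    for (L in lengths) {
      out[[profile_key(al, L)]] <- build_anchor_profile(
        predictor, al, L, n_binders = n_binders, beta = beta,
        rank_threshold = rank_threshold, kind = kind, seed = seed)
    }
  }
  out
}

profile_key <- function(allele, length) paste(allele, length, sep = "|")

#' Positional weight vector for a weighting scheme
#'
#' Turns a profile's information content into per-position weights for
#' composition encoding. `None` applies no weighting (all 1);
#' `Normal` uses `(1 - IC)`, down-weighting anchors; `NormalMask`
#' additionally zeroes positions with `IC >= threshold` (masks
#' anchors); `Inverted` uses the IC itself, up-weighting anchors;
#' `InvertedMask` zeroes the non-anchor positions with
#' `IC < threshold`.
#'
#' @param profile An `anchor_profile`, or a bare numeric IC vector.
#' @param scheme One of `"None"`, `"Normal"`, `"NormalMask"`,
#'   `"Inverted"`, `"InvertedMask"`.
#' @param anchor_threshold IC threshold defining anchors (default 0.2,
#'   on the normalised \[0, 1\] scale).
#' @return Numeric weight vector, one entry per position.
#' @export
make_weights <- function(profile, scheme = c("None", "Normal", "NormalMask",
                                             "Inverted", "InvertedMask"),
                         anchor_threshold = 0.2) {
  scheme <- match.arg(scheme)
  stopifnot(anchor_threshold > 0, anchor_threshold < 1)
  ic <- if (inherits(profile, "anchor_profile")) profile$ic else profile
  switch(scheme,
    None = rep(1, length(ic)),
    Normal = 1 - ic,
    NormalMask = ifelse(ic >= anchor_threshold, 0, 1 - ic),
    Inverted = ic,
    InvertedMask = ifelse(ic < anchor_threshold, 0, ic)
  )
}

#' Anchor positions of a profile
#'
#' @inheritParams make_weights
#' @param threshold IC threshold (default 0.2).
#' @return Integer vector of 1-based anchor positions (IC at or above
#'   the threshold).
#' @export
anchor_positions <- function(profile, threshold = 0.2) {
  ic <- if (inherits(profile, "anchor_profile")) profile$ic else profile
  which(ic >= threshold)
}

#' Serialise anchor profiles to a file
#'
#' Profiles are written as JSON (allele, length, frequency rows, IC
#' vector, parameters) so they can be reused across runs and inspected
#' as plain text.
#'
#' @param profiles Named list from [build_anchor_profiles()].
#' @param path Output file path.
#' @export
write_anchor_profiles <- function(profiles, path) {
  payload <- lapply(profiles, function(p) {
    list(allele = p$allele, length = p$length,
         freq = unname(apply(p$freq, 1, as.list)),
         ic = p$ic, n_binders = p$n_binders, beta = p$beta, kind = p$kind)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_anchor_profiles
#' @export
read_anchor_profiles <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(payload, function(p) {
    freq <- do.call(rbind, lapply(p$freq, function(r) unlist(r)))
    colnames(freq) <- aa_alphabet()
    structure(
      list(allele = p$allele, length = as.integer(p$length), freq = freq,
           ic = unlist(p$ic), n_binders = as.integer(p$n_binders),
           beta = p$beta, kind = p$kind),
      class = "anchor_profile"
    )
  })
  names(out) <- names(payload)
  out
}
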