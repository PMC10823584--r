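check_two_classes <- function(labels) {
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop("both classes must be present")
  }
}

#' ROC AUC
#'
#' The probability that a uniformly chosen positive outranks a
#' uniformly chosen negative, with ties counting one half — computed
#' from the Wilcoxon rank-sum identity.
#'
#' @param labels Binary labels (0/1).
#' @param scores Numeric scores, higher = more positive-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_two_classes(labels)
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Partial AUC up to false-positive rate 0.1
#'
#' Integrates the ROC curve from false-positive rate 0 to
#' `fpr_max` (default 0.1), with linear interpolation at the cut-off;
#' tied scores produce the usual diagonal ROC segments. When
#' `normalised`, the integral is divided by `fpr_max` so a perfect
#' ranker scores 1.
#'
#' @inheritParams roc_auc
#' @param normalised Divide by `fpr_max` (default `TRUE`).
#' @param fpr_max Upper integration limit on the FPR axis.
#' @return Partial AUC (in \[0, 1\] when normalised).
#' @export
pauc01 <- function(labels, scores, normalised = TRUE, fpr_max = 0.1) {
  stopifnot(length(labels) == length(scores))
  check_two_classes(labels)
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t) sum(scores[pos] == t),
                            numeric(1))) / n1)
  fpr <- c(0, cumsum(vapply(thr, function(t) sum(scores[!pos] == t),
                            numeric(1))) / n0)
  # clip the curve at fpr_max with linear interpolation
  area <- 0
  for (j in seq_len(length(thr))) {
    x0 <- fpr[j]; x1 <- fpr[j + 1]
    y0 <- tpr[j]; y1 <- tpr[j + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  if (normalised) area / fpr_max else area
}

#' Paired bootstrap comparison of two score vectors
#'
#' Resamples record indices with replacement for `n_rounds` rounds —
#' the same indices for both methods, so rounds are paired — and
#' counts the rounds where method C1's AUC strictly exceeds method
#' C2's. The reported p-value is `1 - wins / n_rounds`: small values
#' mean C1 reliably outperforms C2. Rounds that resample a single
#' class are redrawn (bounded retries).
#'
#' @param labels Binary labels (0/1).
#' @param scores_c1,scores_c2 Score vectors of the two methods.
#' @param n_rounds Bootstrap rounds (default 10000).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_comparison` with `p_value`,
#'   `wins`, `n_rounds`, `auc_c1`, `auc_c2` (per-round AUC vectors)
#'   and the full-data AUCs.
#' @export
bootstrap_compare <- function(labels, scores_c1, scores_c2,
                              n_rounds = 10000L, seed = 1L) {
  stopifnot(length(labels) == length(scores_c1),
            length(labels) == length(scores_c2))
  check_two_classes(labels)
  n <- length(labels)
  with_seed(derive_seed(seed, "bootstrap"), {
    auc1 <- numeric(n_rounds)
    auc2 <- numeric(n_rounds)
    for (r in seq_len(n_rounds)) {
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        if (try == 100) stop("bootstrap_compare: could not resample ",
                             "both classes in 100 tries")
      }
      auc1[r] <- roc_auc(labels[idx], scores_c1[idx])
      auc2[r] <- roc_auc(labels[idx], scores_c2[idx])
    }
    wins <- sum(auc1 > auc2)
    structure(
      list(p_value = 1 - wins / n_rounds, wins = wins,
           n_rounds = n_rounds, auc_c1 = auc1, auc_c2 = auc2,
           full_auc_c1 = roc_auc(labels, scores_c1),
           full_auc_c2 = roc_auc(labels, scores_c2), seed = seed),
      class = "bootstrap_comparison"
    )
  })
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("Paired bootstrap (%d rounds): AUC_c1 = %.4f, AUC_c2 = %.4f\n",
              x$n_rounds, x$full_auc_c1, x$full_auc_c2))
  cat(sprintf("C1 wins %d/%d rounds; p = %.4g\n", x$wins, x$n_rounds,
              x$p_value))
  invisible(x)
}

#' One-sided pooled two-proportion z-test
#'
#' Classical pooled-variance z statistic for comparing two binomial
#' proportions, with a one-sided normal tail. Used, e.g., to test
#' whether peptides whose mutation falls outside the ICORE are
#' depleted in immunogenic entries.
#'
#' @param successes1,n1 Successes and trials in group 1.
#' @param successes2,n2 Successes and trials in group 2.
#' @param alternative `"less"`: proportion 1 < proportion 2 (default);
#'   `"greater"`: proportion 1 > proportion 2.
#' @return One-sided p-value.
#' @export
#' @examples
#' proportions_ztest(11, 116, 620, 2917, "less")
proportions_ztest <- function(successes1, n1, successes2, n2,
                              alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, successes1 >= 0, successes2 >= 0,
            successes1 <= n1, successes2 <= n2)
  p1 <- successes1 / n1
  p2 <- successes2 / n2
  pool <- (successes1 + successes2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  if (alternative == "less") pnorm(z) else pnorm(z, lower.tail = FALSE)
}

#' One-sided Welch t-test (mean of a greater than mean of b)
#'
#' Thin wrapper over [stats::t.test()] with Welch's unequal-variance
#' statistic and the upper-tail alternative. Degenerate zero-variance
#' input falls back to 0.5 (equal means) or 0/1 by the sign of the
#' difference.
#'
#' @param sample_a,sample_b Numeric samples (each n >= 2).
#' @return One-sided p-value for `mean(sample_a) > mean(sample_b)`.
#' @export
welch_ttest_onesided <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    d <- mean(sample_a) - mean(sample_b)
    return(if (d == 0) 0.5 else if (d > 0) 0 else 1)
  }
  stats::t.test(sample_a, sample_b, alternative = "greater",
                var.equal = FALSE)$p.value
}

#' Harmonic-mean consensus model ranking
#'
#' Ranks model candidates by the harmonic mean `2ab / (a + b)` of
#' their cross-validation AUC on the primary dataset and their test
#' AUC on an external dataset — the selection rule behind the
#' consensus model. Ties keep input order (stable sort).
#'
#' @param candidates Data frame with columns `auc_primary`,
#'   `auc_external` (both in (0, 1\]) and any identifying columns.
#' @return `candidates` with an appended `harmonic_mean` column,
#'   sorted in decreasing consensus order.
#' @export
select_consensus <- function(candidates) {
  a <- candidates$auc_primary
  b <- candidates$auc_external
  if (any(a <= 0) || any(b <= 0)) {
    stop("select_consensus: AUC values must be positive")
  }
  candidates$harmonic_mean <- 2 * a * b / (a + b)
  candidates[order(-candidates$harmonic_mean), , drop = FALSE]
}
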