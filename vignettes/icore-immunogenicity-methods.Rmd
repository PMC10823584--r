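---
title: "Methods: ICORE-based random-forest prediction of neo-epitope immunogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICORE-based random-forest prediction of neo-epitope immunogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

A cancer somatic point mutation can create a neo-epitope: a short
peptide (8–12 residues) that, if presented on an HLA class I molecule,
may be recognised by CD8+ T cells. Given a mutant peptide, its aligned
wild-type (WT) counterpart and an HLA restriction, `icoreRF` predicts
the probability that the mutant is immunogenic, and positions that
probability on a 0–100 percentile scale against a background of
randomly mutated proteome peptides (0 = most immunogenic-like).

The pipeline has five stages:

1. **ICORE extraction.** The reported peptide is not necessarily the
   presented one: antigen processing can trim it. Every contiguous
   sub-window of length 8 to 12 is scored with an MHC presentation
   rank predictor, and the window with the best (lowest) percentile
   rank — the ICORE — becomes the modelling unit. The WT ICORE is the
   substring of the WT peptide at the same offset and length.
2. **Anchor profiles and positional weights.** For each (allele,
   length), position-specific residue frequencies are estimated from
   predicted strong binders (rank ≤ 0.25), with a pseudo-count
   blending `(n·f_obs + β·q)/(n + β)`, β = 20, against a uniform
   background `q = 1/20`. Per-position Kullback–Leibler information
   content (IC), normalised by `log2(20)` to land in [0, 1], localises
   the MHC anchor positions (IC ≥ 0.2). Five weighting schemes turn IC
   into per-position weights: `None` (all 1), `Normal` (1 − IC),
   `NormalMask` (1 − IC, anchors zeroed), `Inverted` (IC),
   `InvertedMask` (IC, non-anchors zeroed).
3. **Features.** The base input is 21-dimensional: the weighted
   amino-acid composition of the mutant ICORE (20 values) plus its
   percentile rank. Optional features extend it: the WT ICORE rank;
   scaled rank-agretopicity `|R_mut − R_wt| · R_mut/R_wt`; BLOSUM62
   and codon single-nucleotide mutation scores summed over mutated
   positions; BLOSUM62 k-mer kernel self-similarity between the two
   ICOREs; four physico-chemical descriptors (Ikai aliphatic index,
   Kyte–Doolittle hydrophobicity, isoelectric point, Boman index);
   antigen expression (TPM); and a precomputed foreignness score. The
   default configuration — anchor masking, one-hot composition, BLOSUM
   mutation score and expression — is the consensus setting that
   generalised best across datasets.
4. **Leakage-free cross-validation.** Peptide datasets are full of
   near-duplicates; random folds leak. A Hobohm-1 scan under the
   BLOSUM62 k-mer kernel (windows 3–8, threshold 0.9) sets redundant
   peptides aside, the dissimilar representatives are dealt
   round-robin into 10 folds, and each held-out peptide is reinserted
   into the fold of its maximum-similarity representative.
5. **Ensemble and calibration.** A nested 10-fold scheme fits one
   random forest per ordered fold pair (o, i), each trained on the
   remaining k − 2 folds — 90 members. The out-of-fold score of a
   record in fold o averages the k − 1 members that never saw fold o;
   external predictions average all members. Scores are calibrated to
   percentile ranks against a mutated synthetic proteome background.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| strong-binder rank cut | 0.25 (%Rank) | binders used for anchor profiles |
| pseudo-count β | 20 | low-count correction weight |
| anchor IC threshold | 0.2 (normalised IC) | defines anchors / masking |
| kernel β | 0.11387 | BLOSUM62 exponent of the k-mer kernel |
| kernel windows | 3–8 | k-mer lengths summed by the kernel |
| similarity threshold | 0.9 | Hobohm-1 / partition leakage bound |
| ICORE mismatch cap | 3 | record filter on ICORE Hamming distance |
| folds k | 10 | nested CV; ensemble size k(k−1) = 90 |
| trees / depth / leaf | 300 / 8 / 7 | forest capacity per member |

`rf_hyperparams()` also records a cost-complexity `pruning_alpha`
(1e-5) describing the reference configuration. The ranger backend
grows depth- and leaf-constrained trees and offers no post-hoc
cost-complexity pruning; at 1e-5 the pruning is negligible relative to
the depth-8/7-per-leaf constraints, so the value is carried as
metadata rather than applied.

## Design choices where the design was open

* **IC scale.** The 0.2 anchor threshold is applied to IC normalised
  by `log2(20)`, not raw bits: the `(1 − IC)` weighting is only well
  defined for IC ∈ [0, 1], and a threshold on the same scale keeps
  one constant meaningful for both. The KL background is uniform
  (1/20); a proteome-frequency background is configurable.
* **Pseudo-counts.** The low-count correction is the simple blending
  formula above rather than a substitution-matrix (Henikoff-style)
  pseudo-count; it is the documented, testable default, and with
  β = 20 every frequency is strictly positive so KL terms are always
  defined.
* **Tie-breaking in ICORE extraction** (equal ranks) prefers the
  longer window, then the smaller offset, so extraction is
  reproducible; coordinates are 0-based internally and 1-based in
  user-facing output.
* **Codon mutation score** averages uniformly over the WT residue's
  synonymous codons and the 9 single-nucleotide neighbours of each;
  stop-codon neighbours count as non-matching; no codon-usage
  weighting is applied (none is defensible without naming a usage
  table).
* **Hobohm-1 scan order** is input order (no pre-sort): reproducible
  from the raw file. A peptide joins the *maximum-similarity*
  representative among those above the threshold.
* **Nested-CV member role.** Members are trained on k − 2 folds and
  pooled; the inner fold is a held-out validation slice for
  diagnostics, not a selection criterion — the pooled mean of all 90
  members is the ensemble prediction.
* **Bootstrap comparison.** Rounds are paired (identical resampled
  indices for both methods). The p-value is `1 − wins/n_rounds`, the
  reading under which a small p means the first method reliably wins;
  rounds that resample a single class are redrawn.
* **Partial AUC** integrates the ROC to FPR = 0.1 and normalises by
  simple division by 0.1.
* **Agretopicity floor.** A WT rank of exactly 0 (possible with
  empirical percentile tables) is clamped to 1e-3 with a warning
  rather than producing an infinite ratio.
* **Degenerate compositions.** A fully masked ICORE (all-zero weight
  vector) falls back to uniform weights with a warning, so every
  record keeps a defined composition.

## The surrogate predictor and what the synthetic data emulate

The pipeline is predictor-agnostic: any object implementing
`predict_rank(predictor, peptides, allele)` works, including a lookup
table over pre-computed NetMHCpan-4.1 output files
(`table_predictor(parse_netmhcpan_output(path))`). For self-contained
runs the package ships a deterministic surrogate: each surrogate
allele holds per-length positional preference tables with
concentrated preferences at anchor positions (position 2 and the
C-terminus, sometimes a third), scores a peptide as the sum of
per-position log-preferences, and converts the score to a percentile
against 10,000 seeded random peptides — mirroring eluted-ligand %Rank
semantics (lower = stronger).

The synthetic generator emulates the *structure* of curated
neo-epitope training data: lengths 8–12 centred on 9–10-mers; mutants
produced by 1–3 point substitutions (85/10/5%), stressing the ≤ 3
ICORE-mismatch filter from both sides; skewed allele usage with one
allele at ~40% of records; log-normal expression; ~21% positives; and
a configurable rate of near-duplicates to exercise the redundancy
scan. Labels are drawn from a logistic model on *pipeline-computed*
features (mutant ICORE rank, BLOSUM mutation score, log TPM), so that
recovering the signal exercises ICORE extraction and feature code,
not just the forest. The intercept is solved numerically so the
expected positive rate matches the 21% target.

What the synthetic data do **not** emulate: real HLA binding motifs,
real codon/residue usage, realistic TCGA expression beyond log-normal
shape, assay heterogeneity behind labels, or inter-dataset biases.
Passing the recovery tests therefore demonstrates that the machinery
is correct and leak-free — not that the reported cross-validation
performance on curated datasets (AUC ≈ 0.74 at best there) transfers.

### Calibrating the "strong signal" recovery condition

`signal_spec_strong()` exists because parameter-recovery tests need a
signal a correct model must find. Under the logistic label model the
best possible ranker is the generating score η itself, and its AUC is
fixed by `sd(η)`: ~0.86 at sd 2.2, ~0.92 at sd 3.9. The strong preset
uses weights (3.1, 1.8, 1.5), i.e. sd(η) ≈ 3.9 and a Bayes AUC near
0.92, leaving headroom for finite-sample loss so an out-of-fold AUC
of at least 0.85 is a fair bar at n = 2000. The default
`signal_spec()` keeps a more realistic moderate signal for
structure-level tests.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full pipeline at
n = 2000 records, k = 10 (90 members), 1000-binder anchor profiles and
1000–2000-peptide calibration backgrounds; module tests use smaller
fixtures (300 records, 3 alleles, 500 binders). Brute-force oracles
(all-window ICORE enumeration, all-pairs similarity audits, the
380-pair codon-neighbourhood check) back the hot paths. The kernel and
the Hobohm-1 scan are implemented in C++ (Rcpp); everything else is
plain R on top of ranger, with single-threaded forests and derived
per-member seeds so results are bit-reproducible.

Known limitations: no gapped binding-core modelling (only contiguous
sub-windows are candidates); foreignness is a pass-through input, not
computed; no class weighting in the forests (the class imbalance is
carried as-is); and percentile calibration quality is bounded by the
size and realism of the background sample.
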