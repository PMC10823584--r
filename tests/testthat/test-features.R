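test_that("weighted one-hot composition is a probability vector", {
  w9 <- rep(1, 9)
  c1 <- weighted_composition("AAAAAAAAA", w9)
  expect_equal(unname(c1["A"]), 1)
  expect_equal(sum(c1), 1)

  c2 <- weighted_composition("ACACACAC", rep(1, 8))
  expect_equal(unname(c2[c("A", "C")]), c(0.5, 0.5))

  # masking all but position 2 gives the indicator of that residue
  w <- c(0, 1, rep(0, 7))
  c3 <- weighted_composition("ACDEFGHIK", w)
  expect_equal(unname(c3["C"]), 1)
  expect_equal(sum(c3), 1)

  # probability vector under every scheme on a realistic profile
  prof <- test_profiles()[[1]]
  for (scheme in c("None", "Normal", "NormalMask", "Inverted",
                   "InvertedMask")) {
    wts <- make_weights(prof, scheme)
    p <- random_test_peptides(1, lengths = prof$length, seed = 61)
    comp <- if (all(wts == 0)) {
      expect_warning(weighted_composition(p, wts), "all-zero")
    } else {
      comp <- weighted_composition(p, wts)
      expect_true(all(comp >= 0))
      expect_equal(sum(comp), 1, tolerance = 1e-12)
    }
  }
})

test_that("BLOSUM62 composition encoding is the weighted mean of rows", {
  b <- blosum62()
  c1 <- weighted_composition("AAA", rep(1, 3), encoding = "blosum62")
  expect_equal(unname(c1), unname(b["A", ]))
  c2 <- weighted_composition("AC", c(3, 1), encoding = "blosum62")
  expect_equal(unname(c2), unname(0.75 * b["A", ] + 0.25 * b["C", ]))
})

test_that("scaled agretopicity separates binder gains from non-binder pairs", {
  res <- scaled_agretopicity(c(0.1, 10), c(1, 100))
  expect_equal(res$ratio, c(0.1, 0.1))
  expect_equal(res$scaled, c(0.09, 9))
  # zero on the diagonal, positive elsewhere
  grid <- expand.grid(m = c(0.05, 0.5, 2, 20, 80), w = c(0.05, 0.5, 2, 20, 80))
  s <- scaled_agretopicity(grid$m, grid$w)$scaled
  expect_true(all(s >= 0))
  expect_equal(s == 0, grid$m == grid$w)
  expect_warning(scaled_agretopicity(1, 0), "clamped")
})

test_that("mutation scores follow BLOSUM62 and the codon table", {
  expect_equal(mutation_scores("KVAELVHFL", "KVAELVHFL"),
               data.frame(blosum_score = 0, codon_score = 0))
  b <- blosum62()
  ms <- mutation_scores("SLLMWITQV", "SLLMWITQC")
  expect_equal(ms$blosum_score, unname(b["C", "V"]))
  # A -> V: exactly one of the nine substitutions of any GCN codon
  m <- codon_mutation_matrix()
  expect_equal(unname(m["A", "V"]), 1 / 9, tolerance = 1e-12)
  # A -> L: no single-nucleotide path
  expect_equal(unname(m["A", "L"]), 0)
  # multi-position sums
  ms2 <- mutation_scores("AAV", "AAA")
  expect_equal(ms2$codon_score, 1 / 9, tolerance = 1e-12)
  expect_error(mutation_scores("AAAA", "AAA"), "equal length")
})

test_that("the codon matrix matches a brute-force oracle on all 380 pairs", {
  # independent oracle built on Biostrings' genetic code
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  aa <- aa_alphabet()
  oracle <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (wt in aa) {
    codons <- names(gc)[gc == wt]
    acc <- setNames(numeric(20), aa)
    for (cd in codons) {
      nt <- strsplit(cd, "")[[1]]
      hits <- setNames(numeric(20), aa)
      for (pos in 1:3) for (b in setdiff(bases, nt[pos])) {
        x <- nt; x[pos] <- b
        res <- unname(gc[paste(x, collapse = "")])
        if (res != "*") hits[res] <- hits[res] + 1 / 9
      }
      acc <- acc + hits
    }
    oracle[wt, ] <- acc / length(codons)
  }
  m <- codon_mutation_matrix()
  for (wt in aa) for (mu in aa) {
    if (wt == mu) next
    expect_equal(unname(m[wt, mu]), unname(oracle[wt, mu]),
                 tolerance = 1e-12)
  }
  expect_true(all(m >= 0 & m <= 1))
})

test_that("kernel similarity is a normalised symmetric similarity", {
  peps <- random_test_peptides(20, lengths = 8:11, seed = 62)
  expect_equal(kernel_similarity(peps, peps), rep(1, 20), tolerance = 1e-12)
  a <- peps[1:10]; b <- peps[11:20]
  expect_equal(kernel_similarity(a, b), kernel_similarity(b, a),
               tolerance = 1e-12)
  expect_true(all(kernel_similarity(a, b) > 0))
  expect_true(all(kernel_similarity(a, b) < 1))
  expect_error(kernel_similarity("AC", "ACD"), "at least 3")
})

test_that("one-substitution neighbours are more similar than random pairs", {
  set.seed(63)
  sims_mut <- numeric(100)
  sims_rand <- numeric(100)
  for (i in 1:100) {
    p <- paste0(sample(aa_alphabet(), 9, replace = TRUE), collapse = "")
    q <- paste0(sample(aa_alphabet(), 9, replace = TRUE), collapse = "")
    ch <- split1(p)
    j <- sample(9, 1)
    ch[j] <- sample(setdiff(aa_alphabet(), ch[j]), 1)
    sims_mut[i] <- kernel_similarity(p, paste0(ch, collapse = ""))
    sims_rand[i] <- kernel_similarity(p, q)
  }
  expect_gt(mean(sims_mut), mean(sims_rand))
})

test_that("kernel similarity of 1 implies identity on length-matched peptides", {
  set.seed(64)
  for (i in 1:200) {
    p <- paste0(sample(aa_alphabet(), 9, replace = TRUE), collapse = "")
    ch <- split1(p)
    j <- sample(9, 1)
    ch[j] <- sample(setdiff(aa_alphabet(), ch[j]), 1)
    q <- paste0(ch, collapse = "")
    expect_lt(kernel_similarity(p, q), 1)
  }
})

test_that("physico-chemical descriptors match reference values", {
  # aliphatic index by direct evaluation of the mole-fraction formula
  expect_equal(physchem("AAAAAAAAA")$aliphatic_index, 100)
  expect_equal(physchem("VVVVV")$aliphatic_index, 290)
  expect_equal(physchem("LILI")$aliphatic_index, 390)
  # GRAVY: frozen values computed with an independent reference
  # implementation (Kyte-Doolittle means)
  ref <- c(SLLMWITQV = 1.366667, SLLMWITQC = 1.177778, AAAAAAAAA = 1.8,
           GILGFVFTL = 2.266667, KVAELVHFL = 1.111111,
           RRRKKKDDE = -3.966667, WYFPHMCNQ = -0.755556,
           TSGSDDEQR = -2.355556, LLLLIIIVVA = 3.89, MQWERTYAK = -1.622222)
  got <- physchem(names(ref))$hydrophobicity
  expect_equal(got, unname(ref), tolerance = 1e-3)
})

test_that("isoelectric point agrees with a pH-grid enumeration oracle", {
  # independent oracle: brute-force scan of the same EMBOSS-model net
  # charge over a fine pH grid
  oracle_pi <- function(pep) {
    ch <- split1(pep)
    counts <- table(factor(ch, levels = aa_alphabet()))
    ph <- seq(0, 14, by = 1e-4)
    pos <- 1 / (1 + 10^(ph - 8.6)) +
      counts[["K"]] / (1 + 10^(ph - 10.8)) +
      counts[["R"]] / (1 + 10^(ph - 12.5)) +
      counts[["H"]] / (1 + 10^(ph - 6.5))
    neg <- 1 / (1 + 10^(3.6 - ph)) +
      counts[["D"]] / (1 + 10^(3.9 - ph)) +
      counts[["E"]] / (1 + 10^(4.1 - ph)) +
      counts[["C"]] / (1 + 10^(8.5 - ph)) +
      counts[["Y"]] / (1 + 10^(10.1 - ph))
    ph[which.min(abs(pos - neg))]
  }
  peps <- c("KVAELVHFL", "RRRKKKDDE", "TSGSDDEQR", "WYFPHMCNQ",
            random_test_peptides(20, lengths = 9:11, seed = 65))
  got <- physchem(peps)$isoelectric_point
  want <- vapply(peps, oracle_pi, numeric(1), USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("Boman index is the mean residue interaction value", {
  # direct arithmetic oracle on two hand-picked peptides
  expect_equal(physchem("AAAAAAAAA")$boman_index, -1.81)
  expect_equal(physchem("RND")$boman_index,
               mean(c(14.92, 6.64, 8.72)), tolerance = 1e-12)
})

test_that("feature assembly produces the 21-dim base block plus extras", {
  rec <- test_dataset()[1:40, ]
  profiles <- test_profiles()
  base <- feature_config(scheme = "None", features = character(0))
  Xb <- assemble_features(rec, profiles, base)
  expect_equal(ncol(Xb), 21L)
  expect_equal(colnames(Xb), c(paste0("comp_", aa_alphabet()), "rank_mut"))

  plus <- feature_config(scheme = "None", features = "expression_tpm",
                         tpm_median = 5)
  Xp <- assemble_features(rec, profiles, plus)
  expect_equal(ncol(Xp), 22L)

  # determinism
  expect_identical(Xb, assemble_features(rec, profiles, base))

  # full optional set keeps the recorded schema order
  fc <- feature_config(scheme = "NormalMask",
                       features = c("rank_wt", "scaled_agretopicity",
                                    "blosum_mutation_score",
                                    "codon_mutation_score",
                                    "self_similarity", "physchem",
                                    "expression_tpm"),
                       tpm_median = 5)
  Xf <- assemble_features(rec, profiles, fc)
  expect_equal(colnames(Xf), feature_schema(fc))
  expect_false(anyNA(Xf))
})

test_that("expression imputation needs a median when all values are missing", {
  rec <- test_dataset()[1:5, ]
  rec$expression_tpm <- NA_real_
  fc <- feature_config(scheme = "None", features = "expression_tpm")
  expect_error(assemble_features(rec, test_profiles(), fc),
               "imputation median")
  fc2 <- feature_config(scheme = "None", features = "expression_tpm",
                        tpm_median = 7.5)
  X <- assemble_features(rec, test_profiles(), fc2)
  expect_equal(unname(X[, "expression_tpm"]), rep(7.5, 5))
})
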