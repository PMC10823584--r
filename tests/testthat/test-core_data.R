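test_that("CSV reading normalises alleles and parses the worked pair", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "mutant_peptide,wt_peptide,hla_allele,target,expression_tpm",
    "SLLMWITQV,SLLMWITQC,HLA-A*02:01,1,12.5",
    "slymwitqv,SLYMWITQC,A0201,0,",
    "APRGPHGGA,APRGPHGGV,HLA-B07:02,,3.2"
  ), path)
  rec <- read_neoepitope_dataset(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$allele, c("HLA-A*02:01", "HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(rec$mutant_peptide[2], "SLYMWITQV") # upper-cased
  # the anchor-optimised pair differs at position 9 (C -> V)
  mm <- which(split1(rec$mutant_peptide[1]) != split1(rec$wt_peptide[1]))
  expect_equal(mm, 9L)
  expect_equal(rec$label, c(1L, 0L, NA_integer_))
  expect_equal(rec$expression_tpm[2], NA_real_)
})

test_that("reading an empty table yields zero records and a clean round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("mutant_peptide,wt_peptide,hla_allele", path)
  rec <- read_neoepitope_dataset(path)
  expect_equal(nrow(rec), 0L)

  out <- withr::local_tempfile(fileext = ".csv")
  rec2 <- test_dataset()[1:20, ]
  write_neoepitope_dataset(rec2, out)
  back <- read_neoepitope_dataset(out)
  expect_equal(back$mutant_peptide, rec2$mutant_peptide)
  expect_equal(back$wt_peptide, rec2$wt_peptide)
  expect_equal(back$allele, rec2$allele)
  expect_equal(back$label, rec2$label)
  expect_equal(back$expression_tpm, rec2$expression_tpm, tolerance = 1e-12)
})

test_that("a missing required column is a configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant_peptide,hla_allele", "SLLMWITQV,HLA-A*02:01"), path)
  expect_error(read_neoepitope_dataset(path), "wt_peptide")
})

test_that("label collapsing keeps one record per peptide-HLA pair", {
  rec <- data.frame(
    mutant_peptide = c("SLLMWITQV", "SLLMWITQV", "SLLMWITQV",
                       "APRGPHGGA", "APRGPHGGA", "KVAELVHFL"),
    wt_peptide = "X", allele = c(rep("HLA-A*02:01", 3),
                                 rep("HLA-B*07:02", 2), "HLA-A*02:01"),
    label = c(1L, 0L, 0L, 0L, 0L, NA_integer_),
    stringsAsFactors = FALSE
  )
  out <- collapse_labels(rec)
  expect_equal(nrow(out), 3L)
  expect_equal(out$label[out$mutant_peptide == "SLLMWITQV"], 1L)
  expect_equal(out$label[out$mutant_peptide == "APRGPHGGA"], 0L)
  expect_true(is.na(out$label[out$mutant_peptide == "KVAELVHFL"]))
  # idempotence
  expect_identical(collapse_labels(out), out)
  # single record unchanged
  one <- rec[6, , drop = FALSE]
  expect_equal(collapse_labels(one)$mutant_peptide, one$mutant_peptide)
})

test_that("filters route records to the right rejection reasons", {
  pred <- test_predictor()
  al <- predictor_alleles(pred)[1]
  rec <- data.frame(
    mutant_peptide = c(
      "KVAELVHFV",          # fine: 1 mismatch
      "KVAELVHF",           # frameshift: length 8 vs WT 9
      "KVAELXHFV",          # bad alphabet
      "KVAELVHFL",          # identical to WT
      "KVAELVHFLKVAELVHFV", # length 18 out of range
      "CCCCCVHFV"           # >= 4 mismatches in every window
    ),
    wt_peptide = c("KVAELVHFL", "KVAELVHFL", "KVAELVHFL", "KVAELVHFL",
                   "KVAELVHFLKVAELVHFL", "KVAELVHFL"),
    allele = al, allele_resolved = TRUE,
    stringsAsFactors = FALSE
  )
  vf <- validate_and_filter(rec, pred)
  expect_equal(vf$report$n_input, 6L)
  expect_equal(vf$report$n_accepted, 1L)
  counts <- setNames(vf$report$counts, vf$report$reasons)
  expect_equal(unname(counts["frameshift_length_mismatch"]), 1L)
  expect_equal(unname(counts["bad_alphabet"]), 1L)
  expect_equal(unname(counts["identical_pair"]), 1L)
  expect_equal(unname(counts["length_out_of_range"]), 1L)
  expect_equal(unname(counts["too_many_icore_mismatches"]), 1L)
  # accepted record carries its ICORE pair
  expect_true(all(c("icore_mut", "icore_wt", "rank_mut", "rank_wt")
                  %in% names(vf$records)))
  expect_lte(vf$records$n_icore_mismatches[1], 3L)
})

test_that("a predictor missing an allele is fatal and names it", {
  pred <- test_predictor()
  rec <- data.frame(mutant_peptide = "KVAELVHFV", wt_peptide = "KVAELVHFL",
                    allele = "HLA-B*57:01", allele_resolved = TRUE,
                    stringsAsFactors = FALSE)
  expect_error(validate_and_filter(rec, pred), "HLA-B\\*57:01")
})

test_that("accepted plus rejected counts always equal the input count", {
  pred <- test_predictor()
  al <- predictor_alleles(pred)
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    wt <- random_test_peptides(n, lengths = 8:12, seed = 1000 + rep)
    mut <- vapply(wt, function(p) {
      ch <- split1(p)
      i <- sample(length(ch), 1)
      ch[i] <- sample(aa_alphabet(), 1) # may equal the original
      paste0(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    # corrupt a random subset
    bad <- sample(n, 12)
    mut[bad[1:3]] <- paste0(substr(mut[bad[1:3]], 1, 6), "X")
    wt[bad[4:6]] <- substr(wt[bad[4:6]], 1, 7) # frameshift or short
    mut[bad[7:9]] <- "KVA" # way short
    rec <- data.frame(mutant_peptide = mut, wt_peptide = wt,
                      allele = sample(al, n, replace = TRUE),
                      allele_resolved = TRUE, stringsAsFactors = FALSE)
    vf <- validate_and_filter(rec, pred)
    expect_equal(vf$report$n_accepted + sum(vf$report$counts),
                 vf$report$n_input)
  }
})

test_that("allele normalisation accepts known conventions, rejects junk", {
  expect_equal(normalize_hla(c("A0201", "HLA-A02:01", "HLA-A*02:01",
                               "B0702", "hla-c*07:01")),
               c("HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01",
                 "HLA-B*07:02", "HLA-C*07:01"))
  expect_true(all(is.na(normalize_hla(c("banana", "HLA-DRB1*01:01", "A02")))))
})
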