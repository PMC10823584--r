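# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small surrogate allele set for module tests
test_alleles <- function() {
  if (is.null(.fixtures$alleles)) {
    .fixtures$alleles <- make_alleles(3, seed = 101)
  }
  .fixtures$alleles
}

test_predictor <- function() test_alleles()$predictor

# a moderate labelled dataset with ICORE columns attached
test_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    al <- test_alleles()
    rec <- make_neoepitope_dataset(300, al, seed = 303)
    vf <- validate_and_filter(rec, al$predictor)
    .fixtures$dataset <- vf$records
  }
  .fixtures$dataset
}

# anchor profiles for the test alleles (reduced binder count: fast,
# still sharp enough to recover anchors)
test_profiles <- function() {
  if (is.null(.fixtures$profiles)) {
    .fixtures$profiles <- build_anchor_profiles(
      test_predictor(), n_binders = 500, seed = 404)
  }
  .fixtures$profiles
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

random_test_peptides <- function(n, lengths = 9L, seed = 1L) {
  set.seed(seed)
  lens <- rep_len(lengths, n)
  lens <- lens[sample.int(length(lens))]
  vapply(lens, function(L) {
    paste0(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, character(1))
}

netmhcpan_fixture <- function() {
  system.file("extdata", "netmhcpan_example.txt", package = "icoreRF")
}

# --- heavy fixtures shared by the acceptance tests -----------------------

# full-scale strong-signal training run (n = 2000, k = 10)
acceptance_run <- function() {
  if (is.null(.fixtures$acceptance)) {
    al <- make_alleles(6, seed = 1)
    rec <- make_neoepitope_dataset(2000, al, signal = signal_spec_strong(),
                                   seed = 1)
    vf <- validate_and_filter(rec, al$predictor)
    rec <- vf$records
    plan <- make_partitions(rec, k = 10, seed = 1)
    rec$fold <- plan$fold
    profiles <- build_anchor_profiles(al$predictor, n_binders = 1000,
                                      seed = 1)
    fc <- feature_config(tpm_median = median(rec$expression_tpm))
    X <- assemble_features(rec, profiles, fc)
    # append a pure-noise column so importance ranking can be probed
    set.seed(1234)
    X <- cbind(X, noise = rnorm(nrow(X)))
    ens <- train_nested_cv(X, rec$label, rec$fold,
                           rf_hyperparams(seed = 1), config = fc)
    .fixtures$acceptance <- list(alleles = al, records = rec, plan = plan,
                                 profiles = profiles, config = fc, X = X,
                                 ensemble = ens)
  }
  .fixtures$acceptance
}
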