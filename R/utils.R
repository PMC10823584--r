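#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. All
#' composition vectors, frequency profiles and the vendored BLOSUM62
#' matrix use this ordering.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# split a peptide into residues
aa_split <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TRUE if every character of every peptide is in the canonical alphabet
is_canonical_peptide <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    length(ch) > 0L && all(ch %in% aa_alphabet())
  }, logical(1))
}

# integer encoding (1..20) of one peptide; NA for non-canonical residues
pep_encode <- function(x) {
  lapply(strsplit(x, "", fixed = TRUE), match, table = aa_alphabet())
}

# Run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Keeps every generator reproducible without
# clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a bounded child seed from a parent seed and a tag
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
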