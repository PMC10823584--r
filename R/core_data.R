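#' Normalise HLA class I allele names
#'
#' Accepts the naming conventions found in benchmark files —
#' `"HLA-A*02:01"`, `"HLA-A02:01"`, `"A*02:01"`, `"A0201"` — and emits
#' the starred canonical form `"HLA-A*02:01"`. Unrecognised patterns
#' return `NA` rather than a guess.
#'
#' @param x Character vector of allele names.
#' @return Character vector of canonical names, `NA` where the input
#'   could not be resolved.
#' @export
#' @examples
#' normalize_hla(c("A0201", "HLA-B07:02", "HLA-C*07:01"))
normalize_hla <- function(x) {
  out <- rep(NA_character_, length(x))
  y <- toupper(trimws(x))
  y <- sub("^HLA-", "", y)
  y <- gsub("*", "", y, fixed = TRUE)
  m <- regmatches(y, regexec("^([ABC])([0-9]{2,3}):([0-9]{2,3})$", y))
  for (i in seq_along(y)) {
    g <- m[[i]]
    if (length(g) == 4L) {
      out[i] <- sprintf("HLA-%s*%s:%s", g[2], g[3], g[4])
      next
    }
    # colon-less four/five-digit form, e.g. A0201
    g <- regmatches(y[i], regexec("^([ABC])([0-9]{4,5})$", y[i]))[[1]]
    if (length(g) == 3L) {
      d <- g[3]
      grp <- substr(d, 1L, nchar(d) - 2L)
      prot <- substr(d, nchar(d) - 1L, nchar(d))
      out[i] <- sprintf("HLA-%s*%s:%s", g[2], grp, prot)
    }
  }
  out
}

# canonical column names and accepted aliases in input files
default_column_map <- function() {
  list(mutant_peptide = c("mutant_peptide", "mutant", "mut_peptide", "peptide"),
       wt_peptide = c("wt_peptide", "wild_type", "wildtype", "wt"),
       allele = c("hla_allele", "allele", "hla", "mhc"),
       label = c("target", "label", "immunogenicity"),
       expression_tpm = c("expression_tpm", "tpm", "total_gene_tpm"),
       foreignness = c("foreignness", "foreignness_score"),
       fold = c("partition", "fold"),
       source_id = c("source_id", "id"))
}

#' Read a neo-epitope dataset
#'
#' Reads a comma-separated file with a header row into a neo-epitope
#' record table. Required columns: mutant peptide, wild-type peptide
#' and HLA allele (several common header spellings are accepted, or an
#' explicit `column_map` can rename them). Optional columns — binary
#' label, expression TPM, foreignness score, fold id — are attached
#' when present. Peptides are upper-cased; alleles are normalised to
#' the canonical starred form where possible (unresolvable names are
#' kept verbatim and rejected later by [validate_and_filter()]).
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named list mapping canonical names
#'   (`mutant_peptide`, `wt_peptide`, `allele`, `label`,
#'   `expression_tpm`, `foreignness`, `fold`) to the file's column
#'   names.
#' @return A data frame of records with a `source_id` column (the
#'   1-based input row), of class `neoepitope_data`.
#' @export
read_neoepitope_dataset <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("read_neoepitope_dataset: no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- default_column_map()
  if (!is.null(column_map)) {
    for (nm in names(column_map)) cmap[[nm]] <- column_map[[nm]]
  }
  pick <- function(field) {
    hit <- intersect(cmap[[field]], names(raw))
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  mut <- pick("mutant_peptide")
  wt <- pick("wt_peptide")
  al <- pick("allele")
  missing_cols <- c("mutant_peptide", "wt_peptide", "allele")[
    c(is.null(mut), is.null(wt), is.null(al))]
  if (length(missing_cols)) {
    stop("read_neoepitope_dataset: required column(s) missing: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  rec <- data.frame(
    mutant_peptide = toupper(trimws(mut)),
    wt_peptide = toupper(trimws(wt)),
    allele_input = trimws(al),
    stringsAsFactors = FALSE
  )
  norm <- normalize_hla(rec$allele_input)
  rec$allele <- ifelse(is.na(norm), rec$allele_input, norm)
  rec$allele_resolved <- !is.na(norm)
  lab <- pick("label")
  rec$label <- if (is.null(lab)) rep(NA_integer_, n) else as.integer(lab)
  tpm <- pick("expression_tpm")
  rec$expression_tpm <- if (is.null(tpm)) rep(NA_real_, n)
                        else as.numeric(tpm)
  fg <- pick("foreignness")
  rec$foreignness <- if (is.null(fg)) rep(NA_real_, n) else as.numeric(fg)
  fold <- pick("fold")
  rec$fold <- if (is.null(fold)) rep(NA_integer_, n) else as.integer(fold)
  sid <- pick("source_id")
  rec$source_id <- if (is.null(sid)) as.character(seq_len(n))
                   else as.character(sid)
  class(rec) <- c("neoepitope_data", "data.frame")
  rec
}

#' Write a neo-epitope dataset
#'
#' Inverse of [read_neoepitope_dataset()]: writes the canonical CSV
#' dialect (plus any appended pipeline columns) so read -> write ->
#' read round-trips all fields.
#'
#' @param records A record data frame.
#' @param path Output CSV path.
#' @export
write_neoepitope_dataset <- function(records, path) {
  drop <- intersect(c("allele_input", "allele_resolved"), names(records))
  out <- records[, setdiff(names(records), drop), drop = FALSE]
  nm <- names(out)
  nm[nm == "allele"] <- "hla_allele"
  nm[nm == "label"] <- "target"
  nm[nm == "fold"] <- "partition"
  names(out) <- nm
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse duplicate labels per (mutant peptide, allele) pair
#'
#' A peptide-HLA pair may carry several assay entries with conflicting
#' labels; the collapsed record is immunogenic (1) if any entry is
#' positive and negative (0) only if all labelled entries are negative.
#' Unlabelled duplicates inherit the collapsed label. The first
#' occurrence of each pair supplies the remaining fields. The operation
#' is idempotent.
#'
#' @param records A record data frame.
#' @return A record data frame with one row per (mutant peptide,
#'   allele) pair, in first-occurrence order.
#' @export
collapse_labels <- function(records) {
  key <- paste(records$mutant_peptide, records$allele, sep = "|")
  first <- !duplicated(key)
  lab <- tapply(records$label, key, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_integer_ else as.integer(max(v))
  })
  out <- records[first, , drop = FALSE]
  out$label <- as.integer(lab[key[first]])
  rownames(out) <- NULL
  out
}

rejection_reasons <- function() {
  c("missing_field", "bad_alphabet", "identical_pair",
    "frameshift_length_mismatch", "length_out_of_range", "bad_allele",
    "unknown_allele", "too_many_icore_mismatches")
}

#' Record filtering with ICORE extraction
#'
#' Applies the record-level filters in a fixed order, routing failures
#' to a rejection report, and attaches ICORE columns (via
#' [extract_icores()]) to the survivors:
#' missing fields; non-canonical residues (X/B/Z/U etc. are rejected,
#' not imputed); mutant identical to wild type; unequal peptide lengths
#' (frameshift products); length outside `length_range`; unresolvable
#' allele name; and finally more than `max_icore_mismatches` mismatches
#' between the mutant ICORE and its aligned wild-type ICORE.
#'
#' @inheritParams predict_rank
#' @param records A record data frame from [read_neoepitope_dataset()]
#'   or [make_neoepitope_dataset()].
#' @param max_icore_mismatches Maximum mutations allowed between the
#'   two ICOREs (default 3).
#' @param length_range Allowed peptide length range (default 8-12).
#' @return A list with `records` (accepted rows with ICORE columns) and
#'   `report` (a `rejection_report`: per-reason counts summing, with
#'   the accepted count, to the input row count).
#' @export
validate_and_filter <- function(records, predictor,
                                max_icore_mismatches = 3L,
                                length_range = c(8L, 12L)) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mut <- records$mutant_peptide
  wt <- records$wt_peptide
  miss <- is.na(mut) | is.na(wt) | is.na(records$allele) |
    mut == "" | wt == "" | records$allele == ""
  reason[miss] <- "missing_field"
  ok <- is.na(reason)
  bad_aa <- ok & !(is_canonical_peptide(mut) & is_canonical_peptide(wt))
  reason[bad_aa] <- "bad_alphabet"
  ok <- is.na(reason)
  ident <- ok & mut == wt
  reason[ident] <- "identical_pair"
  ok <- is.na(reason)
  fs <- ok & nchar(mut) != nchar(wt)
  reason[fs] <- "frameshift_length_mismatch"
  ok <- is.na(reason)
  lbad <- ok & (nchar(mut) < length_range[1] | nchar(mut) > length_range[2])
  reason[lbad] <- "length_out_of_range"
  ok <- is.na(reason)
  if (!is.null(records$allele_resolved)) {
    abad <- ok & !records$allele_resolved
    reason[abad] <- "bad_allele"
    ok <- is.na(reason)
  }
  known <- predictor_alleles(predictor)
  unk <- ok & !(records$allele %in% known)
  if (any(unk)) {
    stop("validate_and_filter: predictor does not cover allele(s): ",
         paste(unique(records$allele[unk]), collapse = ", "))
  }
  kept <- records[ok, , drop = FALSE]
  if (nrow(kept)) {
    kept <- extract_icores(kept, predictor)
    too_many <- kept$n_icore_mismatches > max_icore_mismatches
    reason[ok][too_many] <- "too_many_icore_mismatches"
    kept <- kept[!too_many, , drop = FALSE]
  }
  rownames(kept) <- NULL
  counts <- table(factor(reason, levels = rejection_reasons()))
  report <- structure(
    list(counts = as.integer(counts),
         reasons = rejection_reasons(),
         n_input = n, n_accepted = nrow(kept)),
    class = "rejection_report"
  )
  list(records = kept, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("Rejection report:", x$n_input, "records in,",
      x$n_accepted, "accepted\n")
  for (i in seq_along(x$reasons)) {
    if (x$counts[i] > 0) cat("  ", x$reasons[i], ": ", x$counts[i], "\n",
                             sep = "")
  }
  invisible(x)
}
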