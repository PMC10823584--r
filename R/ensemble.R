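#' Random-forest hyperparameters
#'
#' Defaults are the tuned values used throughout: 300 trees, maximum
#' depth 8, at least 7 samples per leaf. `pruning_alpha` records the
#' cost-complexity regularisation strength of the reference
#' configuration; the ranger backend grows depth/leaf-constrained
#' trees without post-hoc cost-complexity pruning, so at the default
#' 1e-5 the parameter is metadata only (see the methods vignette).
#'
#' @param n_trees,max_depth,min_samples_leaf,pruning_alpha Forest
#'   settings (defaults 300, 8, 7, 1e-5).
#' @param seed Base seed; each ensemble member derives its own seed
#'   from it.
#' @return An object of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(n_trees = 300L, max_depth = 8L,
                           min_samples_leaf = 7L, pruning_alpha = 1e-5,
                           seed = 1L) {
  stopifnot(n_trees > 0, max_depth > 0, min_samples_leaf > 0,
            pruning_alpha > 0)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 pruning_alpha = pruning_alpha, seed = as.integer(seed)),
            class = "rf_hyperparams")
}

fit_member <- function(X, y, hyper, member_seed) {
  ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = hyper$n_trees, max.depth = hyper$max_depth,
    min.node.size = hyper$min_samples_leaf, probability = TRUE,
    importance = "impurity", seed = member_seed, num.threads = 1L,
    verbose = FALSE
  )
}

member_prob <- function(model, X) {
  p <- predict(model, data = X, num.threads = 1L)$predictions
  p[, "1"]
}

#' Train the nested cross-validated random-forest ensemble
#'
#' For each outer fold `o` and each inner fold `i != o`, one forest is
#' fitted on the remaining `k - 2` folds, giving `k * (k - 1)` members
#' (90 for `k = 10`). The out-of-fold prediction for a record in fold
#' `o` is the mean positive-class probability of the `k - 1` members
#' whose training data excluded fold `o` — so no member ever saw the
#' record it scores.
#'
#' @param X Numeric feature matrix with a `schema` attribute (from
#'   [assemble_features()]).
#' @param y Binary labels (0/1), one per row of `X`.
#' @param fold Integer fold id (0-based) per row.
#' @param hyper An [rf_hyperparams()].
#' @param config The [feature_config()] used to build `X`, stored with
#'   the model.
#' @return An object of class `rf_ensemble` with fields `members`
#'   (each with `model`, `outer`, `inner`), `schema`, `hyper`,
#'   `config`, `k`, `oof` (out-of-fold scores, NA where a record's
#'   fold never served as outer fold).
#' @export
train_nested_cv <- function(X, y, fold, hyper = rf_hyperparams(),
                            config = NULL) {
  stopifnot(nrow(X) == length(y), length(fold) == length(y))
  folds <- sort(unique(fold))
  k <- length(folds)
  if (k < 3L) stop("train_nested_cv: need at least 3 folds")
  members <- list()
  oof_sum <- numeric(length(y))
  oof_cnt <- integer(length(y))
  for (o in folds) {
    test_idx <- which(fold == o)
    for (i in setdiff(folds, o)) {
      train_idx <- which(!(fold %in% c(o, i)))
      ytr <- y[train_idx]
      if (length(unique(ytr)) < 2L) {
        stop("train_nested_cv: single-class training split with outer fold ",
             o, ", inner fold ", i)
      }
      member_seed <- derive_seed(hyper$seed, paste0("member_", o, "_", i))
      model <- fit_member(X[train_idx, , drop = FALSE], ytr, hyper,
                          member_seed)
      members[[length(members) + 1L]] <-
        list(model = model, outer = o, inner = i)
      if (length(test_idx)) {
        oof_sum[test_idx] <- oof_sum[test_idx] +
          member_prob(model, X[test_idx, , drop = FALSE])
        oof_cnt[test_idx] <- oof_cnt[test_idx] + 1L
      }
    }
  }
  oof <- ifelse(oof_cnt > 0, oof_sum / oof_cnt, NA_real_)
  structure(
    list(members = members, schema = colnames(X), hyper = hyper,
         config = config, k = k, folds = folds, oof = oof,
         calibration = NULL),
    class = "rf_ensemble"
  )
}

check_schema <- function(ensemble, X) {
  if (!identical(colnames(X), ensemble$schema)) {
    missing <- setdiff(ensemble$schema, colnames(X))
    extra <- setdiff(colnames(X), ensemble$schema)
    stop("schema mismatch: missing [", paste(missing, collapse = ", "),
         "], unexpected [", paste(extra, collapse = ", "), "]")
  }
}

#' Predict with a trained ensemble
#'
#' The score of a record is the mean positive-class probability over
#' all ensemble members, a value in \[0, 1\].
#'
#' @param object An `rf_ensemble`.
#' @param newdata Feature matrix with the ensemble's schema.
#' @param ... Unused.
#' @return Numeric score vector in \[0, 1\].
#' @export
predict.rf_ensemble <- function(object, newdata, ...) {
  check_schema(object, newdata)
  probs <- vapply(object$members,
                  function(m) member_prob(m$model, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) mean(probs) else rowMeans(probs)
}

#' Mean impurity feature importances of an ensemble
#'
#' Mean decrease-in-impurity importance over all members, normalised to
#' sum to 1.
#'
#' @param ensemble An `rf_ensemble`.
#' @return Named numeric vector over the feature schema, summing to 1.
#' @export
feature_importances <- function(ensemble) {
  imp <- rowMeans(vapply(ensemble$members,
                         function(m) m$model$variable.importance[ensemble$schema],
                         numeric(length(ensemble$schema))))
  imp / sum(imp)
}

#' Calibrate percentile ranks against a background
#'
#' Scores a background feature matrix (randomly mutated proteome
#' peptides pushed through the same feature pipeline) with the ensemble
#' and stores the sorted scores. [percentile_rank()] then maps a model
#' score to `100 * (count of background scores >= score) / n` — 0 means
#' more immunogenic-like than every background peptide.
#'
#' @param ensemble An `rf_ensemble`.
#' @param background_X Background feature matrix (ensemble schema).
#' @return The ensemble with a `calibration` field (sorted background
#'   scores).
#' @export
calibrate_percentile <- function(ensemble, background_X) {
  if (nrow(background_X) == 0L) {
    stop("calibrate_percentile: empty background")
  }
  scores <- predict(ensemble, background_X)
  ensemble$calibration <- sort(scores)
  ensemble
}

#' @rdname calibrate_percentile
#' @param scores Model scores to convert to percentile ranks.
#' @return For `percentile_rank`: numeric vector in \[0, 100\],
#'   monotone non-increasing in the score.
#' @export
percentile_rank <- function(ensemble, scores) {
  bg <- if (inherits(ensemble, "rf_ensemble")) ensemble$calibration
        else sort(ensemble)
  if (is.null(bg) || length(bg) == 0L) {
    stop("percentile_rank: no calibration background ",
         "(run calibrate_percentile first)")
  }
  n_lt <- findInterval(scores, bg, left.open = TRUE)
  100 * (length(bg) - n_lt) / length(bg)
}

#' Persist and restore a trained ensemble
#'
#' The model directory holds a JSON metadata file (schema, feature
#' configuration, hyperparameters, fold structure, calibration scores)
#' plus one serialised forest per member.
#'
#' @param ensemble An `rf_ensemble`.
#' @param dir Model directory (created if needed).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    schema = ensemble$schema, k = ensemble$k, folds = ensemble$folds,
    hyper = unclass(ensemble$hyper),
    config = if (!is.null(ensemble$config)) unclass(ensemble$config),
    calibration = ensemble$calibration,
    members = lapply(ensemble$members, function(m)
      list(outer = m$outer, inner = m$inner))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (j in seq_along(ensemble$members)) {
    saveRDS(ensemble$members[[j]]$model,
            file.path(dir, sprintf("member_%03d.rds", j)))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @return For `load_ensemble`: the restored `rf_ensemble`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  members <- vector("list", length(meta$members$outer))
  for (j in seq_along(members)) {
    members[[j]] <- list(
      model = readRDS(file.path(dir, sprintf("member_%03d.rds", j))),
      outer = meta$members$outer[j], inner = meta$members$inner[j])
  }
  config <- if (!is.null(meta$config)) {
    structure(meta$config, class = "feature_config")
  }
  structure(
    list(members = members, schema = meta$schema,
         hyper = structure(meta$hyper, class = "rf_hyperparams"),
         config = config, k = meta$k, folds = meta$folds, oof = NULL,
         calibration = meta$calibration),
    class = "rf_ensemble"
  )
}
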