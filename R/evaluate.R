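#' Squared Pearson correlation between predictions and observations
#'
#' The standard accuracy metric for genomic prediction.  Constant
#' predictions return 0 (no linear association can be claimed); constant
#' observations are an error because the metric is undefined.
#'
#' @param pred,obs numeric vectors of equal length (at least 2).
#' @return A number in \[0, 1\].
#' @export
pearson_r2 <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2L)
  if (stats::sd(obs) == 0) stop("observed values are constant; r2 is undefined",
                                call. = FALSE)
  if (stats::sd(pred) == 0) return(0)
  stats::cor(pred, obs)^2
}

#' Deterministic k-fold assignment
#'
#' Samples are shuffled under the given seed, then cut into `k`
#' contiguous blocks whose sizes differ by at most one.
#'
#' @param n sample count.
#' @param k fold count, `2 <= k <= n`.
#' @param seed integer seed; the caller's RNG stream is untouched.
#' @return Integer vector of length `n` with fold labels in `1..k`.
#' @export
make_folds <- function(n, k, seed) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  assignment <- integer(n)
  assignment[perm] <- rep.int(seq_len(k), sizes)
  assignment
}

#' Leakage-safe k-fold cross validation of encoding/predictor pipelines
#'
#' @description
#' For each fold, every data-dependent step is fitted on the training
#' rows only and then applied unchanged to the held-out rows: allele
#' orientation is re-decided on the training fold, the encoding (and
#' pair grids or product features, if requested) is fitted on the
#' training fold, and the predictor is trained on the encoded training
#' matrix.  The fold's accuracy is the squared Pearson correlation
#' between predicted and observed test traits; the report's headline
#' number is the arithmetic mean of the per-fold values.
#'
#' Several encodings can be compared in one call; they share the same
#' fold assignment so that method differences are not fold noise.
#'
#' @param G a [geno_matrix()] (orientation is handled internally per
#'   fold).
#' @param y a [trait_vector()]; samples are aligned with `G` via
#'   [validate_aligned()].
#' @param encodings character vector of encoding names (see
#'   [fit_encoding()]).
#' @param predictor `"rrblup"` or `"svr"`.
#' @param k fold count (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param ordinal_base passed to [fit_ordinal()].
#' @param epistasis `NULL`, or a list describing interaction features:
#'   `type` one of `"product"`, `"grid_hybrid_one"`, `"grid_hybrid_two"`;
#'   plus pair-selection fields `strategy`, `t`, `pairs` as in
#'   [select_pairs()].  Pair selection is re-run per training fold.
#' @param svr an [svr_config()] used when `predictor = "svr"`.
#' @return An object of class `cv_report`: a list with `k`, `seed`,
#'   `folds` (named assignment), `results` (long data frame: method,
#'   predictor, fold, r2), `summary` (mean r2 per method) and
#'   `predictions` (out-of-fold predictions, samples x methods).  A fold
#'   whose test traits are constant gets `NA` r2 and is excluded from
#'   the mean, with a warning.
#' @examples
#' cfg <- sim_config(n = 60, m = 20, n_causal = 10, h2 = 0.8, seed = 1)
#' G <- simulate_genotypes(cfg)
#' y <- simulate_trait(G, cfg)$trait
#' cross_validate(G, y, encodings = "hybrid_two", k = 5, seed = 1)$summary
#' @export
cross_validate <- function(G, y, encodings = "hybrid_two",
                           predictor = c("rrblup", "svr"), k = 10L,
                           seed = 1L, ordinal_base = "zero_one_two",
                           epistasis = NULL, svr = svr_config()) {
  predictor <- match.arg(predictor)
  encodings <- vapply(encodings, function(e) {
    match.arg(e, c("ordinal", "ordinal_flipped", "target", "hybrid_one",
                   "hybrid_two"))
  }, character(1), USE.NAMES = FALSE)
  al <- validate_aligned(G, y)
  G <- al$G; y <- al$y
  n <- nrow(G$values)
  folds <- make_folds(n, k, seed)
  names(folds) <- rownames(G$values)
  ids <- rownames(G$values)

  results <- expand.grid(method = encodings, fold = seq_len(k),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  results <- results[order(match(results$method, encodings), results$fold), ]
  results$predictor <- predictor
  results$r2 <- NA_real_
  oof <- matrix(NA_real_, nrow = n, ncol = length(encodings),
                dimnames = list(ids, encodings))

  for (f in seq_len(k)) {
    train_ids <- ids[folds != f]
    test_ids <- ids[folds == f]
    Gf <- orient_major_allele(G, reference_rows = train_ids)
    Gtrain <- geno_matrix(Gf$values[train_ids, , drop = FALSE], oriented = TRUE)
    Gtest <- geno_matrix(Gf$values[test_ids, , drop = FALSE], oriented = TRUE)
    ytrain <- trait_vector(unclass(y)[train_ids])
    yobs <- unclass(y)[test_ids]
    for (method in encodings) {
      enc <- fit_encoding(method, Gtrain, ytrain, ordinal_base = ordinal_base)
      Xtr <- encode_genotypes(enc, Gtrain)
      Xte <- encode_genotypes(enc, Gtest)
      if (!is.null(epistasis)) {
        feats <- build_epistasis_features(epistasis, Gtrain, Gtest, ytrain,
                                          Xtr, Xte)
        Xtr <- cbind(Xtr, feats$train)
        Xte <- cbind(Xte, feats$test)
      }
      model <- if (predictor == "rrblup") fit_rrblup(Xtr, as.numeric(ytrain))
               else fit_svr(Xtr, as.numeric(ytrain), cfg = svr)
      pred <- stats::predict(model, Xte)
      oof[test_ids, method] <- pred
      r2 <- if (length(yobs) < 2L || stats::sd(yobs) == 0) {
        warning(sprintf("fold %d has constant test traits; r2 recorded as NA", f),
                call. = FALSE)
        NA_real_
      } else {
        pearson_r2(pred, yobs)
      }
      results$r2[results$method == method & results$fold == f] <- r2
    }
  }
  summary_df <- do.call(rbind, lapply(encodings, function(method) {
    r2 <- results$r2[results$method == method]
    data.frame(method = method, predictor = predictor,
               mean_r2 = mean(r2, na.rm = TRUE),
               folds_used = sum(!is.na(r2)), stringsAsFactors = FALSE)
  }))
  structure(list(k = k, seed = seed, folds = folds,
                 results = results[, c("method", "predictor", "fold", "r2")],
                 summary = summary_df, predictions = oof),
            class = "cv_report")
}

# Fit-on-train / apply-to-test construction of interaction features.
build_epistasis_features <- function(epistasis, Gtrain, Gtest, ytrain,
                                     Xtr, Xte) {
  type <- match.arg(epistasis$type,
                    c("product", "grid_hybrid_one", "grid_hybrid_two"))
  strategy <- epistasis$strategy %||%
    if (!is.null(epistasis$pairs)) "explicit_list" else "top_t_by_correlation"
  pairs <- select_pairs(Xtr, ytrain, strategy = strategy,
                        t = epistasis$t %||% 50L,
                        pairs = epistasis$pairs,
                        all_pairs_cap = epistasis$all_pairs_cap %||% 200L)
  if (type == "product") {
    list(train = product_features(Xtr, pairs),
         test = product_features(Xte, pairs))
  } else {
    fitter <- if (type == "grid_hybrid_one") fit_pair_grid_hybrid_one
              else fit_pair_grid_hybrid_two
    gm <- fitter(Gtrain, ytrain, pairs)
    list(train = transform_pairs(gm, Gtrain),
         test = transform_pairs(gm, Gtest))
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, seed %d\n", x$k, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
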