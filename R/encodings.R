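#' Single-marker genotype encodings
#'
#' @description
#' Five schemes map each marker's genotype categories \{0, 1, 2\} to real
#' values for regression:
#'
#' * **ordinal** — every marker uses the same fixed labels, either
#'   \{0, 1, 2\} or \{-1, 0, 1\}.  Order of the categories is preserved
#'   but no per-marker information is used.
#' * **ordinal_flipped** — ordinal \{0, 1, 2\}, but any marker whose
#'   Pearson correlation with the training trait is negative has
#'   categories 0 and 2 swapped so every feature correlates
#'   non-negatively with the trait.
#' * **target** — each category is encoded as the mean training trait of
#'   the samples in that category (classic target encoding).  Flexible
#'   per marker, but the heterozygote value need not lie between the two
#'   homozygote values, so category order can be lost.
#' * **hybrid_one** — homozygote categories are target-encoded
#'   (`E0 = mean(y | g = 0)`, `E2 = mean(y | g = 2)`) and the heterozygote
#'   takes the overall training-trait mean, `E1 = mean(y)`.
#' * **hybrid_two** — homozygotes as in hybrid one, heterozygote is the
#'   midpoint `E1 = (E0 + E2) / 2`.
#'
#' Both hybrids keep `E1` between `E0` and `E2`, so they retain the
#' ordinal scheme's order preservation while encoding each marker on the
#' trait's own scale.
#'
#' A genotype category unobserved in the training data falls back to the
#' overall training-trait mean (the no-information encoding); for
#' `hybrid_two` the midpoint is taken after that substitution.
#' Monomorphic markers therefore get a constant encoding under every
#' trait-aware scheme.
#'
#' @param G a [geno_matrix()], oriented (see [orient_major_allele()]).
#' @param y a [trait_vector()] aligned with `G` (training samples only).
#' @param base for `fit_ordinal`: `"zero_one_two"` (default) or
#'   `"minus_one_zero_one"`.
#' @return An object of class `marker_encoding`: the method name, an
#'   `m x 3` map of encoded values per category, the overall training
#'   mean, and per-marker imputation values (mean encoded value over the
#'   training rows) used for missing genotypes at transform time.
#' @seealso [encode_genotypes()] to apply a fitted encoding,
#'   [fit_encoding()] for a method-dispatching wrapper.
#' @examples
#' G <- geno_matrix(matrix(c(0, 0, 1, 1, 2, 2), ncol = 1), oriented = TRUE)
#' y <- trait_vector(stats::setNames(c(1, 2, 3, 5, 8, 10), rownames(G$values)))
#' fit_hybrid_two(G, y)$map   # E0 = 1.5, E1 = 5.25, E2 = 9
#' @name encodings
NULL

new_marker_encoding <- function(method, map, train_mean, impute, warn_markers) {
  structure(list(method = method, map = map, train_mean = train_mean,
                 impute = impute, warn_markers = warn_markers),
            class = "marker_encoding")
}

check_fit_inputs <- function(G, y) {
  stopifnot(inherits(G, "geno_matrix"))
  if (!G$oriented) {
    stop("genotypes must be oriented before fitting an encoding; see orient_major_allele()",
         call. = FALSE)
  }
  if (!is.null(y)) {
    stopifnot(inherits(y, "trait_vector"))
    if (!identical(rownames(G$values), names(y))) {
      stop("G and y are not aligned; run validate_aligned() first", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Mean encoded value per marker over the training rows, for missing-value
# imputation at transform time.  A marker with no observed call imputes
# the mean of its three encoded values.
impute_values <- function(map, V) {
  m <- ncol(V)
  out <- numeric(m)
  for (j in seq_len(m)) {
    g <- V[, j]
    obs <- g[!is.na(g)]
    out[j] <- if (length(obs)) mean(map[j, obs + 1L]) else mean(map[j, ])
  }
  names(out) <- colnames(V)
  out
}

#' @rdname encodings
#' @export
fit_ordinal <- function(G, base = c("zero_one_two", "minus_one_zero_one")) {
  base <- match.arg(base)
  check_fit_inputs(G, NULL)
  codes <- if (base == "zero_one_two") c(0, 1, 2) else c(-1, 0, 1)
  m <- ncol(G$values)
  map <- matrix(rep(codes, each = m), nrow = m,
                dimnames = list(colnames(G$values), c("E0", "E1", "E2")))
  new_marker_encoding("ordinal", map, train_mean = NA_real_,
                      impute = impute_values(map, G$values),
                      warn_markers = character())
}

#' @rdname encodings
#' @export
fit_ordinal_flipped <- function(G, y) {
  check_fit_inputs(G, y)
  V <- G$values
  m <- ncol(V)
  map <- matrix(rep(c(0, 1, 2), each = m), nrow = m,
                dimnames = list(colnames(V), c("E0", "E1", "E2")))
  yv <- as.numeric(y)
  for (j in seq_len(m)) {
    if (safe_cor(V[, j], yv) < 0) map[j, ] <- c(2, 1, 0)
  }
  new_marker_encoding("ordinal_flipped", map, train_mean = mean(yv),
                      impute = impute_values(map, V),
                      warn_markers = character())
}

# Per-category training-trait means for one marker; NA where unobserved.
category_means <- function(g, yv) {
  vapply(0:2, function(cat) {
    sel <- !is.na(g) & g == cat
    if (any(sel)) mean(yv[sel]) else NA_real_
  }, numeric(1))
}

fit_trait_encoding <- function(G, y, method) {
  check_fit_inputs(G, y)
  V <- G$values
  yv <- as.numeric(y)
  overall <- mean(yv)
  m <- ncol(V)
  map <- matrix(NA_real_, nrow = m, ncol = 3L,
                dimnames = list(colnames(V), c("E0", "E1", "E2")))
  fallback_used <- logical(m)
  for (j in seq_len(m)) {
    cm <- category_means(V[, j], yv)
    e0 <- cm[1L]; e1 <- cm[2L]; e2 <- cm[3L]
    if (method == "target") {
      fallback_used[j] <- anyNA(cm)
      map[j, ] <- ifelse(is.na(cm), overall, cm)
    } else {
      # hybrids: homozygotes target-encoded, heterozygote synthesised
      fallback_used[j] <- is.na(e0) || is.na(e2)
      if (is.na(e0)) e0 <- overall
      if (is.na(e2)) e2 <- overall
      e1 <- if (method == "hybrid_one") overall else (e0 + e2) / 2
      map[j, ] <- c(e0, e1, e2)
    }
  }
  warn_markers <- colnames(V)[fallback_used]
  if (length(warn_markers)) {
    warning(sprintf("%d marker(s) had unobserved categories; fallback to overall training mean: %s",
                    length(warn_markers),
                    paste(utils::head(warn_markers, 5L), collapse = ", ")),
            call. = FALSE)
  }
  new_marker_encoding(method, map, train_mean = overall,
                      impute = impute_values(map, V),
                      warn_markers = warn_markers)
}

#' @rdname encodings
#' @export
fit_target_based <- function(G, y) fit_trait_encoding(G, y, "target")

#' @rdname encodings
#' @export
fit_hybrid_one <- function(G, y) fit_trait_encoding(G, y, "hybrid_one")

#' @rdname encodings
#' @export
fit_hybrid_two <- function(G, y) fit_trait_encoding(G, y, "hybrid_two")

#' Fit a single-marker encoding by method name
#'
#' Convenience dispatcher used by the cross-validation harness and the
#' command-line interface.
#'
#' @param method one of `"ordinal"`, `"ordinal_flipped"`, `"target"`,
#'   `"hybrid_one"`, `"hybrid_two"`.
#' @param G,y see [encodings].
#' @param ordinal_base passed to [fit_ordinal()].
#' @return A `marker_encoding`.
#' @export
fit_encoding <- function(method, G, y = NULL, ordinal_base = "zero_one_two") {
  method <- match.arg(method, c("ordinal", "ordinal_flipped", "target",
                                "hybrid_one", "hybrid_two"))
  if (method != "ordinal" && is.null(y)) {
    stop(sprintf("encoding '%s' requires a training trait", method), call. = FALSE)
  }
  switch(method,
         ordinal = fit_ordinal(G, base = ordinal_base),
         ordinal_flipped = fit_ordinal_flipped(G, y),
         target = fit_target_based(G, y),
         hybrid_one = fit_hybrid_one(G, y),
         hybrid_two = fit_hybrid_two(G, y))
}

#' Apply a fitted encoding to genotypes
#'
#' Replaces each genotype category by its fitted encoded value.  Missing
#' genotypes are imputed with the marker's mean encoded value over the
#' fit-time training rows, so the output never contains `NA`.  The
#' genotypes must carry the same allele orientation as at fit time.
#'
#' @param model a fitted `marker_encoding`.
#' @param G a [geno_matrix()] whose markers are all present in the model.
#' @return A numeric samples x markers matrix.
#' @examples
#' G <- geno_matrix(matrix(c(0, 0, 1, 1, 2, 2), ncol = 1), oriented = TRUE)
#' y <- trait_vector(stats::setNames(c(1, 2, 3, 5, 8, 10), rownames(G$values)))
#' enc <- fit_hybrid_two(G, y)
#' Gnew <- geno_matrix(matrix(c(2, 1, 0), ncol = 1), oriented = TRUE)
#' encode_genotypes(enc, Gnew)[, 1]   # 9.00 5.25 1.50
#' @export
encode_genotypes <- function(model, G) {
  stopifnot(inherits(model, "marker_encoding"), inherits(G, "geno_matrix"))
  markers <- colnames(G$values)
  missing_m <- setdiff(markers, rownames(model$map))
  if (length(missing_m)) {
    stop(sprintf("markers absent from encoding model: %s",
                 paste(utils::head(missing_m, 5L), collapse = ", ")),
         call. = FALSE)
  }
  V <- G$values
  X <- matrix(NA_real_, nrow = nrow(V), ncol = ncol(V),
              dimnames = dimnames(V))
  map <- model$map[markers, , drop = FALSE]
  imp <- model$impute[markers]
  for (j in seq_along(markers)) {
    g <- V[, j]
    x <- map[j, g + 1L]      # NA genotype indexes to NA
    x[is.na(g)] <- imp[j]
    X[, j] <- x
  }
  X
}

#' @export
print.marker_encoding <- function(x, ...) {
  cat(sprintf("<marker_encoding> method = %s, %d markers\n",
              x$method, nrow(x$map)))
  invisible(x)
}
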