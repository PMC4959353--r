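#' Select marker pairs for epistasis features
#'
#' Pairwise interaction terms grow quadratically in the marker count, so
#' three selection strategies are offered: every unordered pair (guarded
#' by a cap), an explicit user list, or all pairs among the `t` markers
#' most correlated (in absolute value) with the training trait.  Pairs
#' are unordered, deduplicated, and stored with the first marker earlier
#' in marker order.
#'
#' @param Xenc numeric samples x markers matrix (any fitted encoding's
#'   output) with marker ids as column names; training rows only.
#' @param y a [trait_vector()] aligned with `Xenc` (required for
#'   `top_t_by_correlation`).
#' @param strategy one of `"all_pairs"`, `"explicit_list"`,
#'   `"top_t_by_correlation"`.
#' @param t number of markers to keep under `top_t_by_correlation`
#'   (default 50); ties in absolute correlation break by marker order.
#' @param pairs for `explicit_list`: a two-column matrix or data frame of
#'   marker ids.
#' @param all_pairs_cap refuse `all_pairs` above this marker count.
#' @return A data frame with character columns `marker_i`, `marker_j`.
#' @export
select_pairs <- function(Xenc, y = NULL,
                         strategy = c("all_pairs", "explicit_list",
                                      "top_t_by_correlation"),
                         t = 50L, pairs = NULL, all_pairs_cap = 200L) {
  strategy <- match.arg(strategy)
  markers <- colnames(Xenc)
  if (is.null(markers)) stop("Xenc must have marker ids as column names", call. = FALSE)
  canonical <- function(df) {
    a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
    unknown <- setdiff(c(a, b), markers)
    if (length(unknown)) {
      stop(sprintf("unknown markers in pair list: %s",
                   paste(utils::head(unknown, 5L), collapse = ", ")), call. = FALSE)
    }
    if (any(a == b)) stop("self-pairs (i, i) are not allowed", call. = FALSE)
    ia <- match(a, markers); ib <- match(b, markers)
    lo <- pmin(ia, ib); hi <- pmax(ia, ib)
    keep <- !duplicated(paste(lo, hi))
    out <- data.frame(marker_i = markers[lo[keep]], marker_j = markers[hi[keep]],
                      stringsAsFactors = FALSE)
    out[order(match(out$marker_i, markers), match(out$marker_j, markers)), ,
        drop = FALSE]
  }
  all_pairs_of <- function(ids) {
    idx <- utils::combn(seq_along(ids), 2L)
    data.frame(marker_i = ids[idx[1L, ]], marker_j = ids[idx[2L, ]],
               stringsAsFactors = FALSE)
  }
  switch(strategy,
    all_pairs = {
      if (length(markers) > all_pairs_cap) {
        stop(sprintf("all_pairs with %d markers exceeds the cap (%d); use top_t_by_correlation or an explicit list",
                     length(markers), all_pairs_cap), call. = FALSE)
      }
      if (length(markers) < 2L) stop("need at least 2 markers", call. = FALSE)
      all_pairs_of(markers)
    },
    explicit_list = {
      if (is.null(pairs)) stop("explicit_list requires 'pairs'", call. = FALSE)
      canonical(as.data.frame(pairs))
    },
    top_t_by_correlation = {
      if (is.null(y)) stop("top_t_by_correlation requires the training trait", call. = FALSE)
      t <- as.integer(t)
      if (t < 2L) stop("t must be at least 2", call. = FALSE)
      if (t > length(markers)) {
        stop(sprintf("t = %d exceeds the marker count (%d)", t, length(markers)),
             call. = FALSE)
      }
      yv <- as.numeric(y)
      ac <- abs(apply(Xenc, 2L, safe_cor, y = yv))
      # stable order: ties resolve to earlier markers
      top <- markers[order(-ac, seq_along(ac))[seq_len(t)]]
      all_pairs_of(markers[sort(match(top, markers))])
    })
}

#' Product interaction features
#'
#' The classical pairwise-epistasis feature: for each selected pair
#' (i, j) the elementwise product of the two encoded marker columns is
#' appended to the design.
#'
#' @param Xenc numeric samples x markers matrix from a fitted encoding.
#' @param pairs data frame from [select_pairs()].
#' @return A numeric samples x pairs matrix with columns named
#'   `"<i>:<j>"`.
#' @examples
#' X <- cbind(a = c(0, 1, 2), b = c(2, 1, 0))
#' product_features(X, data.frame(marker_i = "a", marker_j = "b"))
#' @export
product_features <- function(Xenc, pairs) {
  stopifnot(is.matrix(Xenc), nrow(pairs) >= 1L)
  out <- matrix(NA_real_, nrow = nrow(Xenc), ncol = nrow(pairs),
                dimnames = list(rownames(Xenc),
                                paste(pairs$marker_i, pairs$marker_j, sep = ":")))
  for (p in seq_len(nrow(pairs))) {
    out[, p] <- Xenc[, pairs$marker_i[p]] * Xenc[, pairs$marker_j[p]]
  }
  out
}

#' Hybrid 3x3 grid encodings for marker pairs
#'
#' @description
#' For a pair of markers (i, j) the nine genotype combinations form a
#' 3x3 grid.  Both hybrid grids encode the four corner cells — the
#' double-homozygote combinations (a, b) with a, b in \{0, 2\} — as the
#' mean training trait of the samples falling in that cell.  They differ
#' on the remaining cells:
#'
#' * **hybrid_one**: an edge cell such as (1, 0) pools all samples with
#'   category 0 at marker j regardless of marker i (the marginal mean),
#'   and the center (1, 1) is the overall training-trait mean — the
#'   single-marker Hybrid One rule applied with the other marker's
#'   category held fixed.
#' * **hybrid_two**: an edge cell is the arithmetic mean of its two
#'   adjacent corners (e.g. `E(1,0) = (E(0,0) + E(2,0)) / 2`) and the
#'   center is the mean of the four edge values, mirroring the
#'   single-marker midpoint rule.
#'
#' A cell with no training samples falls back to the overall training
#' mean; for hybrid_two the fallback applies to corners before edges and
#' center are derived, so those cells always lie between their adjacent
#' corners.
#'
#' @param G a [geno_matrix()], oriented, training rows.
#' @param y a [trait_vector()] aligned with `G`.
#' @param pairs data frame from [select_pairs()].
#' @return An object of class `pair_grid_encoding` holding one 3x3 grid
#'   per pair (rows index the first marker's category, columns the
#'   second's) plus the fallback value.
#' @examples
#' # nine samples covering each cell once, traits 1..9 in row-major order
#' g <- expand.grid(a = 0:2, b = 0:2)[, c("a", "b")]
#' G <- geno_matrix(cbind(mA = g$a, mB = g$b), oriented = TRUE)
#' y <- trait_vector(stats::setNames(c(1, 4, 7, 2, 5, 8, 3, 6, 9),
#'                                   rownames(G$values)))
#' fit_pair_grid_hybrid_one(G, y,
#'   data.frame(marker_i = "mA", marker_j = "mB"))$grids[[1]]
#' @name pair_grids
NULL

fit_pair_grid <- function(G, y, pairs, method) {
  check_fit_inputs(G, y)
  stopifnot(nrow(pairs) >= 1L)
  V <- G$values
  yv <- as.numeric(y)
  overall <- mean(yv)
  grids <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    gi <- V[, pairs$marker_i[p]]
    gj <- V[, pairs$marker_j[p]]
    cell_mean <- function(a, b) {
      sel <- !is.na(gi) & !is.na(gj) & gi == a & gj == b
      if (any(sel)) mean(yv[sel]) else NA_real_
    }
    grid <- matrix(NA_real_, 3L, 3L, dimnames = list(0:2, 0:2))
    for (a in c(0L, 2L)) for (b in c(0L, 2L)) {
      v <- cell_mean(a, b)
      grid[a + 1L, b + 1L] <- if (is.na(v)) overall else v
    }
    if (method == "hybrid_one") {
      marg_i <- function(a) {           # fix marker i's category, pool j
        sel <- !is.na(gi) & !is.na(gj) & gi == a
        if (any(sel)) mean(yv[sel]) else overall
      }
      marg_j <- function(b) {
        sel <- !is.na(gi) & !is.na(gj) & gj == b
        if (any(sel)) mean(yv[sel]) else overall
      }
      grid["1", "0"] <- marg_j(0L)
      grid["1", "2"] <- marg_j(2L)
      grid["0", "1"] <- marg_i(0L)
      grid["2", "1"] <- marg_i(2L)
      grid["1", "1"] <- overall
    } else {                            # hybrid_two: averages of corners
      grid["1", "0"] <- (grid["0", "0"] + grid["2", "0"]) / 2
      grid["1", "2"] <- (grid["0", "2"] + grid["2", "2"]) / 2
      grid["0", "1"] <- (grid["0", "0"] + grid["0", "2"]) / 2
      grid["2", "1"] <- (grid["2", "0"] + grid["2", "2"]) / 2
      grid["1", "1"] <- (grid["1", "0"] + grid["1", "2"] +
                         grid["0", "1"] + grid["2", "1"]) / 4
    }
    grids[[p]] <- grid
  }
  structure(list(method = method,
                 pairs = data.frame(marker_i = as.character(pairs$marker_i),
                                    marker_j = as.character(pairs$marker_j),
                                    stringsAsFactors = FALSE),
                 grids = grids, fallback = overall),
            class = "pair_grid_encoding")
}

#' @rdname pair_grids
#' @export
fit_pair_grid_hybrid_one <- function(G, y, pairs) fit_pair_grid(G, y, pairs, "hybrid_one")

#' @rdname pair_grids
#' @export
fit_pair_grid_hybrid_two <- function(G, y, pairs) fit_pair_grid(G, y, pairs, "hybrid_two")

#' Apply fitted pair grids to genotypes
#'
#' Looks up each sample's (category_i, category_j) cell in the fitted
#' grid of every pair.  A missing genotype at either marker yields the
#' pair's fallback value (the fit-time overall training mean).
#'
#' @param model a `pair_grid_encoding`.
#' @param G a [geno_matrix()] carrying the fit-time orientation.
#' @return A numeric samples x pairs matrix with columns `"<i>:<j>"`.
#' @export
transform_pairs <- function(model, G) {
  stopifnot(inherits(model, "pair_grid_encoding"), inherits(G, "geno_matrix"))
  need <- unique(c(model$pairs$marker_i, model$pairs$marker_j))
  missing_m <- setdiff(need, colnames(G$values))
  if (length(missing_m)) {
    stop(sprintf("pair grid references markers absent from genotypes: %s",
                 paste(utils::head(missing_m, 5L), collapse = ", ")), call. = FALSE)
  }
  V <- G$values
  np <- nrow(model$pairs)
  out <- matrix(NA_real_, nrow = nrow(V), ncol = np,
                dimnames = list(rownames(V),
                                paste(model$pairs$marker_i, model$pairs$marker_j,
                                      sep = ":")))
  for (p in seq_len(np)) {
    gi <- V[, model$pairs$marker_i[p]]
    gj <- V[, model$pairs$marker_j[p]]
    grid <- model$grids[[p]]
    x <- grid[cbind(gi + 1L, gj + 1L)]
    x[is.na(gi) | is.na(gj)] <- model$fallback
    out[, p] <- x
  }
  out
}

#' @export
print.pair_grid_encoding <- function(x, ...) {
  cat(sprintf("<pair_grid_encoding> method = %s, %d pairs\n",
              x$method, nrow(x$pairs)))
  invisible(x)
}
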