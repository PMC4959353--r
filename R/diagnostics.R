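#' Mean absolute correlation of the top-k markers
#'
#' Ranks encoded marker columns by the absolute value of their Pearson
#' correlation with the trait (the sign is arbitrary under flipping and
#' trait-aware encodings) and returns the mean absolute correlation of
#' the k best.  A column with zero variance has correlation 0; ties in
#' the ranking break by marker order.  Higher values indicate features
#' that individually track the trait more closely — the flexibility that
#' per-marker encodings buy.
#'
#' @param Xenc numeric samples x markers matrix from a fitted encoding.
#' @param y a [trait_vector()] (or plain numeric) aligned with `Xenc`.
#' @param k number of markers to keep (default 100).
#' @return The mean of the k largest absolute correlations.
#' @export
topk_abs_correlation <- function(Xenc, y, k = 100L) {
  Xenc <- as.matrix(Xenc)
  yv <- as.numeric(y)
  stopifnot(nrow(Xenc) == length(yv))
  k <- as.integer(k)
  if (k < 1L || k > ncol(Xenc)) {
    stop(sprintf("k = %d must be between 1 and the marker count (%d)",
                 k, ncol(Xenc)), call. = FALSE)
  }
  ac <- abs(apply(Xenc, 2L, safe_cor, y = yv))
  mean(ac[order(-ac, seq_along(ac))[seq_len(k)]])
}

#' Discretize a trait into low / mid / high groups
#'
#' Computes the z-score of each trait value using the population
#' (divide-by-n) standard deviation and thresholds it at one standard
#' deviation: -1 for z < -1, 1 for z > 1, 0 otherwise.
#'
#' @param y a [trait_vector()] or numeric vector, non-constant.
#' @return Integer vector in \{-1, 0, 1\}, named like `y`.
#' @examples
#' discretize_trait(c(0, 0, 0, 10))   # 0 0 0 1
#' @export
discretize_trait <- function(y) {
  yv <- as.numeric(y)
  mu <- mean(yv)
  delta <- sqrt(mean((yv - mu)^2))
  if (delta == 0) stop("trait is constant; discretization is undefined",
                       call. = FALSE)
  z <- (yv - mu) / delta
  out <- integer(length(z))
  out[z < -1] <- -1L
  out[z > 1] <- 1L
  names(out) <- names(y)
  out
}

#' Mean within-group pairwise sample distance in standardized marker space
#'
#' @description
#' The category-order diagnostic: samples are grouped by their
#' discretized trait value (see [discretize_trait()]); each encoded
#' marker column is standardized to z-scores using population
#' (divide-by-n) moments, with zero-variance columns contributing 0; and
#' all pairwise Euclidean distances between samples sharing a group are
#' pooled across the three groups and averaged.  Encodings that scatter
#' same-trait samples across feature space (as target encoding can,
#' by breaking category order) score higher; lower is better.
#'
#' Standardizing per marker makes the measure invariant to per-marker
#' affine rescaling of the encoding, which is what allows encodings on
#' different scales to be compared.
#'
#' @param Xenc numeric samples x markers matrix from a fitted encoding.
#' @param y a [trait_vector()] (or plain numeric) aligned with `Xenc`.
#' @return Mean pairwise within-group Euclidean distance.
#' @export
within_group_distance <- function(Xenc, y) {
  Xenc <- as.matrix(Xenc)
  yv <- as.numeric(y)
  stopifnot(nrow(Xenc) == length(yv))
  groups <- discretize_trait(yv)
  mu <- colMeans(Xenc)
  v <- colMeans(sweep(Xenc, 2L, mu)^2)
  Z <- sweep(Xenc, 2L, mu)
  pos <- v > 0
  Z[, pos] <- sweep(Z[, pos, drop = FALSE], 2L, sqrt(v[pos]), "/")
  Z[, !pos] <- 0
  dists <- unlist(lapply(c(-1L, 0L, 1L), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) return(numeric())
    as.numeric(stats::dist(Z[idx, , drop = FALSE]))
  }))
  if (length(dists) == 0L) {
    stop("no discretized trait group has 2 or more samples", call. = FALSE)
  }
  mean(dists)
}
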