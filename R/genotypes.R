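#' Genotype matrix container
#'
#' Stores a samples x markers table of biallelic genotype categories coded
#' 0 (homozygous, major allele), 1 (heterozygous) and 2 (homozygous, minor
#' allele), with `NA` for missing calls.  The `oriented` flag records
#' whether [orient_major_allele()] has been applied, i.e. whether the
#' allele counted by "2" is known to be the minor allele in the reference
#' rows used for orientation.
#'
#' @param values integer matrix (samples in rows, markers in columns) with
#'   entries in \{0, 1, 2\} or `NA`.
#' @param sample_ids,marker_ids optional character vectors of unique ids;
#'   default to the dimnames of `values` or generated ids.
#' @param oriented logical; set `TRUE` only for data already oriented to
#'   the major allele.
#' @return An object of class `geno_matrix`: a list with elements `values`
#'   (integer matrix with dimnames) and `oriented`.
#' @examples
#' G <- geno_matrix(rbind(c(0, 1), c(2, 1), c(1, 0)))
#' dim(G$values)
#' @export
geno_matrix <- function(values, sample_ids = NULL, marker_ids = NULL,
                        oriented = FALSE) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("genotype matrix is empty", call. = FALSE)
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% c(0L, 1L, 2L))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype value at row %d, column %d: must be 0, 1, 2 or NA",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  sample_ids <- sample_ids %||% rownames(values) %||%
    sprintf("sample_%d", seq_len(nrow(values)))
  marker_ids <- marker_ids %||% colnames(values) %||%
    sprintf("marker_%d", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != nrow(values) || length(marker_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids", call. = FALSE)
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(list(values = values, oriented = isTRUE(oriented)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d markers (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$oriented) "oriented to major allele" else "orientation unknown"))
  invisible(x)
}

#' Trait vector container
#'
#' A quantitative trait keyed by sample id, represented as a named numeric
#' vector.  Values must be finite and at least two samples are required.
#'
#' @param values numeric vector of trait values.
#' @param sample_ids optional character vector of unique sample ids;
#'   defaults to `names(values)`.
#' @return A named numeric vector of class `trait_vector`.
#' @examples
#' y <- trait_vector(c(s1 = 1.2, s2 = 0.7))
#' @export
trait_vector <- function(values, sample_ids = NULL) {
  sample_ids <- sample_ids %||% names(values)
  values <- as.numeric(values)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(values) || is.null(sample_ids) ||
      any(!nzchar(sample_ids))) {
    stop("every trait value needs a sample id", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in trait", call. = FALSE)
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(values))) stop("trait values must be finite", call. = FALSE)
  names(values) <- sample_ids
  class(values) <- "trait_vector"
  values
}

#' Align a genotype matrix and a trait vector on shared samples
#'
#' Restricts both objects to the intersection of their sample ids, in the
#' canonical order of first appearance in the genotype matrix, and reports
#' which ids were dropped from either side.
#'
#' @param G a [geno_matrix()].
#' @param y a [trait_vector()].
#' @return A list with elements `G`, `y` (aligned), `dropped_genotypes`
#'   and `dropped_traits` (character vectors of discarded ids).
#' @examples
#' G <- geno_matrix(rbind(s1 = c(0, 1), s2 = c(2, 0), s3 = c(1, 1)))
#' y <- trait_vector(c(s2 = 1, s3 = 2, s4 = 3))
#' a <- validate_aligned(G, y)
#' rownames(a$G$values)   # "s2" "s3"
#' @export
validate_aligned <- function(G, y) {
  stopifnot(inherits(G, "geno_matrix"), inherits(y, "trait_vector"))
  gids <- rownames(G$values)
  tids <- names(y)
  keep <- gids[gids %in% tids]
  if (length(keep) == 0L) {
    stop("no samples shared between genotypes and trait", call. = FALSE)
  }
  ynew <- unclass(y)[keep]
  class(ynew) <- "trait_vector"
  Gnew <- G
  Gnew$values <- G$values[keep, , drop = FALSE]
  list(G = Gnew, y = ynew,
       dropped_genotypes = setdiff(gids, keep),
       dropped_traits = setdiff(tids, keep))
}

#' Orient genotype categories to the major allele
#'
#' For each marker, the allele counted by the input coding (the one whose
#' dosage the 0/1/2 value reports) should be the minor allele, so that 0
#' denotes the major-allele homozygote.  This function estimates the
#' counted-allele frequency among `reference_rows` only (in cross
#' validation, the training fold) and swaps categories 0 and 2 across
#' *all* rows wherever that frequency exceeds 0.5.  A frequency of
#' exactly 0.5 keeps the input orientation; a marker with no observed
#' genotype among the reference rows is left unswapped with a warning.
#'
#' The decision depends only on the reference rows, which makes the
#' operation safe to use per training fold without test-set leakage, and
#' it is idempotent for a fixed reference set.
#'
#' @param G a [geno_matrix()].
#' @param reference_rows character vector of sample ids (or integer row
#'   indices) used to estimate allele frequencies; defaults to all rows.
#' @return The oriented `geno_matrix` (`oriented = TRUE`), with an
#'   attribute `swapped`: a named logical vector of per-marker decisions.
#' @examples
#' G <- geno_matrix(matrix(c(2, 2, 2, 1, 0), ncol = 1))
#' orient_major_allele(G)$values[, 1]   # 0 0 0 1 2
#' @export
orient_major_allele <- function(G, reference_rows = rownames(G$values)) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is.numeric(reference_rows)) reference_rows <- rownames(G$values)[reference_rows]
  reference_rows <- as.character(reference_rows)
  if (length(reference_rows) == 0L) stop("reference_rows is empty", call. = FALSE)
  if (!all(reference_rows %in% rownames(G$values))) {
    stop("reference_rows contains unknown sample ids", call. = FALSE)
  }
  ref <- G$values[reference_rows, , drop = FALSE]
  n_obs <- colSums(!is.na(ref))
  dosage <- colSums(ref, na.rm = TRUE)
  freq <- ifelse(n_obs > 0, dosage / (2 * n_obs), NA_real_)
  swap <- !is.na(freq) & freq > 0.5
  if (any(n_obs == 0)) {
    warning(sprintf("markers with no observed genotypes in reference rows left unswapped: %s",
                    paste(colnames(ref)[n_obs == 0], collapse = ", ")),
            call. = FALSE)
  }
  out <- G
  if (any(swap)) {
    out$values[, swap] <- 2L - out$values[, swap, drop = FALSE]
  }
  out$oriented <- TRUE
  names(swap) <- colnames(G$values)
  attr(out, "swapped") <- swap
  out
}
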