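#' Read genotypes from delimited text
#'
#' Two dialects are supported.  `matrix_tsv`: a header row of marker
#' ids, first column the sample id, remaining cells in \{0, 1, 2\} or
#' the missing token.  `plink_raw`: the PLINK `--recode A` additive
#' format — whitespace-delimited with leading FID IID PAT MAT SEX
#' PHENOTYPE columns, then one 0/1/2/NA dosage column per marker, whose
#' names carry a counted-allele suffix (e.g. `rs42_A`) that is stripped.
#'
#' @param path file path.
#' @param dialect `"matrix_tsv"` (default) or `"plink_raw"`.
#' @param missing_token string standing for a missing call (default
#'   `"NA"`).
#' @param orientation `"as_is"` (default; run [orient_major_allele()]
#'   downstream) or `"counted_allele"` to assert that the file already
#'   counts the minor allele, which marks the matrix as oriented.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("matrix_tsv", "plink_raw"),
                           missing_token = "NA",
                           orientation = c("as_is", "counted_allele")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "matrix_tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", check.names = FALSE,
                             comment.char = "")
    if (ncol(tab) < 2L) stop("matrix_tsv needs a sample-id column and at least one marker",
                             call. = FALSE)
    sample_ids <- tab[[1L]]
    marker_ids <- colnames(tab)[-1L]
    raw <- as.matrix(tab[, -1L, drop = FALSE])
  } else {
    tab <- utils::read.table(path, header = TRUE, colClasses = "character",
                             check.names = FALSE, comment.char = "")
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) <= length(lead) ||
        !identical(toupper(colnames(tab)[seq_along(lead)]), lead)) {
      stop("malformed PLINK RAW header: expected FID IID PAT MAT SEX PHENOTYPE then markers",
           call. = FALSE)
    }
    sample_ids <- tab[["IID"]]
    marker_ids <- sub("_[ACGT0-9]+$", "", colnames(tab)[-seq_along(lead)])
    raw <- as.matrix(tab[, -seq_along(lead), drop = FALSE])
  }
  vals <- matrix(NA_integer_, nrow(raw), ncol(raw))
  # read.table may have turned the literal string "NA" into NA already
  is_missing <- is.na(raw) | raw == missing_token | raw == "NA"
  cell <- suppressWarnings(as.integer(raw))
  bad <- !is_missing & (is.na(cell) | !(cell %in% c(0L, 1L, 2L)) |
                          raw != as.character(cell))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype '%s' at data row %d, marker '%s' in %s",
                 raw[idx[1L], idx[2L]], idx[1L], marker_ids[idx[2L]], path),
         call. = FALSE)
  }
  vals[!is_missing] <- cell[!is_missing]
  geno_matrix(vals, sample_ids = sample_ids, marker_ids = marker_ids,
              oriented = orientation == "counted_allele")
}

#' Write genotypes as matrix_tsv
#'
#' @param G a [geno_matrix()].
#' @param path output path.
#' @param missing_token string written for missing calls.
#' @export
write_genotypes <- function(G, path, missing_token = "NA") {
  stopifnot(inherits(G, "geno_matrix"))
  out <- matrix(as.character(G$values), nrow(G$values))
  out[is.na(G$values)] <- missing_token
  df <- data.frame(sample_id = rownames(G$values), out,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(G$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait file
#'
#' Two-column delimited text: sample id, trait value.  A header line is
#' detected by a non-numeric second field.
#'
#' @param path file path.
#' @return A [trait_vector()].
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) != 2L) stop("trait file must have exactly two columns", call. = FALSE)
  if (suppressWarnings(is.na(as.numeric(tab[1L, 2L])))) tab <- tab[-1L, , drop = FALSE]
  vals <- suppressWarnings(as.numeric(tab[[2L]]))
  bad <- is.na(vals) | !is.finite(vals)
  if (any(bad)) {
    stop(sprintf("non-finite or non-numeric trait value '%s' for sample '%s'",
                 tab[[2L]][bad][1L], tab[[1L]][bad][1L]), call. = FALSE)
  }
  trait_vector(vals, sample_ids = tab[[1L]])
}

#' @rdname read_traits
#' @param y a [trait_vector()].
#' @param path output path.
#' @export
write_traits <- function(y, path) {
  stopifnot(inherits(y, "trait_vector"))
  df <- data.frame(sample_id = names(y), value = fmt_num(as.numeric(y)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted single-marker encoding
#'
#' Writes a tab-delimited table (marker_id, E0, E1, E2, impute) preceded
#' by header comments naming the method and the training mean.  Values
#' round-trip at full double precision.
#'
#' @param model a `marker_encoding`.
#' @param path output path.
#' @export
write_encoding <- function(model, path) {
  stopifnot(inherits(model, "marker_encoding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", model$method),
               sprintf("# train_mean: %s", fmt_num(model$train_mean))), con)
  df <- data.frame(marker_id = rownames(model$map),
                   E0 = fmt_num(model$map[, "E0"]),
                   E1 = fmt_num(model$map[, "E1"]),
                   E2 = fmt_num(model$map[, "E2"]),
                   impute = fmt_num(model$impute))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_encoding
#' @export
read_encoding <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  method <- sub("^# method: ", "", grep("^# method:", hdr, value = TRUE))
  train_mean <- as.numeric(sub("^# train_mean: ", "",
                               grep("^# train_mean:", hdr, value = TRUE)))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", colClasses = c("character", rep("numeric", 4L)))
  map <- as.matrix(tab[, c("E0", "E1", "E2")])
  rownames(map) <- tab$marker_id
  new_marker_encoding(method, map, train_mean,
                      impute = stats::setNames(tab$impute, tab$marker_id),
                      warn_markers = character())
}

#' Serialize fitted pair grids
#'
#' One row per pair: marker_i, marker_j, then the nine cell values in
#' row-major order (first marker's category outermost).  Header comments
#' carry the method and fallback value.  Exact round-trip.
#'
#' @param model a `pair_grid_encoding`.
#' @param path output path.
#' @export
write_pair_grids <- function(model, path) {
  stopifnot(inherits(model, "pair_grid_encoding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", model$method),
               sprintf("# fallback: %s", fmt_num(model$fallback))), con)
  cells <- t(vapply(model$grids, function(g) as.numeric(t(g)), numeric(9)))
  cn <- as.vector(t(outer(0:2, 0:2, function(a, b) sprintf("E%d%d", a, b))))
  df <- data.frame(model$pairs,
                   matrix(fmt_num(cells), nrow = nrow(cells),
                          dimnames = list(NULL, cn)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_grids
#' @export
read_pair_grids <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  method <- sub("^# method: ", "", grep("^# method:", hdr, value = TRUE))
  fallback <- as.numeric(sub("^# fallback: ", "",
                             grep("^# fallback:", hdr, value = TRUE)))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t",
                           colClasses = c("character", "character",
                                          rep("numeric", 9L)))
  grids <- lapply(seq_len(nrow(tab)), function(p) {
    matrix(as.numeric(tab[p, 3:11]), 3L, 3L, byrow = TRUE,
           dimnames = list(0:2, 0:2))
  })
  structure(list(method = method,
                 pairs = data.frame(marker_i = tab$marker_i,
                                    marker_j = tab$marker_j,
                                    stringsAsFactors = FALSE),
                 grids = grids, fallback = fallback),
            class = "pair_grid_encoding")
}

#' Serialize a fitted rrBLUP model
#'
#' A small header block (beta0, lambda, variance components) followed by
#' a (feature_id, effect) table; exact round-trip.
#'
#' @param model an `rrblup` model.
#' @param path output path.
#' @export
write_rrblup <- function(model, path) {
  stopifnot(inherits(model, "rrblup"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# beta0: %s", fmt_num(model$beta0)),
               sprintf("# lambda: %s", fmt_num(model$lambda)),
               sprintf("# sigma_beta_sq: %s", fmt_num(model$sigma_beta_sq)),
               sprintf("# sigma_e_sq: %s", fmt_num(model$sigma_e_sq))), con)
  df <- data.frame(feature_id = model$feature_ids %||%
                     sprintf("f%d", seq_along(model$beta)),
                   effect = fmt_num(model$beta))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rrblup
#' @export
read_rrblup <- function(path) {
  lines <- readLines(path)
  grab <- function(key) as.numeric(sub(sprintf("^# %s: ", key), "",
                                       grep(sprintf("^# %s:", key), lines,
                                            value = TRUE)))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", colClasses = c("character", "numeric"))
  structure(list(beta0 = grab("beta0"),
                 beta = stats::setNames(tab$effect, tab$feature_id),
                 lambda = grab("lambda"),
                 sigma_beta_sq = grab("sigma_beta_sq"),
                 sigma_e_sq = grab("sigma_e_sq"),
                 feature_ids = tab$feature_id, boundary = FALSE),
            class = "rrblup")
}

#' Write a cross-validation report
#'
#' Long-format delimited table (method, predictor, fold, r2) with one
#' summary row per method (`fold = "mean"`).
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  long <- report$results
  long$fold <- as.character(long$fold)
  long$r2 <- fmt_num(long$r2)
  sm <- data.frame(method = report$summary$method,
                   predictor = report$summary$predictor,
                   fold = "mean", r2 = fmt_num(report$summary$mean_r2))
  utils::write.table(rbind(long, sm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
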