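#' Simulation configuration
#'
#' @description
#' Parameters of the synthetic genotype/phenotype generator.  Genotypes
#' are independent biallelic markers in Hardy-Weinberg proportions; the
#' trait is built from per-category genotypic values at causal markers
#' (not from dosage coefficients), which lets one architecture span the
#' purely additive regime — where the ordinal encoding is already
#' optimal — to regimes with dominance and heterogeneous effect signs,
#' where per-marker trait-aware encodings have an advantage.
#'
#' The defaults describe the benchmark architecture used throughout the
#' package's own evaluations: 300 samples, 200 markers of which 60 are
#' causal, half of the causal markers dominant, randomized effect signs,
#' and heritability 0.6.
#'
#' @param n sample count.
#' @param m marker count.
#' @param maf_range interval within (0, 0.5] from which each marker's
#'   minor-allele frequency is drawn uniformly.
#' @param n_causal number of causal markers (`<= m`).
#' @param additive_scale standard deviation of per-marker additive
#'   effects (half the homozygote contrast).
#' @param dominance_degree fraction in \[0, 1\] of causal markers whose
#'   heterozygote genotypic value deviates from the additive midpoint.
#' @param dominance_scale standard deviation of that heterozygote
#'   deviation, as a multiple of `additive_scale`.
#' @param sign_mixing logical; when `FALSE` all additive effects are
#'   positive (the trait increases with minor-allele dosage at every
#'   causal marker), when `TRUE` signs are random.
#' @param n_epistatic_pairs number of causal-marker pairs given
#'   cell-specific interaction values.
#' @param epistasis_scale standard deviation of the per-cell interaction
#'   values.
#' @param h2 target narrow-sense-plus-interaction heritability in
#'   (0, 1]: residual noise is scaled so that the genetic share of trait
#'   variance hits this value.
#' @param seed integer seed; all randomness is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 300L, m = 200L, maf_range = c(0.05, 0.5),
                       n_causal = 60L, additive_scale = 1,
                       dominance_degree = 0.5, dominance_scale = 1,
                       sign_mixing = TRUE, n_epistatic_pairs = 0L,
                       epistasis_scale = 1, h2 = 0.6, seed = 1L) {
  stopifnot(n >= 2, m >= 1, n_causal >= 1, n_causal <= m,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            dominance_degree >= 0, dominance_degree <= 1,
            h2 > 0, h2 <= 1, additive_scale > 0,
            n_epistatic_pairs >= 0)
  structure(list(n = as.integer(n), m = as.integer(m), maf_range = maf_range,
                 n_causal = as.integer(n_causal),
                 additive_scale = additive_scale,
                 dominance_degree = dominance_degree,
                 dominance_scale = dominance_scale,
                 sign_mixing = isTRUE(sign_mixing),
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 epistasis_scale = epistasis_scale,
                 h2 = h2, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes under Hardy-Weinberg proportions
#'
#' Each marker draws a minor-allele frequency q uniformly from
#' `cfg$maf_range` and samples categories (0, 1, 2) independently with
#' probabilities ((1-q)^2, 2q(1-q), q^2).  Markers are unlinked.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] (`oriented = FALSE`: with a random draw the
#'   realized minor allele can differ from the generating one, which is
#'   exactly what [orient_major_allele()] resolves downstream).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    q <- stats::runif(cfg$m, cfg$maf_range[1], cfg$maf_range[2])
    V <- vapply(seq_len(cfg$m), function(j) {
      sample(0:2, cfg$n, replace = TRUE,
             prob = c((1 - q[j])^2, 2 * q[j] * (1 - q[j]), q[j]^2))
    }, integer(cfg$n))
    geno_matrix(V,
                sample_ids = sprintf("s%04d", seq_len(cfg$n)),
                marker_ids = sprintf("m%04d", seq_len(cfg$m)))
  })
}

#' Simulate a quantitative trait over simulated genotypes
#'
#' @description
#' A random subset of `n_causal` markers receives per-category genotypic
#' values `(v0, v1, v2) = (-a, d, +a)` with `a` drawn half-normal (or
#' signed-normal under `sign_mixing`) at scale `additive_scale`; a
#' fraction `dominance_degree` of the causal markers gets a heterozygote
#' deviation `d ~ N(0, (dominance_scale * additive_scale)^2)`, the rest
#' have `d = 0` (pure additivity).  Optional epistatic pairs of causal
#' markers each contribute a full 3x3 grid of cell values drawn
#' `N(0, epistasis_scale^2)`.  Residual noise is Gaussian with variance
#' chosen so that the genetic share of the (population) trait variance
#' equals `h2`.
#'
#' @param G a [geno_matrix()] produced by [simulate_genotypes()] with
#'   the same `cfg`.
#' @param cfg a [sim_config()].
#' @return A list with `trait` (a [trait_vector()]) and `truth`, a list
#'   of class `sim_truth` recording the causal markers and their
#'   category-value maps, the epistatic pairs and grids, `sigma_e_sq`,
#'   the realized heritability, and the seed.
#' @export
simulate_trait <- function(G, cfg) {
  stopifnot(inherits(G, "geno_matrix"), inherits(cfg, "sim_config"))
  if (nrow(G$values) != cfg$n || ncol(G$values) != cfg$m) {
    stop("genotype dimensions do not match the configuration", call. = FALSE)
  }
  with_seed(cfg$seed + 1L, {
    causal <- sort(sample.int(cfg$m, cfg$n_causal))
    a <- stats::rnorm(cfg$n_causal, 0, cfg$additive_scale)
    if (!cfg$sign_mixing) a <- abs(a)
    n_dom <- round(cfg$dominance_degree * cfg$n_causal)
    dom <- sample.int(cfg$n_causal, n_dom)
    d <- numeric(cfg$n_causal)
    d[dom] <- stats::rnorm(n_dom, 0, cfg$dominance_scale * cfg$additive_scale)
    value_map <- rbind(-a, d, a)           # rows: category 0, 1, 2
    dimnames(value_map) <- list(c("v0", "v1", "v2"),
                                colnames(G$values)[causal])

    Vc <- G$values[, causal, drop = FALSE]
    genetic <- rowSums(vapply(seq_len(cfg$n_causal), function(jj) {
      value_map[Vc[, jj] + 1L, jj]
    }, numeric(cfg$n)))

    pair_df <- NULL
    pair_grids <- list()
    if (cfg$n_epistatic_pairs > 0L) {
      if (cfg$n_causal < 2L) stop("epistatic pairs need at least 2 causal markers",
                                  call. = FALSE)
      npair_max <- choose(cfg$n_causal, 2)
      if (cfg$n_epistatic_pairs > npair_max) {
        stop("more epistatic pairs requested than causal pairs available",
             call. = FALSE)
      }
      combos <- utils::combn(causal, 2L)
      sel <- sample.int(ncol(combos), cfg$n_epistatic_pairs)
      pair_df <- data.frame(marker_i = colnames(G$values)[combos[1L, sel]],
                            marker_j = colnames(G$values)[combos[2L, sel]],
                            stringsAsFactors = FALSE)
      for (p in seq_len(cfg$n_epistatic_pairs)) {
        grid <- matrix(stats::rnorm(9, 0, cfg$epistasis_scale), 3L, 3L,
                       dimnames = list(0:2, 0:2))
        pair_grids[[p]] <- grid
        gi <- G$values[, pair_df$marker_i[p]]
        gj <- G$values[, pair_df$marker_j[p]]
        genetic <- genetic + grid[cbind(gi + 1L, gj + 1L)]
      }
    }

    var_g <- mean((genetic - mean(genetic))^2)
    if (var_g == 0) {
      stop("zero genetic variance: no causal marker is polymorphic", call. = FALSE)
    }
    sigma_e_sq <- var_g * (1 - cfg$h2) / cfg$h2
    e <- if (sigma_e_sq > 0) stats::rnorm(cfg$n, 0, sqrt(sigma_e_sq)) else numeric(cfg$n)
    yv <- genetic + e
    realized_h2 <- var_g / mean((yv - mean(yv))^2)
    trait <- trait_vector(yv, sample_ids = rownames(G$values))
    truth <- structure(list(causal_markers = colnames(G$values)[causal],
                            value_map = value_map,
                            epistatic_pairs = pair_df,
                            pair_grids = pair_grids,
                            genetic_values = stats::setNames(genetic,
                                                             rownames(G$values)),
                            sigma_e_sq = sigma_e_sq,
                            realized_h2 = realized_h2,
                            seed = cfg$seed),
                       class = "sim_truth")
    list(trait = trait, truth = truth)
  })
}
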