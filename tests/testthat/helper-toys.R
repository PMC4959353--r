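# Shared in-code fixtures: the 6-sample single-marker toy and the
# 9-sample pair toy with one sample per genotype-combination cell.

toy_single <- function() {
  G <- geno_matrix(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1,
                          dimnames = list(paste0("s", 1:6), "mk")),
                   oriented = TRUE)
  y <- trait_vector(stats::setNames(c(1, 2, 3, 5, 8, 10), paste0("s", 1:6)))
  list(G = G, y = y)
}

# trait of the sample in cell (a, b) is 3*a + b + 1, i.e. cells read
# 1..9 with marker A's category changing slowest
toy_grid <- function() {
  cells <- expand.grid(b = 0:2, a = 0:2)[, c("a", "b")]
  G <- geno_matrix(cbind(mA = cells$a, mB = cells$b),
                   sample_ids = paste0("s", 1:9), oriented = TRUE)
  y <- trait_vector(stats::setNames(3 * cells$a + cells$b + 1, paste0("s", 1:9)))
  list(G = G, y = y, pairs = data.frame(marker_i = "mA", marker_j = "mB",
                                        stringsAsFactors = FALSE))
}

# random genotype matrix + trait with all categories present per marker
random_dataset <- function(n, m, seed, h2 = 0.6, dominance = 0.5,
                           sign_mixing = TRUE, n_causal = max(1L, m %/% 2L)) {
  cfg <- sim_config(n = n, m = m, n_causal = n_causal, h2 = h2,
                    dominance_degree = dominance, sign_mixing = sign_mixing,
                    seed = seed)
  G <- simulate_genotypes(cfg)
  sim <- simulate_trait(G, cfg)
  list(G = G, y = sim$trait, truth = sim$truth, cfg = cfg)
}
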