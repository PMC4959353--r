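test_that("pair selection covers all strategies and rejects self-pairs", {
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  y <- trait_vector(stats::setNames(X[, 1] + rnorm(10, sd = 0.1), paste0("s", 1:10)))
  expect_equal(nrow(select_pairs(X, strategy = "all_pairs")), 6L)       # C(4,2)
  expect_equal(nrow(select_pairs(X, y, strategy = "top_t_by_correlation",
                                 t = 2)), 1L)
  top <- select_pairs(X, y, strategy = "top_t_by_correlation", t = 2)
  expect_true("m1" %in% c(top$marker_i, top$marker_j))  # m1 drives the trait
  expect_error(select_pairs(X, y, strategy = "top_t_by_correlation", t = 9),
               "exceeds the marker count")
  expect_error(select_pairs(X, strategy = "explicit_list",
                            pairs = data.frame(a = "m1", b = "m1")),
               "self-pairs")
  # unordered dedup with i before j in marker order
  pl <- select_pairs(X, strategy = "explicit_list",
                     pairs = data.frame(a = c("m3", "m1"), b = c("m1", "m3")))
  expect_equal(pl, data.frame(marker_i = "m1", marker_j = "m3",
                              stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  expect_error(select_pairs(X, strategy = "all_pairs", all_pairs_cap = 3),
               "exceeds the cap")
})

test_that("product features are elementwise products of encoded columns", {
  X <- cbind(a = c(0, 1, 2), b = c(2, 1, 0), ones = c(1, 1, 1))
  pf <- product_features(X, data.frame(marker_i = c("a", "a"),
                                       marker_j = c("b", "ones")))
  expect_equal(unname(pf[, "a:b"]), c(0, 1, 0))
  expect_equal(unname(pf[, "a:ones"]), c(0, 1, 2))
})

test_that("pair grids match the enumerated 9-sample toy", {
  toy <- toy_grid()
  g1 <- fit_pair_grid_hybrid_one(toy$G, toy$y, toy$pairs)$grids[[1]]
  expect_equal(g1[cbind(c("0", "0", "2", "2"), c("0", "2", "0", "2"))],
               c(1, 3, 7, 9))                      # corners
  expect_equal(g1["1", "0"], 4)                    # marginal over marker A
  expect_equal(g1["0", "1"], 2)
  expect_equal(g1["2", "1"], 8)
  expect_equal(g1["1", "2"], 6)
  expect_equal(g1["1", "1"], 5)                    # overall mean

  g2 <- fit_pair_grid_hybrid_two(toy$G, toy$y, toy$pairs)$grids[[1]]
  expect_equal(g2["1", "0"], 4)                    # (1 + 7) / 2
  expect_equal(g2["0", "1"], 2)
  expect_equal(g2["2", "1"], 8)
  expect_equal(g2["1", "2"], 6)
  expect_equal(g2["1", "1"], 5)                    # mean of four edges
  # on this additive toy the two grid constructions agree everywhere
  expect_equal(g1, g2)
})

test_that("constant traits and empty cells use the stated fallbacks", {
  toy <- toy_grid()
  yc <- trait_vector(stats::setNames(rep(3, 9), names(toy$y)))
  gc <- fit_pair_grid_hybrid_one(toy$G, yc, toy$pairs)$grids[[1]]
  expect_true(all(gc == 3))

  # remove the (2,2) sample: that corner falls back to the overall mean
  keep <- toy$G$values[, "mA"] != 2L | toy$G$values[, "mB"] != 2L
  G8 <- geno_matrix(toy$G$values[keep, , drop = FALSE], oriented = TRUE)
  y8 <- trait_vector(unclass(toy$y)[keep])
  g8 <- fit_pair_grid_hybrid_one(G8, y8, toy$pairs)$grids[[1]]
  expect_equal(g8["2", "2"], mean(as.numeric(y8)))
})

test_that("transform_pairs looks up cells and handles missing genotypes", {
  toy <- toy_grid()
  model <- fit_pair_grid_hybrid_one(toy$G, toy$y, toy$pairs)
  Gq <- geno_matrix(rbind(t1 = c(mA = 1L, mB = 2L), t2 = c(mA = 0L, mB = 0L),
                          t3 = c(mA = NA, mB = 1L)), oriented = TRUE)
  out <- transform_pairs(model, Gq)
  expect_equal(unname(out[, 1]), c(6, 1, 5))  # cell, corner, fallback
  Gbad <- geno_matrix(rbind(t1 = c(mA = 0L, mX = 0L)), oriented = TRUE)
  expect_error(transform_pairs(model, Gbad), "absent from genotypes")
})

test_that("grids are symmetric under pair order and hybrid-two keeps cell order", {
  dat <- random_dataset(n = 120, m = 12, seed = 13, dominance = 1)
  Go <- orient_major_allele(dat$G)
  markers <- colnames(Go$values)
  fwd <- data.frame(marker_i = markers[1], marker_j = markers[2])
  rev <- data.frame(marker_i = markers[2], marker_j = markers[1])
  for (fitter in list(fit_pair_grid_hybrid_one, fit_pair_grid_hybrid_two)) {
    a <- fitter(Go, dat$y, fwd)
    b <- fitter(Go, dat$y, rev)
    expect_equal(a$grids[[1]], t(b$grids[[1]]), ignore_attr = TRUE)
    expect_equal(transform_pairs(a, Go), transform_pairs(b, Go),
                 ignore_attr = TRUE)
  }

  # hybrid-two order property over many simulated pairs
  n_checked <- 0L
  for (seed in 1:6) {
    d <- random_dataset(n = 100, m = 20, seed = 100 + seed, dominance = 1)
    Gd <- orient_major_allele(d$G)
    pairs <- select_pairs(encode_genotypes(fit_ordinal(Gd), Gd),
                          strategy = "all_pairs")
    gm <- fit_pair_grid_hybrid_two(Gd, d$y, pairs)
    for (g in gm$grids) {
      edges <- c(g["1", "0"], g["1", "2"], g["0", "1"], g["2", "1"])
      lo <- c(min(g["0", "0"], g["2", "0"]), min(g["0", "2"], g["2", "2"]),
              min(g["0", "0"], g["0", "2"]), min(g["2", "0"], g["2", "2"]))
      hi <- c(max(g["0", "0"], g["2", "0"]), max(g["0", "2"], g["2", "2"]),
              max(g["0", "0"], g["0", "2"]), max(g["2", "0"], g["2", "2"]))
      expect_true(all(edges >= lo - 1e-12 & edges <= hi + 1e-12))
      expect_true(g["1", "1"] >= min(edges) - 1e-12 &&
                  g["1", "1"] <= max(edges) + 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 500L)
})

test_that("pair-grid tables round-trip through text exactly", {
  toy <- toy_grid()
  model <- fit_pair_grid_hybrid_two(toy$G, toy$y, toy$pairs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_grids(model, path)
  back <- read_pair_grids(path)
  expect_identical(back$method, model$method)
  expect_equal(back$grids, model$grids, ignore_attr = TRUE)
  expect_identical(back$fallback, model$fallback)
  expect_equal(back$pairs, model$pairs)
})
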