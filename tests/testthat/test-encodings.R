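test_that("ordinal encoding uses fixed labels shared across markers", {
  G <- geno_matrix(cbind(a = c(0L, 1L, 2L), b = c(2L, 0L, 1L)), oriented = TRUE)
  m1 <- fit_ordinal(G)
  expect_equal(unname(m1$map["a", ]), c(0, 1, 2))
  expect_equal(m1$map["a", ], m1$map["b", ])
  m2 <- fit_ordinal(G, base = "minus_one_zero_one")
  expect_equal(unname(m2$map["b", ]), c(-1, 0, 1))
})

test_that("ordinal-flipped swaps 0 and 2 only for negatively correlated markers", {
  ids <- paste0("s", 1:5)
  G <- geno_matrix(cbind(neg = c(0L, 0L, 1L, 2L, 2L), pos = c(0L, 0L, 1L, 2L, 2L),
                         mono = c(1L, 1L, 1L, 1L, 1L)),
                   sample_ids = ids, oriented = TRUE)
  y <- trait_vector(stats::setNames(c(10, 9, 5, 2, 1), ids))
  G$values[, "pos"] <- rev(G$values[, "pos"])
  m <- fit_ordinal_flipped(G, y)
  expect_equal(unname(m$map["neg", ]), c(2, 1, 0))
  expect_equal(unname(m$map["pos", ]), c(0, 1, 2))
  expect_equal(unname(m$map["mono", ]), c(0, 1, 2))  # zero variance: no flip
})

test_that("target and hybrid maps match hand-derived values on the 6-sample toy", {
  toy <- toy_single()
  tgt <- fit_target_based(toy$G, toy$y)
  expect_equal(unname(tgt$map[1, ]), c(1.5, 4.0, 9.0))
  h1 <- fit_hybrid_one(toy$G, toy$y)
  expect_equal(unname(h1$map[1, ]), c(1.5, 29 / 6, 9.0))
  h2 <- fit_hybrid_two(toy$G, toy$y)
  expect_equal(unname(h2$map[1, ]), c(1.5, 5.25, 9.0))
  # homozygote encodings agree across the three trait-aware schemes
  expect_equal(tgt$map[, c("E0", "E2")], h1$map[, c("E0", "E2")])
  expect_equal(tgt$map[, c("E0", "E2")], h2$map[, c("E0", "E2")])
})

test_that("absent categories fall back to the overall training mean", {
  ids <- paste0("s", 1:4)
  G <- geno_matrix(matrix(c(0L, 0L, 1L, 1L), ncol = 1,
                          dimnames = list(ids, "mk")), oriented = TRUE)
  y <- trait_vector(stats::setNames(c(1, 2, 3, 5), ids))
  expect_warning(tgt <- fit_target_based(G, y), "unobserved")
  expect_equal(unname(tgt$map[1, ]), c(1.5, 4.0, 2.75))
  expect_warning(h2 <- fit_hybrid_two(G, y), "unobserved")
  # midpoint taken after fallback substitution of E2
  expect_equal(unname(h2$map[1, ]), c(1.5, (1.5 + 2.75) / 2, 2.75))
})

test_that("constant traits collapse every trait-aware encoding to the constant", {
  ids <- paste0("s", 1:6)
  G <- geno_matrix(matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1,
                          dimnames = list(ids, "mk")), oriented = TRUE)
  y <- trait_vector(stats::setNames(rep(7, 6), ids))
  for (f in list(fit_target_based, fit_hybrid_one, fit_hybrid_two)) {
    expect_equal(unname(f(G, y)$map[1, ]), c(7, 7, 7))
  }
})

test_that("transform looks up fitted values and imputes missing genotypes", {
  toy <- toy_single()
  h2 <- fit_hybrid_two(toy$G, toy$y)
  Gnew <- geno_matrix(matrix(c(2L, 1L, 0L), ncol = 1,
                             dimnames = list(paste0("t", 1:3), "mk")),
                      oriented = TRUE)
  expect_equal(unname(encode_genotypes(h2, Gnew)[, 1]), c(9.0, 5.25, 1.5))

  # ordinal transform is an identity on the categories
  ord <- fit_ordinal(toy$G)
  expect_equal(unname(encode_genotypes(ord, toy$G)[, 1]),
               as.numeric(toy$G$values[, 1]))

  # missing cell imputes the mean encoded training column
  Gmiss <- geno_matrix(matrix(c(NA, 0L), ncol = 1,
                              dimnames = list(c("t1", "t2"), "mk")),
                       oriented = TRUE)
  expect_equal(unname(encode_genotypes(h2, Gmiss)[, 1]),
               c(mean(c(1.5, 1.5, 5.25, 5.25, 9, 9)), 1.5))

  # unknown marker is a transform error
  Gbad <- geno_matrix(matrix(0L, 2, 1, dimnames = list(c("t1", "t2"), "other")),
                      oriented = TRUE)
  expect_error(encode_genotypes(h2, Gbad), "absent from encoding model")
})

test_that("hybrid encodings respect their order guarantees over 1000 markers", {
  cfg <- sim_config(n = 250, m = 1000, maf_range = c(0.2, 0.5), n_causal = 500,
                    dominance_degree = 1, seed = 42)
  G <- simulate_genotypes(cfg)
  y <- simulate_trait(G, cfg)$trait
  dat <- list(G = G, y = y)
  Go <- orient_major_allele(dat$G)
  all_cats <- apply(Go$values, 2, function(g) length(unique(g)) == 3L)
  expect_gt(sum(all_cats), 990)  # high-MAF architecture: all categories seen
  h1 <- suppressWarnings(fit_hybrid_one(Go, dat$y))
  h2 <- suppressWarnings(fit_hybrid_two(Go, dat$y))
  tgt <- suppressWarnings(fit_target_based(Go, dat$y))

  # hybrid two: the midpoint construction is order-preserving, exactly
  map2 <- h2$map[all_cats, , drop = FALSE]
  expect_true(all(map2[, "E1"] >= pmin(map2[, "E0"], map2[, "E2"]) &
                  map2[, "E1"] <= pmax(map2[, "E0"], map2[, "E2"])))
  expect_identical(h2$map[, "E1"], (h2$map[, "E0"] + h2$map[, "E2"]) / 2)

  # hybrid one: the overall mean is a weighted mean of the three category
  # means, so it is guaranteed to lie within their range (it can leave the
  # narrower [E0, E2] interval whenever the raw heterozygote mean does)
  lo <- pmin(tgt$map[, "E0"], tgt$map[, "E1"], tgt$map[, "E2"])[all_cats]
  hi <- pmax(tgt$map[, "E0"], tgt$map[, "E1"], tgt$map[, "E2"])[all_cats]
  e1 <- h1$map[all_cats, "E1"]
  expect_true(all(e1 >= lo - 1e-12 & e1 <= hi + 1e-12))
})

test_that("fitted maps ignore samples outside the training set", {
  dat <- random_dataset(n = 60, m = 20, seed = 9)
  train <- rownames(dat$G$values)[1:40]
  Go <- orient_major_allele(dat$G, train)
  Gtrain <- geno_matrix(Go$values[train, , drop = FALSE], oriented = TRUE)
  ytrain <- trait_vector(unclass(dat$y)[train])
  ref <- suppressWarnings(fit_hybrid_two(Gtrain, ytrain))
  # same training rows extracted from a perturbed full dataset
  G2 <- dat$G
  other <- setdiff(rownames(G2$values), train)
  G2$values[other, ] <- 0L
  Go2 <- orient_major_allele(G2, train)
  Gtrain2 <- geno_matrix(Go2$values[train, , drop = FALSE], oriented = TRUE)
  alt <- suppressWarnings(fit_hybrid_two(Gtrain2, ytrain))
  expect_identical(ref$map, alt$map)
})

test_that("unpenalized least squares is invariant to per-marker constant shifts", {
  dat <- random_dataset(n = 50, m = 8, seed = 21)
  Go <- orient_major_allele(dat$G)
  X <- encode_genotypes(fit_ordinal(Go), Go)
  yv <- as.numeric(dat$y)
  base <- ridge_solve(X, yv, 0)
  shifts <- seq_len(ncol(X)) * 1.7 - 5
  Xs <- sweep(X, 2L, shifts, "+")
  shifted <- ridge_solve(Xs, yv, 0)
  fitted_base <- base$beta0 + X %*% base$beta
  fitted_shift <- shifted$beta0 + Xs %*% shifted$beta
  expect_lt(max(abs(fitted_base - fitted_shift)), 1e-8)
  expect_lt(max(abs(base$beta - shifted$beta)), 1e-8)
})

test_that("encoding tables round-trip through text at full precision", {
  dat <- random_dataset(n = 30, m = 12, seed = 4)
  Go <- orient_major_allele(dat$G)
  enc <- suppressWarnings(fit_hybrid_one(Go, dat$y))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_encoding(enc, path)
  back <- read_encoding(path)
  expect_identical(back$method, enc$method)
  expect_identical(back$map, enc$map)
  expect_identical(back$impute, enc$impute)
  expect_identical(back$train_mean, enc$train_mean)
})
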