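test_that("z-scores match hand computation under the population divisor", {
  df <- tibble::tibble(x = c(1, 2, 3), y = c(10, 20, 60))
  z <- zscore(df, mode = "population")
  # mu = 2, sigma = sqrt(2/3): z = (x - 2) / 0.81650
  expect_equal(z$x, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(z$x, 4), c(-1.2247, 0, 1.2247))
  expect_equal(mean(z$y), 0)
  zs <- zscore(df, mode = "sample")
  expect_equal(sd(zs$x), 1)
})

test_that("z-scoring is invariant to affine rescaling of the raw columns", {
  set.seed(1)
  df <- tibble::tibble(a = rnorm(20), b = runif(20))
  df2 <- dplyr::mutate(df, a = 3.7 * a - 12, b = -0.4 * b + 5)
  z1 <- zscore(df)
  z2 <- zscore(df2)
  expect_equal(z1$a, z2$a, tolerance = 1e-9)
  expect_equal(abs(z1$b), abs(z2$b), tolerance = 1e-9)  # sign may flip
})

test_that("constant columns are rejected", {
  expect_error(zscore(tibble::tibble(a = 1:5, b = rep(2, 5))),
               "zero variance")
})

test_that("PCA: perfectly correlated columns, unit fraction sums, fixed
           signs", {
  df <- tibble::tibble(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  pca <- quality_pca(zscore(df))
  expect_equal(pca$variance_fraction[1], 1)
  expect_equal(sum(pca$variance_fraction), 1)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(pca$loadings))) {
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
})

test_that("PC1+PC2 variance matches the generator's construction target", {
  tab <- make_quality_table(seed = 2)
  truth <- attr(tab, "truth")
  pca <- quality_pca(zscore(tab))
  target <- truth$expected_fraction_f1 + truth$expected_fraction_f2
  expect_lt(abs(sum(pca$variance_fraction[1:2]) - target), 0.05)
})

test_that("weights follow the worked loading example and sum to one", {
  pca <- structure(
    list(loadings = matrix(c(0.9, 0.3, 0.1), 3, 1,
                           dimnames = list(c("p1", "p2", "p3"), "PC1")),
         variance_fraction = 1,
         sdev = 1, scores = tibble::tibble(PC1 = numeric(0)),
         parameters = c("p1", "p2", "p3")),
    class = "quality_pca"
  )
  w <- derive_weights(pca, k = 1)
  expect_equal(round(w$weight, 4), c(0.6923, 0.2308, 0.0769))
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)

  # symmetry: two symmetric variables get equal weights
  df <- tibble::tibble(a = c(1, 2, 3, 5), b = c(5, 3, 2, 1))
  w2 <- derive_weights(quality_pca(zscore(df)), k = 1)
  expect_equal(w2$weight[1], w2$weight[2], tolerance = 1e-9)

  # monotone in loading: the dominant variable takes the top weight
  tab <- make_quality_table(seed = 6)
  pca3 <- quality_pca(zscore(tab))
  w3 <- derive_weights(pca3, k = 1, strategy = "pc1_only")
  top <- w3$parameter[which.max(w3$weight)]
  expect_equal(top,
               rownames(pca3$loadings)[which.max(abs(pca3$loadings[, 1]))])
})

test_that("weights are permutation-equivariant in the parameter order", {
  tab <- make_quality_table(seed = 9)
  z <- zscore(tab)
  cols <- attr(z, "z_cols")
  w1 <- derive_weights(quality_pca(z, cols))
  w2 <- derive_weights(quality_pca(z, rev(cols)))
  expect_equal(
    w1$weight[match(w2$parameter, w1$parameter)], w2$weight,
    tolerance = 1e-9
  )
})

test_that("the quality score is the weighted z-sum", {
  z <- tibble::tibble(a = 1.0, b = -0.5, c = 2.0)
  attr(z, "z_cols") <- c("a", "b", "c")
  w <- tibble::tibble(parameter = c("a", "b", "c"), weight = c(0.5, 0.3, 0.2))
  expect_equal(quality_score(z, w)$Q, 0.75)

  # all-zero z row scores zero; one-hot weights pick a single column
  z2 <- tibble::tibble(a = c(0, 1.3), b = c(0, -2), c = c(0, 0.4))
  attr(z2, "z_cols") <- c("a", "b", "c")
  one_hot <- tibble::tibble(parameter = c("a", "b", "c"),
                            weight = c(0, 1, 0))
  expect_equal(quality_score(z2, one_hot)$Q, c(0, -2))

  bad <- tibble::tibble(parameter = c("a", "x"), weight = c(0.5, 0.5))
  z3 <- tibble::tibble(a = 1, b = 2)
  attr(z3, "z_cols") <- c("a", "b")
  expect_error(quality_score(z3, bad), "mismatch")
})

test_that("Q is invariant under affine rescaling of raw columns", {
  tab <- make_quality_table(seed = 12)
  raw_cols <- setdiff(names(tab), c("sample_id", "treatment"))
  tab2 <- tab
  set.seed(5)
  for (cc in raw_cols) {
    tab2[[cc]] <- runif(1, 0.5, 4) * tab2[[cc]] + rnorm(1, 0, 10)
  }
  z1 <- zscore(tab)
  z2 <- zscore(tab2)
  w <- derive_weights(quality_pca(z1))
  q1 <- quality_score(z1, w)$Q
  q2 <- quality_score(z2, w)$Q
  expect_lt(max(abs(q1 - q2)), 1e-9)
  expect_lt(abs(mean(q1)), 1e-9)  # centred by construction
})

test_that("group assignment follows loading dominance", {
  pca <- structure(
    list(loadings = matrix(c(0.9, 0.1, 0.5, 0.1, 0.9, 0.45), 3, 2,
                           dimnames = list(c("p1", "p2", "p3"),
                                           c("PC1", "PC2"))),
         variance_fraction = c(0.6, 0.4), sdev = c(1, 1),
         scores = tibble::tibble(), parameters = c("p1", "p2", "p3")),
    class = "quality_pca"
  )
  gr <- assign_groups(pca, dominance_margin = 0.2)
  expect_equal(as.character(gr$group), c("A", "C", "B"))
})

test_that("planted group memberships are recovered across seeds", {
  rec <- vapply(1:20, function(s) {
    tab <- make_quality_table(seed = s)
    truth <- attr(tab, "truth")
    gr <- assign_groups(quality_pca(zscore(tab)))
    mean(gr$group ==
           truth$groups$group[match(gr$parameter, truth$groups$parameter)])
  }, 0)
  expect_gte(mean(rec), 0.9)
})

test_that("radar export scales to [0, 1], orders by group and flags
           degenerate axes", {
  tab <- make_quality_table(seed = 15)
  gr <- assign_groups(quality_pca(zscore(tab)))
  radar <- radar_export(tab, gr, "treatment")
  expect_true(all(radar$value >= 0 & radar$value <= 1))
  # per parameter, the best level scores exactly 1
  best <- dplyr::summarise(dplyr::group_by(radar, .data$parameter),
                           top = max(.data$value))
  expect_true(all(best$top == 1))
  # axis order: group blocks A, B, C, alphabetical within
  ord <- levels(radar$parameter)
  expected <- gr |>
    dplyr::arrange(.data$group, .data$parameter) |>
    dplyr::pull("parameter")
  expect_equal(ord, expected)

  # degenerate axis: equal means across levels -> 0 and flagged
  tab$flatline <- rep(1:3, length.out = nrow(tab)) # same mean per level
  gr2 <- dplyr::bind_rows(gr, tibble::tibble(parameter = "flatline",
                                             group = factor("C", c("A", "B", "C")),
                                             abs_loading_pc1 = 0,
                                             abs_loading_pc2 = 0))
  radar2 <- radar_export(tab, gr2, "treatment")
  fl <- radar2[radar2$parameter == "flatline", ]
  expect_true(all(fl$degenerate))
  expect_true(all(fl$value == 0))

  one_level <- tab[tab$treatment == "high", ]
  expect_error(radar_export(one_level, gr, "treatment"),
               "nothing to compare")
})
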