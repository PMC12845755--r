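uniform_pmap <- function(value = 25, dim = c(12, 12, 12), sp = c(1, 1, 1)) {
  porosity_volume(array(value, dim), sp, clipped = TRUE)
}

full_masks <- function(pmap) {
  lab <- array(1L, dim(pmap$porosity))
  poroct:::new_fruit_masks(lab, pmap$spacing_mm)
}

test_that("a uniform 25% phantom has whole-fruit mean 25.0", {
  pmap <- uniform_pmap(25)
  wf <- whole_fruit_porosity(pmap, full_masks(pmap))
  expect_equal(wf$mean_porosity, 25)
})

test_that("whole-fruit mean equals the voxel-weighted mean of regional
           means", {
  ph <- make_fruit_phantom(small_fruit_spec(seed = 9))
  pmap <- ph$porosity
  masks <- poroct:::new_fruit_masks((ph$regions$regions > 0L) * 1L,
                                    pmap$spacing_mm)
  wf <- whole_fruit_porosity(pmap, masks)
  rs <- regional_summary(pmap, ph$regions, masks)
  rs <- rs[rs$n_voxels > 0, ]
  weighted <- sum(rs$mean_porosity * rs$n_voxels) / sum(rs$n_voxels)
  expect_equal(wf$mean_porosity, weighted, tolerance = 1e-9)
})

test_that("excluding the cavity shifts the mean by the analytic mixture
           difference", {
  ph <- make_fruit_phantom(small_fruit_spec(jitter_sd = 0))
  pmap <- ph$porosity
  masks <- poroct:::new_fruit_masks((ph$regions$regions > 0L) * 1L,
                                    pmap$spacing_mm)
  with_cav <- whole_fruit_porosity(pmap, masks)$mean_porosity
  without <- whole_fruit_porosity(pmap, masks, include_cavity = FALSE,
                                  regions = ph$regions)$mean_porosity
  n <- sum(ph$regions$regions > 0L)
  ncav <- sum(ph$regions$regions == 4L)
  p_cav <- mean(pmap$porosity[ph$regions$regions == 4L])
  expected <- (with_cav * n - p_cav * ncav) / (n - ncav)
  expect_equal(without, expected, tolerance = 1e-9)
})

test_that("regional summary recovers generator region porosities within one
           point", {
  spec <- small_fruit_spec(porosity = c(seed = 5, core = 10, cortex = 22,
                                        cavity = 100))
  ph <- make_fruit_phantom(spec)
  g <- porosity_to_grey(ph$porosity, noise_sd = 10, seed = 4)
  pmap <- apply_calibration(g, fit_two_point())
  masks <- poroct:::new_fruit_masks((ph$regions$regions > 0L) * 1L,
                                    pmap$spacing_mm)
  rs <- regional_summary(pmap, ph$regions, masks)
  nominal <- c(cortex = 22, core = 10, seed = 5)
  for (rg in names(nominal)) {
    expect_lt(abs(rs$mean_porosity[rs$region == rg] - nominal[[rg]]), 1)
  }
  # cavity is clipped from above at 100, so its mean sits just below
  expect_gt(rs$mean_porosity[rs$region == "cavity"], 99)
})

test_that("line profiles are constant on uniform maps and hit both
           endpoints", {
  pmap <- uniform_pmap(25, dim = c(10, 10, 10))
  pr <- line_profile(pmap, c(1, 1, 1), c(9, 9, 9), n_samples = 50)
  expect_equal(pr$porosity, rep(25, 50))
  expect_equal(pr$position_mm[1], 0)
  expect_equal(max(pr$position_mm), sqrt(3 * 64))

  # n = 2 returns exactly the endpoint values
  arr <- array(0, c(10, 10, 10))
  arr[, , ] <- rep(seq(0, 90, by = 10), each = 100)  # varies along col axis
  pmap2 <- porosity_volume(arr, c(1, 1, 1))
  pr2 <- line_profile(pmap2, c(5, 5, 0.5), c(5, 5, 9.5), n_samples = 2)
  expect_equal(pr2$porosity, c(0, 90))
})

test_that("a diameter profile peaks at the cavity crossing", {
  spec <- small_fruit_spec(jitter_sd = 0)
  ph <- make_fruit_phantom(spec)
  d <- dim(ph$porosity$porosity)
  sp <- ph$porosity$spacing_mm
  centre <- d * sp / 2
  # cross the cavity ring: profile along the row axis through the centre
  pr <- line_profile(ph$porosity, c(centre[1], 0.5, centre[3]),
                     c(centre[1], d[2] * sp[2] - 0.5, centre[3]),
                     n_samples = 200)
  inner <- pr[pr$position_mm > 10 & pr$position_mm < max(pr$position_mm) - 10, ]
  expect_equal(max(inner$porosity), 100, tolerance = 1e-6)
})

test_that("slice maps equal direct indexing and respect bounds", {
  set.seed(5)
  arr <- array(runif(8^3, 0, 100), c(8, 8, 8))
  pmap <- porosity_volume(arr, c(0.5, 0.3, 0.3))
  sl <- slice_porosity_map(pmap, "slice", 3)
  expect_equal(sl$values, arr[3, , ])
  rw <- slice_porosity_map(pmap, "row", 8)
  expect_equal(rw$values, arr[, 8, ])
  expect_error(slice_porosity_map(pmap, "col", 9), "out of range")
})

test_that("group comparison: identical groups give F = 0; planted separation
           is detected", {
  df <- data.frame(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  cmp <- compare_groups(df, "y", "g")
  expect_equal(cmp$anova$f_statistic, 0)

  set.seed(11)
  df2 <- data.frame(
    y = c(rnorm(9, 24.70, 0.5), rnorm(9, 26.44, 0.5), rnorm(9, 29.06, 0.5)),
    g = rep(c("high", "standard", "low"), each = 9)
  )
  cmp2 <- compare_groups(df2, "y", "g")
  expect_lt(cmp2$anova$p_value, 0.001)
  expect_equal(nrow(cmp2$tukey), 3L)
  expect_s3_class(tidy(cmp2), "tbl_df")
  expect_equal(glance(cmp2)$p_value, cmp2$anova$p_value)
})

test_that("insufficient replication is rejected", {
  df <- data.frame(y = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(compare_groups(df, "y", "g"), "insufficient replication")
})

test_that("macro-micro correlation handles exact, anti-monotone and constant
           inputs", {
  x <- c(1, 2, 3, 4, 5)
  out <- macro_micro_correlation(x, x)
  expect_equal(out$estimate, c(1, 1))

  y <- exp(-x)  # anti-monotone, nonlinear
  out2 <- macro_micro_correlation(x, y)
  expect_equal(out2$estimate[out2$method == "spearman"], -1)

  out3 <- macro_micro_correlation(x, rep(1, 5))
  expect_true(all(is.na(out3$estimate)))
})
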