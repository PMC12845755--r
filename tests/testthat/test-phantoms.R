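test_that("phantom whole-fruit mean equals the analytic region mixture", {
  ph <- make_fruit_phantom(small_fruit_spec(seed = 41))
  infruit <- ph$regions$regions > 0L
  observed <- mean(ph$porosity$porosity[infruit])
  expect_lt(abs(observed - ph$mixture), 0.5)
  # and the stats table is consistent with the label volume
  expect_equal(sum(ph$region_stats$n_voxels), sum(infruit))
})

test_that("target_whole_mean re-solves the cortex porosity exactly", {
  ph <- make_fruit_phantom(small_fruit_spec(target_whole_mean = 24.70,
                                            jitter_sd = 0))
  expect_equal(ph$mixture, 24.70)
  infruit <- ph$regions$regions > 0L
  expect_equal(mean(ph$porosity$porosity[infruit]), 24.70, tolerance = 1e-9)
  expect_true(ph$spec$porosity[["cortex"]] >= 15 &&
                ph$spec$porosity[["cortex"]] <= 30)
})

test_that("zero seed count paints no seed voxels", {
  ph <- make_fruit_phantom(small_fruit_spec(seed_count = 0L))
  expect_equal(sum(ph$regions$regions == 3L), 0L)
})

test_that("phantom generation is bit-deterministic given its seed", {
  a <- make_fruit_phantom(small_fruit_spec(seed = 7))
  b <- make_fruit_phantom(small_fruit_spec(seed = 7))
  expect_identical(a$porosity$porosity, b$porosity$porosity)
  expect_identical(a$regions$regions, b$regions$regions)
  c <- make_fruit_phantom(small_fruit_spec(seed = 8))
  expect_false(identical(a$porosity$porosity, c$porosity$porosity))

  g1 <- porosity_to_grey(a$porosity, noise_sd = 10, seed = 3)
  g2 <- porosity_to_grey(b$porosity, noise_sd = 10, seed = 3)
  expect_identical(g1$voxels, g2$voxels)
})

test_that("the forward model maps the anchors exactly at zero noise", {
  cal <- fit_two_point()
  p0 <- porosity_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(porosity_to_grey(p0, cal, noise_sd = 0)$voxels == 49L))
  p100 <- porosity_volume(array(100, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(porosity_to_grey(p100, cal, noise_sd = 0)$voxels == -1007L))
})

test_that("multi-fruit scenes close the loop with segmentation", {
  phs <- lapply(c(51, 52, 53), function(s) {
    make_fruit_phantom(small_fruit_spec(seed = s))
  })
  scene <- make_multi_fruit_scene(phs, noise_sd = 10, seed = 2)
  expect_equal(segment_fruits(scene$grey)$fruit_count, 3L)
  expect_equal(scene$masks$fruit_count, 3L)

  single <- make_multi_fruit_scene(phs[1], noise_sd = 0)
  expect_identical(dim(single$grey$voxels), dim(phs[[1]]$porosity$porosity))

  s1 <- make_multi_fruit_scene(phs, noise_sd = 10, seed = 9)
  s2 <- make_multi_fruit_scene(phs, noise_sd = 10, seed = 9)
  expect_identical(s1$grey$voxels, s2$grey$voxels)
})

test_that("cell phantoms honour their packing and porosity bookkeeping", {
  ph <- make_cell_phantom(small_cell_spec(seed = 5))
  # achieved packing equals the voxel-counted cell fraction by construction;
  # cross-check against the analytic sphere volumes (voxelization error)
  analytic <- sum(4 / 3 * pi * (ph$cells$diameter_um / 2000)^3)
  cube <- prod(dim(ph$grey$voxels)) * prod(ph$grey$spacing_mm)
  expect_lt(abs(ph$achieved$packing_fraction - analytic / cube), 0.01)
  expect_lt(abs(ph$achieved$porosity - ph$spec$target_porosity), 0.01)

  # pore-free phantom: empty pore table
  dry <- make_cell_phantom(small_cell_spec(target_porosity = 0, seed = 6))
  expect_equal(nrow(dry$pores), 0L)
  expect_equal(dry$achieved$porosity, 0)

  # determinism
  a <- make_cell_phantom(small_cell_spec(seed = 12))
  b <- make_cell_phantom(small_cell_spec(seed = 12))
  expect_identical(a$grey$voxels, b$grey$voxels)
  expect_identical(a$cells, b$cells)
})

test_that("an exact cell count can be requested", {
  ph <- make_cell_phantom(small_cell_spec(n_cells = 30, seed = 8))
  expect_equal(nrow(ph$cells), 30L)
  expect_equal(ph$achieved$n_cells, 30L)
})

test_that("quality tables are deterministic with planted structure", {
  a <- make_quality_table(seed = 3)
  b <- make_quality_table(seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))

  truth <- attr(a, "truth")
  expect_equal(nrow(truth$groups), 11L)
  expect_setequal(unique(truth$groups$group), c("A", "B", "C"))

  # strong two-factor structure: first two PCs carry > 60% of the variance
  strong <- make_quality_table(loading_a = c(0.9, 0), loading_b = c(0.6, 0.6),
                               loading_c = c(0, 0.9), noise_sd = 0.1,
                               seed = 4)
  pca <- quality_pca(zscore(strong))
  expect_gt(sum(pca$variance_fraction[1:2]), 0.6)
})

test_that("null treatment effects give uniform-ish group-comparison
           p-values", {
  set.seed(10)
  pvals <- replicate(200, {
    tab <- make_quality_table(n_per_level = 6, effect_f1 = c(0, 0, 0),
                              effect_f2 = c(0, 0, 0),
                              seed = sample.int(1e6, 1))
    compare_groups(tab, "porosity", "treatment")$anova$p_value
  })
  # type-I rate at the nominal 5% level, binomial 99% band for 200 reps
  expect_gt(mean(pvals < 0.05), 0.05 - 0.04)
  expect_lt(mean(pvals < 0.05), 0.05 + 0.04)
})
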