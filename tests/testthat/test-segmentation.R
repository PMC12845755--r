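test_that("a three-fruit scene is segmented into three fruits with accurate
           centroids", {
  phs <- lapply(c(101, 102, 103), function(s) {
    make_fruit_phantom(small_fruit_spec(seed = s))
  })
  scene <- make_multi_fruit_scene(phs, gap_mm = 5, noise_sd = 10, seed = 1)
  masks <- segment_fruits(scene$grey)
  expect_equal(masks$fruit_count, 3L)
  # labels are ordered by size; match detected to true centres by distance
  sp <- scene$grey$spacing_mm
  for (i in seq_len(3)) {
    det <- masks$fruits[i, ]
    d2 <- (scene$centres_mm$centre_slice_mm - det$centroid_slice_mm)^2 +
      (scene$centres_mm$centre_row_mm - det$centroid_row_mm)^2 +
      (scene$centres_mm$centre_col_mm - det$centroid_col_mm)^2
    expect_lt(sqrt(min(d2)), max(sp))  # within one voxel of a true centre
  }
})

test_that("segmentation labels are invariant to fruit order in the scene", {
  phs <- lapply(c(201, 202), function(s) {
    make_fruit_phantom(small_fruit_spec(seed = s))
  })
  s12 <- make_multi_fruit_scene(phs, noise_sd = 0)
  s21 <- make_multi_fruit_scene(rev(phs), noise_sd = 0)
  m12 <- segment_fruits(s12$grey)
  m21 <- segment_fruits(s21$grey)
  expect_equal(m12$fruit_count, m21$fruit_count)
  expect_equal(sort(m12$fruits$n_voxels), sort(m21$fruits$n_voxels))
})

test_that("internal cavities are filled into the fruit mask", {
  ph <- make_fruit_phantom(small_fruit_spec(jitter_sd = 0))
  g <- porosity_to_grey(ph$porosity, noise_sd = 0)
  masks <- segment_fruits(g)
  cavity_idx <- which(ph$regions$regions == 4L)
  expect_gt(length(cavity_idx), 0)
  expect_true(all(masks$labels[cavity_idx] == 1L))
  # and the mask equals the generator's fruit extent exactly (noiseless)
  expect_identical(masks$labels > 0L, ph$regions$regions > 0L)
})

test_that("an all-air volume yields no fruit", {
  set.seed(1)
  g <- grey_volume(array(as.integer(round(rnorm(16^3, -1007, 10))),
                         c(16, 16, 16)), c(1, 1, 1))
  expect_error(segment_fruits(g), "no fruit detected")
})

test_that("more components than expected_max keeps the largest with a
           warning", {
  ph <- make_fruit_phantom(small_fruit_spec(jitter_sd = 0))
  g <- porosity_to_grey(ph$porosity, noise_sd = 0)
  # add a second, smaller blob of tissue in a corner
  g$voxels[2:17, 2:17, 2:17] <- 49L  # ~1900 mm^3, above min volume
  expect_warning(masks <- segment_fruits(g, expected_max = 1L),
                 "expected_max")
  expect_equal(masks$fruit_count, 1L)
})

test_that("region classification recovers generator labels and partitions
           the mask", {
  ph <- make_fruit_phantom(fruit_phantom_spec())  # default 128^3 geometry
  g <- porosity_to_grey(ph$porosity, noise_sd = 10, seed = 2)
  pmap <- apply_calibration(g, fit_two_point())
  masks <- segment_fruits(g)
  regions <- classify_regions(pmap, masks)

  infruit <- ph$regions$regions > 0L
  agreement <- mean(regions$regions[infruit] == ph$regions$regions[infruit])
  expect_gte(agreement, 0.9)

  # partition: every fruit voxel is assigned, no background voxel is
  expect_true(all(regions$regions[masks$labels > 0L] > 0L))
  expect_true(all(regions$regions[masks$labels == 0L] == 0L))
  counts <- regional_summary(pmap, regions, masks)
  expect_equal(sum(counts$n_voxels), sum(masks$labels > 0L))
})

test_that("a uniform tissue sphere is classified as pure cortex", {
  spec <- small_fruit_spec(seed_count = 0L, cavity_count = 0L,
                           porosity = c(seed = 5, core = 25, cortex = 25,
                                        cavity = 100),
                           jitter_sd = 0)
  ph <- make_fruit_phantom(spec)
  g <- porosity_to_grey(ph$porosity, noise_sd = 0)
  pmap <- apply_calibration(g, fit_two_point())
  masks <- segment_fruits(g)
  regions <- classify_regions(pmap, masks)
  infruit <- masks$labels > 0L
  expect_true(all(regions$regions[infruit] == 1L))  # all cortex
})

test_that("cavity voxel counts match the generator within a surface shell", {
  ph <- make_fruit_phantom(small_fruit_spec(jitter_sd = 0))
  g <- porosity_to_grey(ph$porosity, noise_sd = 0)
  pmap <- apply_calibration(g, fit_two_point())
  masks <- segment_fruits(g)
  regions <- classify_regions(pmap, masks)
  true_cavity <- sum(ph$regions$regions == 4L)
  got_cavity <- sum(regions$regions == 4L)
  # tolerance: the cavity surface shell, where smoothing dilutes the band
  surface <- sum(ph$regions$regions == 4L &
                   poroct:::cpp_edt3d(as.vector(ph$regions$regions == 4L),
                                      dim = dim(ph$regions$regions),
                                      spacing = ph$porosity$spacing_mm) <=
                   max(ph$porosity$spacing_mm) * 1.01)
  expect_lte(abs(got_cavity - true_cavity), surface)
})

test_that("invalid band specifications are rejected", {
  expect_error(region_bands(seed = c(10, 0)), "invalid band spec")
  expect_error(region_bands(cavity_min = 20), "invalid band spec")
})
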