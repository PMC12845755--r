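test_that("a 0.5 mm ROI at 6.6 um spacing is 75-76 voxels per edge", {
  set.seed(1)
  big <- grey_volume(
    array(sample(0:100, 100^3, replace = TRUE), c(100, 100, 100)),
    rep(0.0066, 3)
  )
  roi <- extract_roi(big, center_mm = rep(0.33, 3), edge_mm = 0.5)
  expect_true(all(dim(roi$voxels) %in% 75:76))

  expect_error(extract_roi(big, center_mm = c(0.05, 0.33, 0.33)),
               "out of bounds")
})

test_that("a uniform volume yields a uniform ROI", {
  v <- grey_volume(array(7L, c(40, 40, 40)), rep(0.01, 3))
  roi <- extract_roi(v, center_mm = rep(0.2, 3), edge_mm = 0.2)
  expect_true(all(roi$voxels == 7L))
})

test_that("contrast enhancement maps into [0, 1] and is monotone for Otsu", {
  two <- grey_volume(array(rep(c(0L, 100L), 500), c(10, 10, 10)), rep(1, 3))
  enh <- enhance_contrast(two)
  expect_setequal(unique(as.vector(enh$values)), c(0, 1))

  set.seed(2)
  v <- grey_volume(array(as.integer(rnorm(8000, 0, 300)), c(20, 20, 20)),
                   rep(1, 3))
  enh2 <- enhance_contrast(v)
  expect_gte(min(enh2$values), 0)
  expect_lte(max(enh2$values), 1)

  # Otsu classes before and after the (monotone) stretch agree >= 99%
  raw_thr <- otsu_threshold(as.vector(v$voxels))
  enh_thr <- otsu_threshold(as.vector(enh2$values))
  agree <- mean((v$voxels >= raw_thr) == (enh2$values >= enh_thr))
  expect_gte(agree, 0.99)

  eq <- enhance_contrast(v, method = "adaptive_equalize")
  expect_gte(min(eq$values), 0)
  expect_lte(max(eq$values), 1)

  expect_error(enhance_contrast(grey_volume(array(1L, c(3, 3, 3)),
                                            rep(1, 3))),
               "no contrast")
})

test_that("non-touching bright spheres are counted exactly with accurate
           diameters", {
  dia <- c(40, 55, 69, 80, 95)
  for (seed in c(1, 2)) {
    cen <- scatter_centres(12, edge_mm = 0.5, radius_mm = 0.05,
                           min_gap_mm = 0.02, seed = seed)
    dd <- rep_len(dia, 12)
    roi <- sphere_roi(cen, dd)
    blobs <- detect_blobs(enhance_contrast(roi), "bright",
                          diameter_range_um = c(20, 150))
    expect_equal(nrow(blobs), 12L)
    expect_true(all(!blobs$boundary))
    # match detected to planted spheres by centre distance
    for (i in seq_len(12)) {
      d2 <- (blobs$centre_slice_mm - cen[i, 1])^2 +
        (blobs$centre_row_mm - cen[i, 2])^2 +
        (blobs$centre_col_mm - cen[i, 3])^2
      j <- which.min(d2)
      # within two voxels' worth of diameter
      expect_lt(abs(blobs$equivalent_diameter_um[j] - dd[i]), 2 * 6.6)
    }
  }
})

test_that("two overlapping spheres 1.2 diameters apart are split in two", {
  cen <- rbind(c(0.25, 0.20, 0.25),
               c(0.25, 0.20 + 1.2 * 0.069, 0.25))
  roi <- sphere_roi(cen, c(69, 69))
  blobs <- detect_blobs(enhance_contrast(roi), "bright",
                        diameter_range_um = c(30, 150))
  expect_equal(nrow(blobs), 2L)
})

test_that("an all-dark ROI yields no bright blobs", {
  # dark phase plus a sprinkle of isolated single bright voxels: everything
  # above threshold is far below the admissible diameter range
  set.seed(3)
  arr <- array(-1007L, c(30, 30, 30))
  arr[cbind(sample(2:29, 10), sample(2:29, 10), sample(2:29, 10))] <- 49L
  roi <- grey_volume(arr, rep(0.0066, 3))
  blobs <- detect_blobs(enhance_contrast(roi), "bright",
                        diameter_range_um = c(30, 150))
  expect_equal(nrow(blobs), 0L)
  # and a fixed threshold above every value gives an empty mask outright
  none <- detect_blobs(enhance_contrast(roi), "bright",
                       threshold_mode = "fixed", threshold = 2)
  expect_equal(nrow(none), 0L)
})

test_that("blob equivalent diameters match analytic sphere volumes to one
           voxel for diameters of five voxels and up", {
  vox <- 6.6
  for (dia_vox in c(5, 8, 12, 16)) {
    dia <- dia_vox * vox
    roi <- sphere_roi(matrix(c(0.25, 0.25, 0.25), 1), dia)
    blobs <- detect_blobs(enhance_contrast(roi), "bright",
                          diameter_range_um = c(dia * 0.5, dia * 2),
                          threshold_mode = "otsu")
    expect_equal(nrow(blobs), 1L)
    expect_lt(abs(blobs$equivalent_diameter_um - dia), vox)
    # and the stored diameter satisfies the equivalent-sphere identity
    expect_equal(blobs$equivalent_diameter_um,
                 2 * (3 * blobs$voxel_count * vox^3 / (4 * pi))^(1 / 3))
  }
})

test_that("cell phantom morphometrics recover diameter, density and
           porosity", {
  ph <- make_cell_phantom(cell_phantom_spec(seed = 31))
  res <- analyze_roi(ph$grey)
  m <- res$metrics
  true_dia <- mean(ph$cells$diameter_um)
  expect_lt(abs(m$mean_cell_diameter_um - true_dia) / true_dia, 0.03)
  vol <- prod(dim(ph$grey$voxels)) * prod(ph$grey$spacing_mm)
  true_density <- nrow(ph$cells) / vol
  expect_lt(abs(m$cell_density_mm3 - true_density) / true_density, 0.10)
  expect_lt(abs(m$pore_volume_ratio - ph$achieved$porosity), 0.01)
  # conservation: pore volume never exceeds the ROI volume
  expect_lte(sum(res$pores$voxel_count) * prod(ph$grey$spacing_mm), vol)
})

test_that("metric arithmetic matches its definitions", {
  mk_blobs <- function(n, dia, boundary = FALSE) {
    tibble::tibble(
      blob = seq_len(n), centre_slice_mm = 0, centre_row_mm = 0,
      centre_col_mm = 0, equivalent_diameter_um = dia,
      voxel_count = 10L, polarity = "bright", boundary = boundary
    )
  }
  roi <- structure(list(values = array(0, c(50, 50, 50)),
                        spacing_mm = rep(0.01, 3)),
                   class = "enhanced_roi")  # exactly 0.125 mm^3
  m <- compute_metrics(mk_blobs(200, 69), mk_blobs(0, 0), roi)
  expect_equal(m$cell_count, 200)
  expect_equal(m$cell_density_mm3, 1600)
  expect_equal(m$cell_density_mm3, m$cell_count / 0.125)

  # pores occupying 27 voxels of a 10^3 ROI
  roi2 <- structure(list(values = array(0, c(10, 10, 10)),
                         spacing_mm = rep(0.01, 3)),
                    class = "enhanced_roi")
  pores <- mk_blobs(1, 30)
  pores$voxel_count <- 27L
  pores$polarity <- "dark"
  m2 <- compute_metrics(mk_blobs(0, 0), pores, roi2)
  expect_equal(m2$pore_volume_ratio, 0.027)
  expect_equal(m2$roi_porosity, 2.7)

  # no pores: zero ratio, undefined mean diameter
  m3 <- compute_metrics(mk_blobs(3, 50), mk_blobs(0, 0), roi2)
  expect_equal(m3$pore_volume_ratio, 0)
  expect_true(is.na(m3$mean_pore_diameter_um))

  # boundary cells count half
  m4 <- compute_metrics(
    dplyr::bind_rows(mk_blobs(10, 60), mk_blobs(4, 60, boundary = TRUE)),
    mk_blobs(0, 0), roi
  )
  expect_equal(m4$cell_count, 12)
})

test_that("paired position test recovers a planted offset and flags
           degenerate inputs", {
  mk_metrics <- function(porosity) {
    tibble::tibble(roi_id = sprintf("a%02d", seq_along(porosity)),
                   roi_porosity = porosity)
  }
  # identical arms: zero difference, undefined-p marker
  same <- mk_metrics(rep(25, 5))
  out <- paired_position_test(same, same, metrics = "roi_porosity")
  expect_equal(out$mean_difference, 0)
  expect_true(is.na(out$p_value))

  set.seed(17)
  base <- rnorm(9, 26, 1)
  delta <- rnorm(9, 1.71, 0.5)
  out2 <- paired_position_test(mk_metrics(base + delta), mk_metrics(base),
                               metrics = "roi_porosity")
  expect_lt(abs(out2$mean_difference - 1.71), 0.5)
  expect_lt(out2$p_value, 0.05)

  # unpaired apples are rejected
  expect_error(paired_position_test(mk_metrics(1:4), mk_metrics(1:5)),
               "incomplete pair")
})
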