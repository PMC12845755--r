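# Small phantom specifications shared across test files. Coarser voxels than
# the package defaults keep unit tests fast; acceptance tests use the
# defaults.

small_fruit_spec <- function(...) {
  fruit_phantom_spec(
    spacing_mm = c(1, 0.678, 0.678),
    dim = c(64L, 64L, 64L),
    ...
  )
}

small_cell_spec <- function(...) {
  args <- utils::modifyList(
    list(edge_mm = 0.3, packing_fraction = 0.2, target_porosity = 0.1),
    list(...)
  )
  do.call(cell_phantom_spec, args)
}

# a grey ROI containing explicit bright spheres on a dark background, with
# exact ground truth; diameters in um, cube edge in mm
sphere_roi <- function(centres_mm, diameters_um, edge_mm = 0.5,
                       voxel_um = 6.6, fg = 300L, bg = -500L) {
  vox_mm <- voxel_um / 1000
  n <- as.integer(round(edge_mm / vox_mm))
  arr <- array(bg, c(n, n, n))
  ax <- ((1:n) - 0.5) * vox_mm
  for (i in seq_len(nrow(centres_mm))) {
    r <- diameters_um[i] / 2000
    inside <- outer(outer((ax - centres_mm[i, 1])^2,
                          (ax - centres_mm[i, 2])^2, "+"),
                    (ax - centres_mm[i, 3])^2, "+") <= r^2
    arr[inside] <- fg
  }
  grey_volume(arr, rep(vox_mm, 3))
}

# uniformly scattered non-touching sphere centres by seeded rejection
scatter_centres <- function(n, edge_mm, radius_mm, min_gap_mm, seed) {
  set.seed(seed)
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    cen <- runif(3, radius_mm + min_gap_mm, edge_mm - radius_mm - min_gap_mm)
    if (nrow(out) == 0 ||
        all(colSums((t(out) - cen)^2) > (2 * radius_mm + min_gap_mm)^2)) {
      out <- rbind(out, cen)
    }
  }
  out
}
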