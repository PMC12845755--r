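# Synthetic phantom generators. These define the study conditions for every
# validation in the package: whole-fruit CT scenes at low resolution,
# packed-cell volumes at high resolution, and latent-factor quality tables.
# All generators are bit-deterministic given their seed.

#' Specification for a synthetic whole-fruit phantom
#'
#' Describes an axis-aligned ellipsoidal fruit at low-resolution CT geometry
#' with nested anatomical regions: a central core cylinder, a ring of
#' ellipsoidal seeds, a ring of ellipsoidal cavity lobes, and cortex
#' elsewhere. Each region carries a nominal porosity (percent); voxelwise
#' porosity adds a small intra-region jitter.
#'
#' The default geometry is a scaled-down fruit (semi-axes 17 x 15 x 15 mm)
#' voxelized at the low-resolution scan spacing (0.5, 0.339, 0.339) mm on a
#' 128^3 grid, so the default phantom is a complete single-fruit scene.
#'
#' @param semi_axes_mm fruit ellipsoid semi-axes (slice, row, col) in mm.
#' @param spacing_mm voxel spacing (slice, row, col) in mm.
#' @param dim volume dimensions (slice, row, col) in voxels.
#' @param core_radius_mm,core_half_height_mm core cylinder geometry (axis
#'   along the slice direction).
#' @param seed_count number of seeds (0 allowed).
#' @param seed_semi_axes_mm seed ellipsoid semi-axes in mm.
#' @param seed_ring_mm radial offset of seed centres from the fruit axis.
#' @param cavity_count,cavity_semi_axes_mm,cavity_ring_mm cavity lobe
#'   geometry; lobes are placed on a ring rotated halfway between seeds.
#' @param porosity named numeric vector with entries `seed`, `core`,
#'   `cortex`, `cavity` (percent).
#' @param jitter_sd intra-region porosity jitter SD in percentage points.
#' @param target_whole_mean optional whole-fruit mean porosity (percent); if
#'   set, the cortex porosity is re-solved from the voxelized region volumes
#'   so the volume-weighted mixture equals this target exactly.
#' @param seed RNG seed.
#' @return A `fruit_phantom_spec` list.
#' @export
fruit_phantom_spec <- function(semi_axes_mm = c(17, 15, 15),
                               spacing_mm = c(0.5, 0.339, 0.339),
                               dim = c(128L, 128L, 128L),
                               core_radius_mm = 6,
                               core_half_height_mm = 9,
                               seed_count = 5L,
                               seed_semi_axes_mm = c(3.5, 1.4, 1.4),
                               seed_ring_mm = 3.8,
                               cavity_count = 5L,
                               cavity_semi_axes_mm = c(4, 1.1, 1.1),
                               cavity_ring_mm = 2.2,
                               porosity = c(seed = 5, core = 10,
                                            cortex = 22, cavity = 100),
                               jitter_sd = 1,
                               target_whole_mean = NULL,
                               seed = 20240830L) {
  spacing_mm <- check_spacing(spacing_mm)
  stopifnot(length(semi_axes_mm) == 3L, all(semi_axes_mm > 0),
            length(dim) == 3L, all(dim >= 4))
  req <- c("seed", "core", "cortex", "cavity")
  if (!all(req %in% names(porosity))) {
    abort("`porosity` must name seed, core, cortex and cavity values")
  }
  if (any(porosity < 0 | porosity > 100)) {
    abort("region porosities must lie in [0, 100]")
  }
  extent <- dim * spacing_mm
  if (any(2 * semi_axes_mm >= extent)) {
    abort("geometry overflow: fruit does not fit inside the volume")
  }
  if (core_half_height_mm >= semi_axes_mm[1] ||
      core_radius_mm >= min(semi_axes_mm[2:3])) {
    abort("geometry overflow: core exceeds fruit bounds")
  }
  structure(
    list(
      semi_axes_mm = semi_axes_mm, spacing_mm = spacing_mm,
      dim = as.integer(dim),
      core_radius_mm = core_radius_mm,
      core_half_height_mm = core_half_height_mm,
      seed_count = as.integer(seed_count),
      seed_semi_axes_mm = seed_semi_axes_mm, seed_ring_mm = seed_ring_mm,
      cavity_count = as.integer(cavity_count),
      cavity_semi_axes_mm = cavity_semi_axes_mm,
      cavity_ring_mm = cavity_ring_mm,
      porosity = porosity[req], jitter_sd = jitter_sd,
      target_whole_mean = target_whole_mean, seed = seed
    ),
    class = "fruit_phantom_spec"
  )
}

REGION_LEVELS <- c(background = 0L, cortex = 1L, core = 2L, seed = 3L,
                   cavity = 4L)

#' Generate a voxelized fruit phantom with ground truth
#'
#' Voxelizes the fruit described by a [fruit_phantom_spec()]: region labels
#' are painted by geometry (cortex, then core, then cavity lobes, then
#' seeds), voxelwise porosity is the region's nominal value plus seeded
#' Gaussian jitter (clamped to \[0, 100\]), and background voxels are air at
#' 100% porosity. When `target_whole_mean` is set the cortex porosity is
#' solved from the voxel-counted region volumes so that the volume-weighted
#' mixture over the fruit equals the target exactly.
#'
#' @param spec a [fruit_phantom_spec()].
#' @return A `fruit_phantom` list: `porosity` ([porosity_volume()] truth),
#'   `regions` (`region_labels` truth, background = 0), `mixture` (analytic
#'   voxel-weighted mixture of the painted regions, percent), `region_stats`
#'   (tibble of voxel counts and nominal porosities) and the `spec` (with
#'   the solved cortex porosity when a target was requested).
#' @export
make_fruit_phantom <- function(spec) {
  stopifnot(inherits(spec, "fruit_phantom_spec"))
  d <- spec$dim
  sp <- spec$spacing_mm
  centre <- d * sp / 2

  co <- voxel_coords(d, sp)
  # normalized ellipsoid radius of every voxel
  r2 <- ((co$x1 - centre[1]) / spec$semi_axes_mm[1])^2 +
    ((co$x2 - centre[2]) / spec$semi_axes_mm[2])^2 +
    ((co$x3 - centre[3]) / spec$semi_axes_mm[3])^2
  regions <- array(REGION_LEVELS[["background"]], d)
  fruit <- r2 <= 1
  regions[fruit] <- REGION_LEVELS[["cortex"]]

  # core cylinder along the slice axis
  in_core <- fruit &
    abs(co$x1 - centre[1]) <= spec$core_half_height_mm &
    ((co$x2 - centre[2])^2 + (co$x3 - centre[3])^2) <= spec$core_radius_mm^2
  regions[in_core] <- REGION_LEVELS[["core"]]

  paint_ring <- function(regions, count, semi, ring, phase, level) {
    if (count < 1L) return(regions)
    ang <- 2 * pi * (seq_len(count) - 1) / count + phase
    for (a in ang) {
      cen <- c(centre[1],
               centre[2] + ring * cos(a),
               centre[3] + ring * sin(a))
      e2 <- ((co$x1 - cen[1]) / semi[1])^2 +
        ((co$x2 - cen[2]) / semi[2])^2 +
        ((co$x3 - cen[3]) / semi[3])^2
      inside <- e2 <= 1
      if (any(inside & !fruit)) abort("geometry overflow: lobe outside fruit")
      regions[inside] <- level
    }
    regions
  }
  cavity_phase <- if (spec$seed_count > 0) pi / spec$seed_count else 0
  regions <- paint_ring(regions, spec$cavity_count, spec$cavity_semi_axes_mm,
                        spec$cavity_ring_mm, cavity_phase,
                        REGION_LEVELS[["cavity"]])
  regions <- paint_ring(regions, spec$seed_count, spec$seed_semi_axes_mm,
                        spec$seed_ring_mm, 0,
                        REGION_LEVELS[["seed"]])

  counts <- tabulate(regions + 1L, nbins = 5L)  # index = level + 1
  names(counts) <- names(REGION_LEVELS)
  n_fruit <- sum(counts[-1])

  pors <- spec$porosity
  if (!is.null(spec$target_whole_mean)) {
    other <- counts[["seed"]] * pors[["seed"]] +
      counts[["core"]] * pors[["core"]] +
      counts[["cavity"]] * pors[["cavity"]]
    cortex_p <- (spec$target_whole_mean * n_fruit - other) /
      counts[["cortex"]]
    if (!is.finite(cortex_p) || cortex_p < 0 || cortex_p > 100) {
      abort("target_whole_mean is not reachable with this geometry")
    }
    pors[["cortex"]] <- cortex_p
    spec$porosity <- pors
  }

  lookup <- c(100, pors[["cortex"]], pors[["core"]], pors[["seed"]],
              pors[["cavity"]])  # background = air = 100%
  p <- lookup[regions + 1L]
  if (spec$jitter_sd > 0) {
    jit <- with_seed(spec$seed, rnorm(length(p), 0, spec$jitter_sd))
    p <- p + jit
    p[p < 0] <- 0
    p[p > 100] <- 100
  }
  dim(p) <- d

  mixture <- (counts[["cortex"]] * pors[["cortex"]] +
                counts[["core"]] * pors[["core"]] +
                counts[["seed"]] * pors[["seed"]] +
                counts[["cavity"]] * pors[["cavity"]]) / n_fruit

  structure(
    list(
      porosity = porosity_volume(p, sp, clipped = TRUE),
      regions = new_region_labels(regions, sp),
      mixture = mixture,
      region_stats = tibble(
        region = names(REGION_LEVELS)[-1],
        nominal_porosity = as.numeric(pors[c("cortex", "core", "seed",
                                             "cavity")]),
        n_voxels = as.integer(counts[c("cortex", "core", "seed", "cavity")]),
        volume_mm3 = counts[c("cortex", "core", "seed", "cavity")] * prod(sp)
      ),
      spec = spec
    ),
    class = "fruit_phantom"
  )
}

# voxel-centre coordinate arrays for a (d, spacing) grid, broadcast to 3D
voxel_coords <- function(d, sp) {
  x1 <- axis_mm(seq_len(d[1]), sp[1])
  x2 <- axis_mm(seq_len(d[2]), sp[2])
  x3 <- axis_mm(seq_len(d[3]), sp[3])
  list(
    x1 = array(rep(x1, times = d[2] * d[3]), d),
    x2 = array(rep(rep(x2, each = d[1]), times = d[3]), d),
    x3 = array(rep(x3, each = d[1] * d[2]), d)
  )
}

#' Forward-model a porosity volume to CT grey values
#'
#' Inverts the two-point calibration: a voxel at porosity `p` maps to
#' `juice_grey - (p / 100) * (juice_grey - air_grey)`, optionally plus
#' Gaussian noise (seeded), then rounds and clamps to the signed 16-bit
#' range. Background voxels in a phantom truth volume are at 100% porosity
#' and therefore map to the air anchor automatically.
#'
#' @param truth a [porosity_volume()] of true porosity (percent).
#' @param calib a [fit_two_point()] calibration.
#' @param noise_sd Gaussian noise SD in grey units (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return A [grey_volume()].
#' @export
porosity_to_grey <- function(truth, calib = fit_two_point(), noise_sd = 10,
                             seed = 1L) {
  stopifnot(inherits(truth, "porosity_volume"),
            inherits(calib, "porosity_calibration"))
  g <- calib$juice_grey -
    (truth$porosity / 100) * (calib$juice_grey - calib$air_grey)
  if (noise_sd > 0) {
    g <- g + with_seed(seed, rnorm(length(g), 0, noise_sd))
  }
  g <- round(g)
  g[g < -32768] <- -32768
  g[g > 32767] <- 32767
  dim(g) <- dim(truth$porosity)
  grey_volume(g, truth$spacing_mm,
              series_meta = list(synthetic = TRUE, noise_sd = noise_sd))
}

#' Compose several fruit phantoms into one multi-fruit scene
#'
#' Places 1-3 fruit phantoms side by side along the column axis with a
#' configured air gap, merges their truth volumes, and forward-models the
#' scene to grey values. All phantoms must share spacing and (slice, row)
#' dimensions.
#'
#' @param phantoms list of [make_fruit_phantom()] results (1 to 3).
#' @param gap_mm air gap between phantom boxes along the column axis; must
#'   be >= 0 (boxes may not overlap).
#' @param calib calibration used for the forward model.
#' @param noise_sd,seed forward-model noise (grey units) and RNG seed.
#' @return A `fruit_scene` list: `grey` ([grey_volume()]), `porosity` (truth
#'   [porosity_volume()]), `masks` (truth `fruit_masks`), `regions` (truth
#'   `region_labels`) and `centres_mm` (tibble of true fruit centres).
#' @export
make_multi_fruit_scene <- function(phantoms, gap_mm = 4,
                                   calib = fit_two_point(),
                                   noise_sd = 10, seed = 1L) {
  if (inherits(phantoms, "fruit_phantom")) phantoms <- list(phantoms)
  stopifnot(length(phantoms) >= 1L, length(phantoms) <= 3L,
            all(vapply(phantoms, inherits, TRUE, "fruit_phantom")))
  if (gap_mm < 0) abort("fruits collide: gap_mm must be >= 0")
  sp <- phantoms[[1]]$porosity$spacing_mm
  dims <- vapply(phantoms, function(p) dim(p$porosity$porosity), integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("phantoms must share (slice, row) dimensions")
  }
  for (p in phantoms) {
    if (!isTRUE(all.equal(p$porosity$spacing_mm, sp))) {
      abort("phantoms must share spacing")
    }
  }
  gap_vox <- as.integer(round(gap_mm / sp[3]))
  d <- c(dims[1, 1], dims[2, 1],
         sum(dims[3, ]) + gap_vox * (length(phantoms) - 1L))

  porosity <- array(100, d)  # air background
  regions <- array(0L, d)
  labels <- array(0L, d)
  centres <- vector("list", length(phantoms))
  off <- 0L
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    nc <- dims[3, i]
    cols <- (off + 1L):(off + nc)
    porosity[, , cols] <- ph$porosity$porosity
    regions[, , cols] <- ph$regions$regions
    infruit <- ph$regions$regions > 0L
    lab_block <- array(0L, dim(infruit))
    lab_block[infruit] <- i
    labels[, , cols] <- lab_block
    centres[[i]] <- tibble(
      fruit = i,
      centre_slice_mm = dim(infruit)[1] * sp[1] / 2,
      centre_row_mm = dim(infruit)[2] * sp[2] / 2,
      centre_col_mm = off * sp[3] + dim(infruit)[3] * sp[3] / 2
    )
    off <- off + nc + gap_vox
  }
  truth_p <- porosity_volume(porosity, sp, clipped = TRUE)
  list(
    grey = porosity_to_grey(truth_p, calib, noise_sd = noise_sd, seed = seed),
    porosity = truth_p,
    masks = new_fruit_masks(labels, sp),
    regions = new_region_labels(regions, sp),
    centres_mm = dplyr::bind_rows(centres)
  )
}

#' Specification for a packed-cell high-resolution phantom
#'
#' Describes a cubic high-resolution ROI filled with non-overlapping bright
#' spheres (cells) by random sequential adsorption, plus dark pore spheres
#' placed in the interstitial space (pores may overlap each other, never
#' cells); the remaining interstice is a cell-wall/juice matrix at an
#' intermediate grey level. The true pore volume is tracked by painted-voxel
#' count, so it is exact even where pores overlap.
#'
#' Either a target cell packing fraction or an exact cell count can be
#' requested. Cells are fully interior by default (no boundary contact), so
#' planted counts translate directly into density ground truth.
#'
#' @param edge_mm cube edge length (default 0.5 mm).
#' @param voxel_um isotropic voxel size (default 6.6 um).
#' @param cell_diameter_um,cell_diameter_sd_um cell diameter distribution.
#' @param packing_fraction target cell volume fraction in (0, 0.74]; ignored
#'   when `n_cells` is given.
#' @param n_cells optional exact number of cells to place.
#' @param target_porosity target pore volume fraction of the whole cube in
#'   \[0, 1) (the pore fraction of the interstitial space follows from the
#'   achieved packing).
#' @param pore_diameter_um,pore_diameter_sd_um pore diameter distribution.
#' @param cell_grey,matrix_grey,pore_grey nominal grey values of the three
#'   phases (defaults 300 / 49 / -1007: bright cells, juice-like matrix,
#'   air-filled pores).
#' @param noise_sd Gaussian grey noise SD.
#' @param margin_um minimum surface-to-surface clearance between cells.
#' @param max_failures consecutive failed insertions before stopping; a
#'   packing run that stops short of 90% of the target volume (or of the
#'   exact requested count) is an error reporting the achieved fraction.
#' @param seed RNG seed.
#' @return A `cell_phantom_spec` list.
#' @export
cell_phantom_spec <- function(edge_mm = 0.5, voxel_um = 6.6,
                              cell_diameter_um = 69, cell_diameter_sd_um = 2,
                              packing_fraction = 0.30, n_cells = NULL,
                              target_porosity = 0.20,
                              pore_diameter_um = 40, pore_diameter_sd_um = 8,
                              cell_grey = 300, matrix_grey = 49,
                              pore_grey = -1007,
                              noise_sd = 30, margin_um = 0,
                              max_failures = 20000L, seed = 20240830L) {
  stopifnot(edge_mm > 0, voxel_um > 0, cell_diameter_um > 0,
            cell_diameter_sd_um >= 0, pore_diameter_um > 0,
            pore_diameter_sd_um >= 0, noise_sd >= 0)
  if (is.null(n_cells)) {
    if (packing_fraction <= 0 || packing_fraction > 0.74) {
      abort("packing_fraction must lie in (0, 0.74]")
    }
  }
  if (target_porosity < 0 || target_porosity >= 1) {
    abort("target_porosity must lie in [0, 1)")
  }
  structure(
    list(edge_mm = edge_mm, voxel_um = voxel_um,
         cell_diameter_um = cell_diameter_um,
         cell_diameter_sd_um = cell_diameter_sd_um,
         packing_fraction = packing_fraction,
         n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells),
         target_porosity = target_porosity,
         pore_diameter_um = pore_diameter_um,
         pore_diameter_sd_um = pore_diameter_sd_um,
         cell_grey = cell_grey, matrix_grey = matrix_grey,
         pore_grey = pore_grey, noise_sd = noise_sd,
         margin_um = margin_um, max_failures = as.integer(max_failures),
         seed = seed),
    class = "cell_phantom_spec"
  )
}

#' Generate a packed-cell phantom with ground-truth sphere tables
#'
#' @param spec a [cell_phantom_spec()].
#' @return A `cell_phantom` list: `grey` ([grey_volume()]), `cells` and
#'   `pores` (tibbles of true sphere centres (mm), diameters (um) and
#'   polarity), and `achieved` (list with voxel-counted `packing_fraction`
#'   and `porosity`).
#' @export
make_cell_phantom <- function(spec) {
  stopifnot(inherits(spec, "cell_phantom_spec"))
  with_seed(spec$seed, make_cell_phantom_impl(spec))
}

make_cell_phantom_impl <- function(spec) {
  vox_mm <- spec$voxel_um / 1000
  n <- max(2L, as.integer(round(spec$edge_mm / vox_mm)))
  d <- c(n, n, n)
  edge_mm_eff <- n * vox_mm
  cube_vol_mm3 <- edge_mm_eff^3

  # --- cells: strict RSA, fully interior ---
  centres <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)  # mm
  target_cell_vol <- if (is.null(spec$n_cells)) {
    spec$packing_fraction * cube_vol_mm3
  } else {
    Inf  # count-driven
  }
  margin_mm <- spec$margin_um / 1000
  placed_vol <- 0
  fails <- 0L
  repeat {
    if (!is.null(spec$n_cells) && nrow(centres) >= spec$n_cells) break
    if (is.null(spec$n_cells) && placed_vol >= target_cell_vol) break
    if (fails >= spec$max_failures) {
      if (!is.null(spec$n_cells) ||
          placed_vol < 0.90 * target_cell_vol) {
        abort(sprintf(
          "packing failed: achieved fraction %.3f",
          placed_vol / cube_vol_mm3
        ))
      }
      break
    }
    dia_um <- rnorm(1, spec$cell_diameter_um, spec$cell_diameter_sd_um)
    if (dia_um <= 2 * spec$voxel_um) { fails <- fails + 1L; next }
    r <- dia_um / 2000  # mm
    lo <- r + margin_mm
    hi <- edge_mm_eff - r - margin_mm
    if (hi <= lo) { fails <- fails + 1L; next }
    cen <- runif(3, lo, hi)
    ok <- TRUE
    if (nrow(centres) > 0) {
      dist2 <- colSums((t(centres) - cen)^2)
      ok <- all(dist2 > (radii + r + margin_mm)^2)
    }
    if (ok) {
      centres <- rbind(centres, cen)
      radii <- c(radii, r)
      placed_vol <- placed_vol + 4 / 3 * pi * r^3
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }

  phase <- array(0L, d)  # 0 = matrix, 1 = cell, 2 = pore
  cell_vox <- 0
  for (i in seq_along(radii)) {
    phase <- paint_sphere(phase, centres[i, ], radii[i], vox_mm, 1L)
    cell_vox <- cell_vox + attr(phase, "painted")
  }

  # --- pores: avoid cells, may overlap each other ---
  pore_centres <- matrix(numeric(0), 0, 3)
  pore_radii <- numeric(0)
  target_pore_vox <- spec$target_porosity * prod(d)
  fails <- 0L
  pore_vox <- 0
  while (pore_vox < target_pore_vox && fails < spec$max_failures) {
    dia_um <- rnorm(1, spec$pore_diameter_um, spec$pore_diameter_sd_um)
    if (dia_um <= spec$voxel_um) { fails <- fails + 1L; next }
    r <- dia_um / 2000
    cen <- runif(3, r, edge_mm_eff - r)
    if (nrow(centres) > 0) {
      dist2 <- colSums((t(centres) - cen)^2)
      if (any(dist2 <= (radii + r)^2)) { fails <- fails + 1L; next }
    }
    phase <- paint_sphere(phase, cen, r, vox_mm, 2L)
    painted <- attr(phase, "painted")
    pore_vox <- pore_vox + painted
    if (painted > 0) {
      pore_centres <- rbind(pore_centres, cen)
      pore_radii <- c(pore_radii, r)
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
  }
  if (spec$target_porosity > 0 && pore_vox < 0.9 * target_pore_vox) {
    abort(sprintf("packing failed: achieved porosity %.3f",
                  pore_vox / prod(d)))
  }

  grey_lookup <- c(spec$matrix_grey, spec$cell_grey, spec$pore_grey)
  g <- grey_lookup[phase + 1L]
  if (spec$noise_sd > 0) g <- g + rnorm(length(g), 0, spec$noise_sd)
  g <- round(g)
  g[g < -32768] <- -32768
  g[g > 32767] <- 32767
  dim(g) <- d

  sphere_tibble <- function(cen, rad, polarity) {
    if (length(rad) == 0) {
      return(tibble(centre_slice_mm = numeric(0), centre_row_mm = numeric(0),
                    centre_col_mm = numeric(0), diameter_um = numeric(0),
                    polarity = character(0)))
    }
    tibble(
      centre_slice_mm = cen[, 1], centre_row_mm = cen[, 2],
      centre_col_mm = cen[, 3],
      diameter_um = rad * 2000, polarity = polarity
    )
  }

  structure(
    list(
      grey = grey_volume(g, rep(vox_mm, 3),
                         series_meta = list(synthetic = TRUE)),
      phase = phase,
      cells = sphere_tibble(centres, radii, "bright"),
      pores = sphere_tibble(pore_centres, pore_radii, "dark"),
      achieved = list(
        packing_fraction = cell_vox / prod(d),
        porosity = pore_vox / prod(d),
        n_cells = length(radii), n_pore_spheres = length(pore_radii)
      ),
      spec = spec
    ),
    class = "cell_phantom"
  )
}

# paint a sphere into an integer phase array (voxel-centre inclusion test);
# level 2 (pore) never overwrites level 1 (cell). Returns the phase array
# with attribute "painted": the number of voxels newly set to `level`.
paint_sphere <- function(phase, centre_mm, radius_mm, vox_mm, level) {
  d <- dim(phase)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, as.integer(ceiling((centre_mm[a] - radius_mm) / vox_mm + 0.5)))
    hi <- min(d[a], as.integer(floor((centre_mm[a] + radius_mm) / vox_mm + 0.5)))
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) {
    attr(phase, "painted") <- 0L
    return(phase)
  }
  x1 <- axis_mm(rng[[1]], vox_mm) - centre_mm[1]
  x2 <- axis_mm(rng[[2]], vox_mm) - centre_mm[2]
  x3 <- axis_mm(rng[[3]], vox_mm) - centre_mm[3]
  n1 <- length(x1); n2 <- length(x2); n3 <- length(x3)
  inside <- array(
    rep(x1^2, times = n2 * n3) +
      rep(rep(x2^2, each = n1), times = n3) +
      rep(x3^2, each = n1 * n2) <= radius_mm^2,
    c(n1, n2, n3)
  )
  block <- phase[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  if (level == 2L) {
    sel <- inside & block != 1L & block != 2L
  } else {
    sel <- inside & block != level
  }
  block[sel] <- level
  phase[rng[[1]], rng[[2]], rng[[3]]] <- block
  attr(phase, "painted") <- sum(sel)
  phase
}

#' Generate a synthetic quality table with planted latent structure
#'
#' Simulates a samples-by-traits quality table driven by two standardized
#' latent factors: factor 1 drives the planted group-A traits (seed traits,
#' cell diameter), factor 2 the group-C traits (diameter, weight, porosity),
#' and both moderately drive group-B traits (height, sugar, firmness, color,
#' pore diameter). Treatment levels shift the factor means by the given
#' effect patterns (the factors are rescaled to unit total variance, so the
#' planted loadings are on the correlation scale that a PCA of z-scored
#' traits sees). Residual noise per trait defaults to whatever brings each
#' trait to unit variance.
#'
#' Two design details keep the planted groups identifiable by PCA loading
#' dominance: group-B traits alternate the sign of their factor-2 loading
#' (identical B loadings would form a coherent bridging direction between
#' the factors and rotate the leading components toward a general
#' component), and group-C traits carry a small compensating factor-1
#' loading that cancels the residual factor coupling from the odd number of
#' B traits, keeping the effective loading columns orthogonal.
#'
#' @param n_per_level samples per treatment level.
#' @param levels character vector of treatment levels (>= 2).
#' @param effect_f1,effect_f2 per-level shifts of the two factor means
#'   (recycled to `length(levels)`); the default patterns are orthogonal
#'   across levels so the treatment structure does not correlate the
#'   factors.
#' @param loading_a,loading_b,loading_c numeric pairs: loadings of each
#'   planted group on (factor 1, factor 2), correlation scale.
#' @param noise_sd residual SD of every trait, or `NULL` (default) to give
#'   every trait unit total variance.
#' @param seed RNG seed.
#' @return A tibble with `sample_id`, `treatment` and 11 trait columns;
#'   attribute `truth` (list with planted `groups`, factor scores, the
#'   planted loading matrix and the analytic expected variance fractions of
#'   the two factors under z-scoring).
#' @export
make_quality_table <- function(n_per_level = 30,
                               levels = c("high", "standard", "low"),
                               effect_f1 = c(-1.5, 0, 1.5),
                               effect_f2 = c(-0.5, 1, -0.5),
                               loading_a = c(0.92, 0),
                               loading_b = c(0.62, 0.42),
                               loading_c = c(0, 0.72),
                               noise_sd = NULL,
                               seed = 1L) {
  if (length(levels) < 2L) abort("need >= 2 treatment levels")
  effect_f1 <- rep_len(effect_f1, length(levels))
  effect_f2 <- rep_len(effect_f2, length(levels))

  params <- list(
    A = c("seed_count", "seed_weight", "cell_diameter"),
    B = c("height", "sugar", "firmness", "color", "pore_diameter"),
    C = c("diameter", "weight", "porosity")
  )
  if (any(lengths(params) < 2L)) abort("undersized design")
  nB <- length(params$B)
  b_signs <- rep_len(c(1, -1), nB)
  # compensate the residual factor coupling left by an odd number of B traits
  coupling <- sum(b_signs) * loading_b[1] * loading_b[2] +
    length(params$A) * loading_a[1] * loading_a[2]
  c_f1 <- if (loading_c[2] != 0) {
    loading_c[1] - coupling / (length(params$C) * loading_c[2])
  } else {
    loading_c[1]
  }
  loadings <- rbind(
    matrix(rep(loading_a, each = length(params$A)), ncol = 2),
    cbind(rep(loading_b[1], nB), b_signs * loading_b[2]),
    cbind(rep(c_f1, length(params$C)),
          rep(loading_c[2], length(params$C)))
  )
  pnames <- unlist(params, use.names = FALSE)
  rownames(loadings) <- pnames

  n <- n_per_level * length(levels)
  # population variance of the level shift pattern as realized in the sample
  shift_var <- function(e) mean((rep(e, each = n_per_level) -
                                   mean(rep(e, each = n_per_level)))^2)
  out <- with_seed(seed, {
    treatment <- rep(levels, each = n_per_level)
    f1 <- (rnorm(n) + rep(effect_f1, each = n_per_level)) /
      sqrt(1 + shift_var(effect_f1))
    f2 <- (rnorm(n) + rep(effect_f2, each = n_per_level)) /
      sqrt(1 + shift_var(effect_f2))
    sig <- if (is.null(noise_sd)) {
      sqrt(pmax(0.05, 1 - rowSums(loadings^2)))
    } else {
      rep(noise_sd, length(pnames))
    }
    eps <- matrix(rnorm(n * length(pnames)), n) %*% diag(sig)
    x <- cbind(f1, f2) %*% t(loadings) + eps
    colnames(x) <- pnames
    list(treatment = treatment, f1 = f1, f2 = f2, x = x, sig = sig)
  })

  tab <- dplyr::bind_cols(
    tibble(sample_id = sprintf("S%03d", seq_len(n)),
           treatment = factor(out$treatment, levels = levels)),
    as_tibble(out$x)
  )
  # analytic variance fractions: top eigenvalues of the population
  # correlation matrix implied by the construction
  pop_cov <- loadings %*% t(loadings) + diag(out$sig^2)
  dinv <- diag(1 / sqrt(diag(pop_cov)))
  pop_eig <- eigen(dinv %*% pop_cov %*% dinv, symmetric = TRUE,
                   only.values = TRUE)$values
  truth <- list(
    groups = tibble(
      parameter = pnames,
      group = rep(names(params), lengths(params))
    ),
    f1 = out$f1, f2 = out$f2,
    loadings = loadings,
    expected_fraction_f1 = pop_eig[1] / length(pnames),
    expected_fraction_f2 = pop_eig[2] / length(pnames)
  )
  attr(tab, "truth") <- truth
  tab
}
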