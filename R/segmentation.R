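# Fruit-scene segmentation: tissue/air separation, per-fruit labelling and
# anatomical region classification by porosity bands.

new_fruit_masks <- function(labels, spacing_mm) {
  storage.mode(labels) <- "integer"
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  d <- dim(labels)
  fruits <- purrr::map_dfr(ids, function(id) {
    idx <- which(labels == id)
    co <- arrayInd(idx, d)
    tibble(
      fruit = id,
      n_voxels = length(idx),
      volume_mm3 = length(idx) * prod(spacing_mm),
      centroid_slice_mm = mean(axis_mm(co[, 1], spacing_mm[1])),
      centroid_row_mm = mean(axis_mm(co[, 2], spacing_mm[2])),
      centroid_col_mm = mean(axis_mm(co[, 3], spacing_mm[3]))
    )
  })
  structure(
    list(labels = labels, fruit_count = length(ids), fruits = fruits,
         spacing_mm = spacing_mm),
    class = "fruit_masks"
  )
}

#' @export
print.fruit_masks <- function(x, ...) {
  cat(sprintf("<fruit_masks> %d fruit(s) in a %s volume\n", x$fruit_count,
              paste(dim(x$labels), collapse = " x ")))
  print(x$fruits)
  invisible(x)
}

new_region_labels <- function(regions, spacing_mm, fruit_labels = NULL) {
  storage.mode(regions) <- "integer"
  counts <- tibble(
    region = names(REGION_LEVELS),
    level = as.integer(REGION_LEVELS),
    n_voxels = tabulate(regions + 1L, nbins = 5L)
  )
  structure(
    list(regions = regions, counts = counts, spacing_mm = spacing_mm,
         fruit_labels = fruit_labels),
    class = "region_labels"
  )
}

#' @export
print.region_labels <- function(x, ...) {
  cat("<region_labels>\n")
  print(x$counts)
  invisible(x)
}

#' Segment individual fruits from a multi-fruit CT scene
#'
#' Separates tissue from background air with an Otsu threshold on the grey
#' values (or a fixed threshold), fills internal holes (gas-filled cavities
#' belong to the fruit extent), labels 26-connected components, discards
#' components smaller than `min_volume_mm3`, and orders the surviving fruits
#' by decreasing voxel count. If more than `expected_max` components
#' survive, a warning is raised and only the largest `expected_max` are
#' kept.
#'
#' @param volume a [grey_volume()].
#' @param threshold optional fixed grey threshold; when `NULL` (default) the
#'   threshold is Otsu's on the full grey histogram. Voxels at or above the
#'   threshold are tissue.
#' @param min_volume_mm3 minimum fruit volume to keep (default 500 mm^3).
#' @param min_contrast minimum separation (grey units) between the mean grey
#'   of the tissue and background classes; an automatic threshold whose
#'   classes are closer than this (e.g. an air-only scene, where Otsu can
#'   only split the noise) means no fruit is present (default 100).
#' @param expected_max maximum number of fruits expected in the scene
#'   (default 3, matching a three-fruit scanning tray).
#' @return A `fruit_masks` object: `labels` (3D integer array, 0 =
#'   background), `fruit_count`, and a `fruits` tibble with voxel counts,
#'   volumes and centroids (mm).
#' @export
segment_fruits <- function(volume, threshold = NULL, min_volume_mm3 = 500,
                           expected_max = 3L, min_contrast = 100) {
  stopifnot(inherits(volume, "grey_volume"))
  g <- volume$voxels
  auto <- is.null(threshold)
  thr <- threshold %||% tryCatch(
    otsu_threshold(as.vector(g)),
    error = function(e) abort("no fruit detected: constant volume")
  )
  tissue <- g >= thr
  if (!any(tissue) || all(tissue)) abort("no fruit detected")
  if (auto && (mean(g[tissue]) - mean(g[!tissue])) < min_contrast) {
    abort("no fruit detected: tissue/background contrast below min_contrast")
  }
  tissue <- fill_holes_3d(tissue)
  lab <- label_components(tissue, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0L])
  min_vox <- min_volume_mm3 / prod(volume$spacing_mm)
  keep <- which(sizes >= min_vox)
  if (length(keep) == 0L) abort("no fruit detected")
  if (length(keep) > expected_max) {
    warn(sprintf("%d components exceed expected_max = %d; keeping largest %d",
                 length(keep), expected_max, expected_max))
    keep <- keep[order(sizes[keep], decreasing = TRUE)][seq_len(expected_max)]
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  new_fruit_masks(out, volume$spacing_mm)
}

# fill internal holes: background components (6-connected) not touching the
# volume border are part of the enclosing object
fill_holes_3d <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 6L)
  d <- dim(lab)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border_labels <- setdiff(border_labels, 0)
  hole <- bg & !(lab %in% border_labels)
  dim(hole) <- d
  mask | hole
}

#' Region porosity bands
#'
#' The anatomical regions of a fruit are characterized by porosity bands:
#' seeds are densest (0-10%), core tissue 5-15%, cortex 15-30%, and
#' gas-filled cavities are at (or near) 100%. The seed and core bands
#' overlap in 5-10%; [classify_regions()] resolves the overlap with a radial
#' gate and a band-midpoint rule.
#'
#' @param seed,core,cortex numeric `(min, max)` porosity bands in percent.
#' @param cavity_min porosity at or above which a voxel is cavity (default
#'   90, tolerant of noise and partial-volume voxels).
#' @return A named list of bands.
#' @export
region_bands <- function(seed = c(0, 10), core = c(5, 15),
                         cortex = c(15, 30), cavity_min = 90) {
  for (b in list(seed, core, cortex)) {
    if (length(b) != 2L || b[1] >= b[2]) abort("invalid band spec")
  }
  if (cavity_min <= cortex[2]) {
    abort("invalid band spec: cavity_min must exceed the cortex band")
  }
  list(seed = seed, core = core, cortex = cortex, cavity_min = cavity_min)
}

#' Classify anatomical regions from a porosity map
#'
#' Per fruit, the porosity map is locally averaged over a ball of
#' `smooth_radius_mm` (restricted to the fruit mask, so background air does
#' not bleed in), then every voxel is assigned a region:
#'
#' * smoothed porosity >= `cavity_min` -> cavity;
#' * voxels whose normalized radial position (distance from the fruit
#'   centroid over the fruit's equivalent radius) is below `inner_fraction`
#'   are eligible for seed/core: within the seed/core band overlap the
#'   nearer band midpoint wins, otherwise plain band membership decides;
#' * outer voxels in the cortex band -> cortex;
#' * anything left unassigned takes the label of the nearest assigned voxel
#'   of the same fruit (multi-source BFS).
#'
#' The result is a partition of every fruit mask.
#'
#' @param pmap a [porosity_volume()].
#' @param masks a `fruit_masks` from [segment_fruits()].
#' @param bands a [region_bands()] list.
#' @param smooth_radius_mm radius of the local averaging ball in mm
#'   (default 1).
#' @param inner_fraction radial gate for seed/core eligibility (default
#'   0.35).
#' @return A `region_labels` object; `regions` uses levels 0 background,
#'   1 cortex, 2 core, 3 seed, 4 cavity.
#' @export
classify_regions <- function(pmap, masks, bands = region_bands(),
                             smooth_radius_mm = 1, inner_fraction = 0.35) {
  stopifnot(inherits(pmap, "porosity_volume"), inherits(masks, "fruit_masks"))
  d <- dim(pmap$porosity)
  if (!identical(d, dim(masks$labels))) abort("pmap and masks must share shape")
  sp <- pmap$spacing_mm
  regions <- array(0L, d)
  fruit_any <- masks$labels > 0L
  psmooth <- masked_ball_mean(pmap$porosity, fruit_any, sp, smooth_radius_mm)

  for (f in seq_len(masks$fruit_count)) {
    idx <- which(masks$labels == f)
    co <- arrayInd(idx, d)
    cen <- c(mean(axis_mm(co[, 1], sp[1])), mean(axis_mm(co[, 2], sp[2])),
             mean(axis_mm(co[, 3], sp[3])))
    eq_r <- (3 * length(idx) * prod(sp) / (4 * pi))^(1 / 3)
    rnorm_pos <- sqrt((axis_mm(co[, 1], sp[1]) - cen[1])^2 +
                        (axis_mm(co[, 2], sp[2]) - cen[2])^2 +
                        (axis_mm(co[, 3], sp[3]) - cen[3])^2) / eq_r
    p <- psmooth[idx]
    lab <- integer(length(idx))  # 0 = unassigned
    lab[p >= bands$cavity_min] <- REGION_LEVELS[["cavity"]]

    inner <- rnorm_pos < inner_fraction & lab == 0L
    seed_mid <- mean(bands$seed)
    core_mid <- mean(bands$core)
    in_seed <- p >= bands$seed[1] & p <= bands$seed[2]
    in_core <- p >= bands$core[1] & p <= bands$core[2]
    both <- in_seed & in_core
    lab[inner & both & abs(p - seed_mid) <= abs(p - core_mid)] <-
      REGION_LEVELS[["seed"]]
    lab[inner & both & lab == 0L] <- REGION_LEVELS[["core"]]
    lab[inner & !both & in_seed & lab == 0L] <- REGION_LEVELS[["seed"]]
    lab[inner & !both & in_core & lab == 0L] <- REGION_LEVELS[["core"]]

    in_cortex <- p >= bands$cortex[1] & p <= bands$cortex[2]
    lab[lab == 0L & in_cortex] <- REGION_LEVELS[["cortex"]]

    if (any(lab == 0L)) {
      if (all(lab == 0L)) {
        abort("invalid band spec: no voxel matched any band")
      }
      sub <- array(0L, d)
      sub[idx] <- lab
      msk <- array(FALSE, d)
      msk[idx] <- TRUE
      sub <- cpp_grow_nearest(sub, msk, dim = d)
      dim(sub) <- d
      lab <- sub[idx]
    }
    regions[idx] <- lab
  }
  new_region_labels(regions, sp, fruit_labels = masks$labels)
}

# mean over a ball neighbourhood restricted to a mask, via FFT convolution
# of both the masked values and the mask itself
masked_ball_mean <- function(x, mask, spacing, radius_mm) {
  if (radius_mm <= 0) return(x)
  d <- dim(x)
  r_vox <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  if (all(r_vox == 0L)) return(x)
  k1 <- (-r_vox[1]):r_vox[1]
  k2 <- (-r_vox[2]):r_vox[2]
  k3 <- (-r_vox[3]):r_vox[3]
  kern_small <- array(0, c(length(k1), length(k2), length(k3)))
  kk <- expand.grid(a = k1 * spacing[1], b = k2 * spacing[2],
                    c = k3 * spacing[3])
  kern_small[] <- as.numeric(kk$a^2 + kk$b^2 + kk$c^2 <= radius_mm^2)
  # embed kernel centred at origin with wraparound
  kern <- array(0, d)
  ix1 <- (k1 %% d[1]) + 1L
  ix2 <- (k2 %% d[2]) + 1L
  ix3 <- (k3 %% d[3]) + 1L
  kern[ix1, ix2, ix3] <- kern_small
  fk <- fft(kern)
  num <- Re(fft(fft(x * mask) * fk, inverse = TRUE)) / prod(d)
  den <- Re(fft(fft(mask * 1) * fk, inverse = TRUE)) / prod(d)
  out <- x
  inm <- mask & den > 0.5  # at least one in-mask voxel contributes
  out[inm] <- num[inm] / den[inm]
  out
}

# 3D connected-component labelling (compiled BFS); connectivity 6 or 26
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label3d(as.vector(mask), dim = d, connectivity = connectivity)
  dim(lab) <- d
  lab
}
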