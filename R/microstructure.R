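# High-resolution ROI analysis: contrast enhancement, cell/pore blob
# detection with watershed splitting, and morphometrics.

#' Extract a cubic region of interest
#'
#' Crops an axis-aligned cube of `edge_mm` per side centred (to the nearest
#' voxel) at `center_mm`. Spacing is inherited. The ROI must lie fully
#' inside the volume.
#'
#' @param volume a [grey_volume()].
#' @param center_mm physical centre (slice, row, col) in mm.
#' @param edge_mm cube edge length in mm (default 0.5).
#' @return A [grey_volume()] cropped to the ROI.
#' @export
extract_roi <- function(volume, center_mm, edge_mm = 0.5) {
  stopifnot(inherits(volume, "grey_volume"), length(center_mm) == 3L,
            edge_mm > 0)
  d <- dim(volume$voxels)
  sp <- volume$spacing_mm
  idx <- vector("list", 3)
  for (a in 1:3) {
    n <- max(1L, as.integer(round(edge_mm / sp[a])))
    lo <- as.integer(round((center_mm[a] - edge_mm / 2) / sp[a] + 0.5))
    hi <- lo + n - 1L
    if (lo < 1L || hi > d[a]) abort("ROI out of bounds")
    idx[[a]] <- lo:hi
  }
  grey_volume(volume$voxels[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              sp, volume$series_meta)
}

#' Contrast enhancement of a high-resolution ROI
#'
#' `percentile_stretch` (default) maps the `probs[1]`-`probs[2]` quantile
#' range linearly onto \[0, 1\] and clamps; it is monotone, so downstream
#' Otsu class assignments are preserved. `adaptive_equalize` applies
#' contrast-limited adaptive histogram equalization slice by slice
#' (EBImage's CLAHE), then rescales to \[0, 1\].
#'
#' @param roi a [grey_volume()] (non-constant).
#' @param method `"percentile_stretch"` or `"adaptive_equalize"`.
#' @param probs stretch quantiles (default `c(0.01, 0.99)`).
#' @return An `enhanced_roi`: list with `values` (double array in \[0, 1\])
#'   and `spacing_mm`.
#' @export
enhance_contrast <- function(roi,
                             method = c("percentile_stretch",
                                        "adaptive_equalize"),
                             probs = c(0.01, 0.99)) {
  stopifnot(inherits(roi, "grey_volume"))
  method <- match.arg(method)
  v <- roi$voxels
  if (min(v) == max(v)) abort("no contrast: constant ROI")
  if (method == "percentile_stretch") {
    q <- quantile(v, probs, names = FALSE)
    if (q[1] == q[2]) q <- range(v)
    out <- (v - q[1]) / (q[2] - q[1])
    out[out < 0] <- 0
    out[out > 1] <- 1
  } else {
    d <- dim(v)
    rng <- range(v)
    unit <- (v - rng[1]) / (rng[2] - rng[1])
    img <- EBImage::Image(aperm(unit, c(2, 3, 1)))  # frames = slices
    eq <- EBImage::clahe(img, nx = 4, ny = 4)
    out <- aperm(as.array(eq), c(3, 1, 2))
    out <- (out - min(out)) / max(1e-12, max(out) - min(out))
  }
  dim(out) <- dim(v)
  structure(list(values = out, spacing_mm = roi$spacing_mm),
            class = "enhanced_roi")
}

#' @export
print.enhanced_roi <- function(x, ...) {
  cat(sprintf("<enhanced_roi> %s voxels in [0, 1]\n",
              paste(dim(x$values), collapse = " x ")))
  invisible(x)
}

#' Detect cell or pore blobs in an enhanced ROI
#'
#' Binarizes the ROI (cells are bright objects, pores dark), splits touching
#' objects by a marker-based watershed on the Euclidean distance transform
#' (markers are distance local maxima, greedily separated by at least the
#' minimum diameter), labels the resulting objects and summarizes each as an
#' equivalent sphere. Objects whose equivalent diameter falls outside
#' `diameter_range_um` are dropped; objects touching the ROI boundary are
#' kept but flagged, so they can be excluded from diameter statistics and
#' half-weighted in counts.
#'
#' Threshold modes: `"otsu"` (single two-class threshold, for two-phase
#' ROIs), `"multi_otsu"` (two-threshold, three-class split for ROIs with a
#' pore / matrix / cell structure: dark objects are below the lower
#' threshold, bright objects above the upper) and `"fixed"` (explicit
#' `threshold`, below = dark / at-or-above = bright).
#'
#' @param roi an `enhanced_roi` from [enhance_contrast()].
#' @param polarity `"bright"` (cells) or `"dark"` (pores).
#' @param diameter_range_um admissible equivalent-diameter range in um.
#' @param threshold_mode `"otsu"`, `"multi_otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required for `"fixed"`).
#' @return A tibble of blobs: `blob`, centre coordinates (mm),
#'   `equivalent_diameter_um`, `voxel_count`, `polarity`, `boundary`.
#'   Empty detection returns an empty tibble (not an error).
#' @export
detect_blobs <- function(roi, polarity = c("bright", "dark"),
                         diameter_range_um = c(20, 200),
                         threshold_mode = c("otsu", "multi_otsu", "fixed"),
                         threshold = NULL) {
  stopifnot(inherits(roi, "enhanced_roi"))
  polarity <- match.arg(polarity)
  threshold_mode <- match.arg(threshold_mode)
  if (length(diameter_range_um) != 2L || any(diameter_range_um <= 0) ||
      diameter_range_um[1] >= diameter_range_um[2]) {
    abort("diameter range must be positive with min < max")
  }
  v <- roi$values
  d <- dim(v)
  sp_um <- roi$spacing_mm * 1000

  mask <- switch(threshold_mode,
    otsu = {
      thr <- otsu_threshold(as.vector(v))
      if (polarity == "bright") v >= thr else v < thr
    },
    multi_otsu = {
      thr <- multi_otsu_thresholds(as.vector(v))
      if (polarity == "bright") v >= thr[2] else v < thr[1]
    },
    fixed = {
      if (is.null(threshold)) abort("`threshold` required for fixed mode")
      if (polarity == "bright") v >= threshold else v < threshold
    }
  )
  dim(mask) <- d
  if (!any(mask)) return(empty_blob_table(polarity))

  labels <- split_objects(mask, sp_um, min_sep_um = diameter_range_um[1])
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0L) return(empty_blob_table(polarity))

  vox_vol_um3 <- prod(sp_um)
  rows <- purrr::map_dfr(ids, function(id) {
    idx <- which(labels == id)
    co <- arrayInd(idx, d)
    nvox <- length(idx)
    eqd <- 2 * (3 * vox_vol_um3 * nvox / (4 * pi))^(1 / 3)
    on_boundary <- any(co == 1L) ||
      any(co[, 1] == d[1]) || any(co[, 2] == d[2]) || any(co[, 3] == d[3])
    tibble(
      centre_slice_mm = mean(axis_mm(co[, 1], roi$spacing_mm[1])),
      centre_row_mm = mean(axis_mm(co[, 2], roi$spacing_mm[2])),
      centre_col_mm = mean(axis_mm(co[, 3], roi$spacing_mm[3])),
      equivalent_diameter_um = eqd,
      voxel_count = nvox,
      boundary = on_boundary
    )
  })
  rows <- rows[rows$equivalent_diameter_um >= diameter_range_um[1] &
                 rows$equivalent_diameter_um <= diameter_range_um[2], ]
  if (nrow(rows) == 0L) return(empty_blob_table(polarity))
  dplyr::bind_cols(tibble(blob = seq_len(nrow(rows))), rows) |>
    dplyr::mutate(polarity = polarity, .before = "boundary")
}

empty_blob_table <- function(polarity) {
  tibble(
    blob = integer(0), centre_slice_mm = numeric(0),
    centre_row_mm = numeric(0), centre_col_mm = numeric(0),
    equivalent_diameter_um = numeric(0), voxel_count = integer(0),
    polarity = character(0), boundary = logical(0)
  )
}

# split a binary mask into objects: connected components, then per-component
# watershed from distance-transform maxima separated by >= min_sep_um
split_objects <- function(mask, sp_um, min_sep_um) {
  d <- dim(mask)
  comp <- label_components(mask, connectivity = 26L)
  edt <- cpp_edt3d(as.vector(mask), dim = d, spacing = sp_um)
  dim(edt) <- d
  cand <- cpp_local_maxima(edt, dim = d)
  dim(cand) <- d
  cand <- cand & mask

  # collapse plateaus: one representative (max-EDT, lowest index) per
  # connected candidate plateau
  plat <- label_components(cand, connectivity = 26L)
  nplat <- max(plat)
  if (nplat == 0L) return(comp)
  cand_idx <- which(plat > 0L)
  reps <- vapply(split(cand_idx, plat[cand_idx]), function(ix) {
    ix[which.max(edt[ix])]
  }, 0L)

  # greedy minimum-separation suppression within each component
  co <- arrayInd(reps, d)
  pos <- sweep(co - 0.5, 2, sp_um, "*")
  compid <- comp[reps]
  keep <- logical(length(reps))
  ord <- order(-edt[reps], reps)
  for (i in ord) {
    sel <- keep & compid == compid[i]
    if (!any(sel)) {
      keep[i] <- TRUE
    } else {
      d2 <- colSums((t(pos[sel, , drop = FALSE]) - pos[i, ])^2)
      keep[i] <- all(d2 >= min_sep_um^2)
    }
  }
  reps <- reps[keep]

  markers <- array(0L, d)
  markers[reps] <- seq_along(reps)
  lab <- cpp_watershed(as.vector(edt), as.vector(markers), as.vector(mask),
                       dim = d)
  dim(lab) <- d
  # voxels in components that lost all markers (none, by construction, since
  # each component's global maximum always survives) would remain 0
  lab
}

#' Morphometrics of one ROI
#'
#' Summarizes detected cell and pore blobs into the per-ROI metric set:
#' mean equivalent diameters over interior (non-boundary) blobs, an
#' edge-corrected cell count (boundary-touching cells weighted 0.5, unbiased
#' to first order for convex objects), cell density per mm^3, the pore
#' volume ratio (total pore voxel volume over ROI volume, boundary pores
#' included) and the ROI porosity in percent.
#'
#' @param cells,pores blob tibbles from [detect_blobs()].
#' @param roi the ROI the blobs came from (`enhanced_roi` or
#'   [grey_volume()]); provides the geometry.
#' @param roi_id,position_class optional identifiers carried through (e.g.
#'   apple id and `"sunny"` / `"shady"`).
#' @return A one-row tibble: `roi_id`, `position_class`,
#'   `mean_cell_diameter_um`, `cell_count`, `cell_density_mm3`,
#'   `mean_pore_diameter_um`, `pore_count`, `pore_volume_ratio`,
#'   `roi_porosity`. Diameter means are `NA` when no interior blob exists.
#' @export
compute_metrics <- function(cells, pores, roi, roi_id = NA_character_,
                            position_class = NA_character_) {
  d <- if (inherits(roi, "enhanced_roi")) dim(roi$values) else dim(vol_array(roi))
  sp <- roi$spacing_mm
  roi_vol_mm3 <- prod(d) * prod(sp)
  if (roi_vol_mm3 <= 0) abort("invalid ROI: zero volume")

  interior_cells <- cells[!cells$boundary, ]
  interior_pores <- pores[!pores$boundary, ]
  cell_count <- nrow(interior_cells) + 0.5 * sum(cells$boundary)
  pore_count <- nrow(interior_pores) + 0.5 * sum(pores$boundary)
  pore_vox_vol_mm3 <- sum(pores$voxel_count) * prod(sp)
  pvr <- pore_vox_vol_mm3 / roi_vol_mm3

  tibble(
    roi_id = roi_id,
    position_class = position_class,
    mean_cell_diameter_um = if (nrow(interior_cells) > 0) {
      mean(interior_cells$equivalent_diameter_um)
    } else NA_real_,
    cell_count = cell_count,
    cell_density_mm3 = cell_count / roi_vol_mm3,
    mean_pore_diameter_um = if (nrow(interior_pores) > 0) {
      mean(interior_pores$equivalent_diameter_um)
    } else NA_real_,
    pore_count = pore_count,
    pore_volume_ratio = pvr,
    roi_porosity = 100 * pvr
  )
}

#' Analyze one ROI end to end
#'
#' Convenience wrapper: enhance, detect bright cells and dark pores, and
#' compute the metric row. Uses the three-class threshold split, which is
#' the appropriate mode for parenchyma ROIs with pore / matrix / cell
#' phases.
#'
#' @param roi a [grey_volume()] ROI.
#' @param cell_diameter_range_um,pore_diameter_range_um admissible
#'   equivalent-diameter ranges.
#' @param threshold_mode passed to [detect_blobs()] (default
#'   `"multi_otsu"`).
#' @param roi_id,position_class identifiers carried into the metrics row.
#' @return A list with `cells`, `pores` (blob tibbles) and `metrics`
#'   (one-row tibble).
#' @export
analyze_roi <- function(roi, cell_diameter_range_um = c(30, 150),
                        pore_diameter_range_um = c(10, 200),
                        threshold_mode = "multi_otsu",
                        roi_id = NA_character_,
                        position_class = NA_character_) {
  enh <- enhance_contrast(roi)
  cells <- detect_blobs(enh, "bright", cell_diameter_range_um,
                        threshold_mode = threshold_mode)
  pores <- detect_blobs(enh, "dark", pore_diameter_range_um,
                        threshold_mode = threshold_mode)
  list(
    cells = cells, pores = pores,
    metrics = compute_metrics(cells, pores, enh, roi_id = roi_id,
                              position_class = position_class)
  )
}

#' Paired comparison of sunny vs shady ROI metrics
#'
#' Two-sided paired t-test per metric across apples that each contribute one
#' sunny and one shady ROI. The reported mean difference is sunny minus
#' shady. Metrics with constant (including all-zero) paired differences get
#' an `NA` p-value marker.
#'
#' @param sunny,shady metric tibbles (one row per apple) as produced by
#'   [compute_metrics()], each containing `roi_id`.
#' @param metrics character vector of metric columns to test (default: all
#'   shared numeric metric columns).
#' @return A tibble with `metric`, `mean_difference`, `t_statistic`, `df`,
#'   `p_value`, `n_pairs`.
#' @export
paired_position_test <- function(sunny, shady, metrics = NULL) {
  stopifnot(is.data.frame(sunny), is.data.frame(shady))
  if (!"roi_id" %in% names(sunny) || !"roi_id" %in% names(shady)) {
    abort("metric tables need a `roi_id` pairing column")
  }
  if (anyDuplicated(sunny$roi_id) || anyDuplicated(shady$roi_id)) {
    abort("incomplete pair: duplicated roi_id within an arm")
  }
  if (!setequal(sunny$roi_id, shady$roi_id)) {
    abort("incomplete pair: every apple needs one sunny and one shady record")
  }
  shady <- shady[match(sunny$roi_id, shady$roi_id), ]
  if (is.null(metrics)) {
    num <- intersect(names(sunny), names(shady))
    metrics <- num[vapply(sunny[num], is.numeric, TRUE)]
  }
  purrr::map_dfr(metrics, function(m) {
    dif <- sunny[[m]] - shady[[m]]
    dif <- dif[is.finite(dif)]
    n <- length(dif)
    if (n < 2L || sd(dif) == 0) {
      return(tibble(metric = m,
                    mean_difference = if (n > 0) mean(dif) else NA_real_,
                    t_statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, n_pairs = n))
    }
    tt <- t.test(dif)
    tibble(metric = m, mean_difference = mean(dif),
           t_statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, n_pairs = n)
  })
}
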