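#' Segment the cell from an intensity channel
#'
#' Global threshold (Otsu by default) on the chosen channel, retention of
#' the largest connected component, and hole filling — mirroring the
#' threshold / fill-holes route used for phalloidin-stained cells.
#' Background pixels are excluded from every downstream intensity
#' statistic via the mask (they are invalid, not zero).
#'
#' @param image a [cell_image()].
#' @param channel channel name to threshold (default `"signal"`).
#' @param method `"otsu"` or a fixed numeric threshold in channel units.
#' @return Binary matrix mask of the cell.
#' @details When two components tie in area the one whose centroid has
#'   the smaller row index is kept, and a message is emitted.
#' @export
segment_cell <- function(image, channel = "signal", method = "otsu") {
  im <- get_channel(image, channel)
  if (identical(method, "otsu")) {
    rng <- range(im)
    if (diff(rng) <= 0) abort(
      "channel is constant; cannot threshold", "dcmotion_segmentation_error")
    scaled <- (im - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    mask <- scaled > thr
  } else if (is.numeric(method) && length(method) == 1L) {
    mask <- im > method
  } else abort_param("`method` must be \"otsu\" or a numeric threshold")
  if (!any(mask))
    abort("segmentation produced an empty mask", "dcmotion_segmentation_error")

  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    cent_row <- vapply(best, function(k)
      mean(which(lab == k, arr.ind = TRUE)[, 1]), numeric(1))
    best <- best[which.min(cent_row)]
    message("tie in component area broken toward the smallest centroid row")
  }
  mask <- lab == best
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  matrix(mask, nrow(im), ncol(im))
}

# pixel-centre coordinate grids (um) for a mask's dimensions; image
# convention: x along columns, y along rows increasing downward
coord_grids <- function(dims, pixel_size) {
  nr <- dims[1]; nc <- dims[2]
  list(X = matrix((seq_len(nc) - 0.5) * pixel_size, nr, nc, byrow = TRUE),
       Y = matrix((seq_len(nr) - 0.5) * pixel_size, nr, nc))
}

# first crossing of the mask boundary marching from `start` (um) along
# unit direction `dir`; returns distance in um
march_to_edge <- function(mask, start, dir, pixel_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  step <- pixel_size / 4
  max_steps <- ceiling(2 * sqrt(nr^2 + nc^2) * pixel_size / step)
  for (k in seq_len(max_steps)) {
    p <- start + k * step * dir
    r <- ceiling(p[2] / pixel_size); c <- ceiling(p[1] / pixel_size)
    if (r < 1 || r > nr || c < 1 || c > nc || !mask[r, c])
      return((k - 0.5) * step)
  }
  abort_data("failed to find the mask boundary along the axis")
}

#' Front-rear geometry of a segmented cell
#'
#' Anchors the polarity axis on the nucleus: the axis is the principal
#' axis of the cell mask, passing through the nucleus centroid; it is
#' intersected with the cell boundary on both sides, and the side with
#' the shorter nucleus-edge-to-cell-edge distance is the rear (the rear
#' is always the shorter distance). The returned axis unit vector points
#' toward the front.
#'
#' @param cell_mask,nucleus_mask binary matrices of equal dimension.
#' @param pixel_size um/px.
#' @return A `cell_geometry` list: `cell_mask`, `nucleus_mask`, `axis`
#'   (unit 2-vector, image x/y convention, pointing front), `centroid`
#'   (nucleus centroid, um), `rear_point`, `front_point` (boundary
#'   crossings, um), `rear_distance`, `front_distance` (um, nucleus edge
#'   to cell edge), `tie` (logical; TRUE when the two distances are
#'   equal and the rear was assigned to the negative axis direction).
#' @export
compute_geometry <- function(cell_mask, nucleus_mask, pixel_size) {
  if (!all(dim(cell_mask) == dim(nucleus_mask)))
    abort_param("masks must share dimensions")
  check_scalar(pixel_size, "pixel_size", lower = 1e-12)
  cell_mask <- cell_mask > 0; nucleus_mask <- nucleus_mask > 0
  if (!any(nucleus_mask)) abort_data("empty nucleus mask")
  if (!any(cell_mask)) abort_data("empty cell mask")
  if (any(nucleus_mask & !cell_mask))
    abort_data("nucleus mask extends outside the cell mask")

  g <- coord_grids(dim(cell_mask), pixel_size)
  cx <- g$X[cell_mask]; cy <- g$Y[cell_mask]
  ctr_nuc <- c(mean(g$X[nucleus_mask]), mean(g$Y[nucleus_mask]))

  # principal axis of the cell mask (largest-eigenvalue direction)
  cc <- cbind(cx - mean(cx), cy - mean(cy))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))

  d_cell_pos <- march_to_edge(cell_mask, ctr_nuc, axis, pixel_size)
  d_cell_neg <- march_to_edge(cell_mask, ctr_nuc, -axis, pixel_size)
  d_nuc_pos <- march_to_edge(nucleus_mask, ctr_nuc, axis, pixel_size)
  d_nuc_neg <- march_to_edge(nucleus_mask, ctr_nuc, -axis, pixel_size)
  edge_pos <- d_cell_pos - d_nuc_pos
  edge_neg <- d_cell_neg - d_nuc_neg

  tie <- abs(edge_pos - edge_neg) < pixel_size / 4
  if (tie) {
    # symmetric cell: deterministically call the negative side the rear
    rear_dir <- -axis; rear_edge <- edge_neg; front_edge <- edge_pos
    d_rear <- d_cell_neg; d_front <- d_cell_pos
    message("rear/front tie: rear assigned to the negative axis direction")
  } else if (edge_neg < edge_pos) {
    rear_dir <- -axis; rear_edge <- edge_neg; front_edge <- edge_pos
    d_rear <- d_cell_neg; d_front <- d_cell_pos
  } else {
    rear_dir <- axis; rear_edge <- edge_pos; front_edge <- edge_neg
    d_rear <- d_cell_pos; d_front <- d_cell_neg
  }
  front_dir <- -rear_dir

  # nucleus touching the cell boundary: warn but keep the distances
  if (min(edge_pos, edge_neg) < pixel_size / 2)
    warning("nucleus touches the cell boundary along the axis",
            call. = FALSE)

  structure(
    list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
         axis = front_dir, centroid = ctr_nuc,
         rear_point = ctr_nuc + d_rear * rear_dir,
         front_point = ctr_nuc + d_front * front_dir,
         rear_distance = rear_edge, front_distance = front_edge,
         pixel_size = pixel_size, tie = tie),
    class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "<cell_geometry> rear %.2f um, front %.2f um (nucleus edge to cell edge)%s\n",
    x$rear_distance, x$front_distance, if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Rear-over-front intensity ratio
#'
#' Cell pixels are partitioned by the line through the nucleus centroid
#' perpendicular to the polarity axis; the ratio is the mean intensity of
#' the rear partition over the mean intensity of the front partition.
#' Background pixels never enter either mean.
#'
#' @param image a [cell_image()].
#' @param geometry a [compute_geometry()] result.
#' @param channel channel to measure (default `"signal"`).
#' @return rear/front intensity ratio (dimensionless).
#' @export
rear_front_ratio <- function(image, geometry, channel = "signal") {
  if (!inherits(geometry, "cell_geometry"))
    abort_param("`geometry` must come from compute_geometry()")
  im <- get_channel(image, channel)
  if (!all(dim(im) == dim(geometry$cell_mask)))
    abort_param("image and geometry dimensions differ")
  g <- coord_grids(dim(im), geometry$pixel_size)
  s <- (g$X - geometry$centroid[1]) * geometry$axis[1] +
       (g$Y - geometry$centroid[2]) * geometry$axis[2]
  rear <- geometry$cell_mask & s < 0
  front <- geometry$cell_mask & s > 0
  if (!any(rear) || !any(front))
    abort("empty rear or front partition", "dcmotion_geometry_error")
  mean(im[rear]) / mean(im[front])
}

#' Width-averaged axial intensity profile
#'
#' Intensity along the polarity axis, averaged at each axial offset over
#' the full width of the cell: pixels are projected onto the axis, binned
#' at one pixel size from the chosen end (rear-most or front-most point),
#' and averaged per bin over valid cell pixels only; the profile is then
#' normalized to the per-cell maximum (so every cell's maximum is 1).
#'
#' @param image a [cell_image()].
#' @param geometry a [compute_geometry()] result.
#' @param channel channel to measure (default `"signal"`).
#' @param from_end `"rear"` or `"front"`: the reference end; offsets
#'   increase into the cell.
#' @param length profile length in um (default 25).
#' @return A `line_profile` data.frame with columns `offset_um`
#'   (bin centres from the reference end), `intensity` (normalized) and
#'   `n_pixels`; truncated with a warning if the cell is shorter than
#'   `length`.
#' @export
width_averaged_profile <- function(image, geometry, channel = "signal",
                                   from_end = c("rear", "front"),
                                   length = 25) {
  from_end <- match.arg(from_end)
  if (!inherits(geometry, "cell_geometry"))
    abort_param("`geometry` must come from compute_geometry()")
  check_scalar(length, "length", lower = 1e-12)
  im <- get_channel(image, channel)
  px <- geometry$pixel_size
  g <- coord_grids(dim(im), px)
  ref <- if (from_end == "rear") geometry$rear_point else geometry$front_point
  inward <- if (from_end == "rear") geometry$axis else -geometry$axis
  proj <- (g$X - ref[1]) * inward[1] + (g$Y - ref[2]) * inward[2]
  m <- geometry$cell_mask
  extent <- max(proj[m])
  n_bins <- round(length / px)
  if (extent < length) {
    warning(sprintf(
      "cell extent %.1f um shorter than profile length %g um; truncated",
      extent, length), call. = FALSE)
    n_bins <- max(1L, floor(extent / px))
  }
  vals <- numeric(n_bins); npx <- integer(n_bins)
  bin <- ceiling(proj / px)
  for (k in seq_len(n_bins)) {
    sel <- m & bin == k
    npx[k] <- sum(sel)
    vals[k] <- if (npx[k]) mean(im[sel]) else NA_real_
  }
  if (npx[1] == 0L)
    abort("no valid cell pixels at offset 0", "dcmotion_geometry_error")
  vals <- vals / max(vals, na.rm = TRUE)
  out <- data.frame(offset_um = (seq_len(n_bins) - 0.5) * px,
                    intensity = vals, n_pixels = npx)
  attr(out, "from_end") <- from_end
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Average line profiles across cells
#'
#' Per-offset mean and SEM of per-cell normalized profiles (each profile
#' is normalized before averaging; the group mean itself is not
#' re-normalized).
#'
#' @param profiles list of [width_averaged_profile()] results with equal
#'   binning.
#' @return data.frame with `offset_um`, `mean_intensity`, `sem` and
#'   `n_cells` per offset.
#' @export
aggregate_profiles <- function(profiles) {
  if (!length(profiles)) abort_data("no profiles to aggregate")
  n_bins <- max(vapply(profiles, nrow, integer(1)))
  px <- profiles[[1]]$offset_um[1] * 2
  mat <- vapply(profiles, function(p) {
    v <- rep(NA_real_, n_bins); v[seq_len(nrow(p))] <- p$intensity; v
  }, numeric(n_bins))
  mat <- matrix(mat, nrow = n_bins)
  nc <- rowSums(!is.na(mat))
  data.frame(
    offset_um = (seq_len(n_bins) - 0.5) * px,
    mean_intensity = rowMeans(mat, na.rm = TRUE),
    sem = apply(mat, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    }),
    n_cells = nc)
}

# shared thresholded connected-component counting
count_components <- function(im, region, min_area_px, threshold) {
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(im[region])
    if (diff(rng) <= 0) return(0L)
    rng[1] + EBImage::otsu(
      EBImage::Image((im - rng[1]) / diff(rng)), range = c(0, 1)) * diff(rng)
  } else threshold
  fg <- im > thr & region
  if (!any(fg)) return(0L)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  areas <- tabulate(lab[lab > 0])
  sum(areas >= min_area_px)
}

#' Count foci per unit cell area
#'
#' Thresholds the channel within the cell mask, counts connected
#' components of at least `min_area` and reports the density per square
#' micrometre of mask area — the "foci per cell area" readout of
#' proximity-ligation imaging.
#'
#' @param image a [cell_image()].
#' @param cell_mask binary matrix.
#' @param channel channel holding the foci (default `"signal"`).
#' @param min_area minimum focus area in um^2 (default 0: all components).
#' @param threshold `"otsu"` (within the mask) or a numeric intensity.
#' @return list with `count`, `area_um2` (mask area) and `density`
#'   (foci per um^2).
#' @export
count_foci <- function(image, cell_mask, channel = "signal", min_area = 0,
                       threshold = "otsu") {
  im <- get_channel(image, channel)
  if (!all(dim(im) == dim(cell_mask)))
    abort_param("image and mask dimensions differ")
  check_scalar(min_area, "min_area", lower = 0)
  cell_mask <- cell_mask > 0
  if (!any(cell_mask)) abort_data("empty cell mask")
  px_area <- image$pixel_size^2
  cnt <- count_components(im, cell_mask, min_area / px_area, threshold)
  area <- sum(cell_mask) * px_area
  list(count = cnt, area_um2 = area, density = cnt / area)
}

#' Count objects inside an arbitrary region
#'
#' Threshold-and-count within a region of interest (for example a fixed-
#' area annulus around a tumour spheroid, or the spheroid mask itself).
#'
#' @param image a [cell_image()].
#' @param region binary matrix (the region of interest).
#' @param channel channel to threshold (default `"signal"`).
#' @param min_area minimum object area in um^2.
#' @param threshold `"otsu"` (within the region) or a numeric intensity.
#' @return integer object count.
#' @export
count_objects_in_region <- function(image, region, channel = "signal",
                                    min_area = 0, threshold = "otsu") {
  im <- get_channel(image, channel)
  if (!all(dim(im) == dim(region)))
    abort_param("image and region dimensions differ")
  check_scalar(min_area, "min_area", lower = 0)
  region <- region > 0
  if (!any(region)) return(0L)
  count_components(im, region, min_area / image$pixel_size^2, threshold)
}

#' Annulus region mask
#'
#' Convenience constructor for a circular-band region of fixed area
#' around a point (e.g. the collagen band surrounding a spheroid).
#'
#' @param dims `c(rows, cols)` of the target image.
#' @param center `c(x, y)` centre in um (image convention).
#' @param r_inner,r_outer inner and outer radii in um.
#' @param pixel_size um/px.
#' @return binary matrix.
#' @export
annulus_mask <- function(dims, center, r_inner, r_outer, pixel_size) {
  check_scalar(r_inner, "r_inner", lower = 0)
  check_scalar(r_outer, "r_outer", lower = 1e-12)
  if (r_outer <= r_inner) abort_param("`r_outer` must exceed `r_inner`")
  g <- coord_grids(dims, pixel_size)
  d2 <- (g$X - center[1])^2 + (g$Y - center[2])^2
  d2 > r_inner^2 & d2 <= r_outer^2
}
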