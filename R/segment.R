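#' Normalize a slice to the unit intensity range
#'
#' Affine rescaling of the slice intensities so that the minimum maps to 0
#' and the maximum to 1. The intensity order is preserved, so downstream
#' histogram thresholding and GLM t-statistics are invariant to the native
#' scanner scaling.
#'
#' @param slice A [phantom_slice()].
#' @return A `phantom_slice` with intensities in `[0, 1]`.
#' @export
normalize_slice <- function(slice) {
  stopifnot(inherits(slice, "phantom_slice"))
  rng <- range(slice$intensities)
  if (rng[1] == rng[2]) {
    stop("cannot normalize a constant image", call. = FALSE)
  }
  slice$intensities <- (slice$intensities - rng[1]) / (rng[2] - rng[1])
  slice
}

#' Segment the inner contrast disk and locate its centroid
#'
#' Implements the mask-building front end of the LCOD pipeline: the
#' normalized slice is binarized by Otsu's histogram threshold (256 bins),
#' connected foreground components are labeled, and the component that is
#' both nearest the image center and closest in equivalent radius to the
#' expected inner-disk radius is selected (ties broken toward larger area).
#' Internal holes are filled before the centroid is taken, so the
#' low-contrast holes cannot bias it. The center of gravity (COG) is the
#' unweighted sub-pixel centroid of the filled binary mask.
#'
#' Candidates whose equivalent radius `sqrt(area / pi)` (in mm) falls outside
#' +/-20% of `layout$inner_disk_radius_mm` are rejected; if none survives,
#' segmentation fails with a diagnostic table of all components.
#'
#' @param slice A normalized [phantom_slice()] (see [normalize_slice()]).
#' @param layout A [phantom_layout()].
#' @param radius_tolerance Allowed relative deviation of the equivalent
#'   radius from the expected inner-disk radius (default 0.2).
#' @return A `disk_mask`: `mask` (logical matrix), `cog_rowcol_px`
#'   (sub-pixel centroid), `equivalent_radius_mm`, `pixel_spacing_mm`,
#'   `components` (diagnostic tibble).
#' @export
segment_inner_disk <- function(slice, layout = phantom_layout(),
                               radius_tolerance = 0.2) {
  stopifnot(inherits(slice, "phantom_slice"))
  img <- slice$intensities
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("segment_inner_disk expects a normalized slice; call normalize_slice first",
         call. = FALSE)
  }
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  bw <- EBImage::Image(img > thr)
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  n_comp <- max(labm)
  if (n_comp < 1L) {
    stop("segmentation failure: no foreground component above threshold",
         call. = FALSE)
  }
  sp <- slice$pixel_spacing_mm
  px_area_mm2 <- sp[1] * sp[2]
  keep <- which(labm > 0)
  lab_v <- as.integer(labm[keep])
  rows_v <- ((keep - 1L) %% nrow(labm)) + 1L
  cols_v <- ((keep - 1L) %/% nrow(labm)) + 1L
  area <- tabulate(lab_v, nbins = n_comp)
  stats_tbl <- tibble::tibble(
    label = seq_len(n_comp),
    area_px = area,
    cog_row = as.vector(rowsum(as.numeric(rows_v), lab_v)) / area,
    cog_col = as.vector(rowsum(as.numeric(cols_v), lab_v)) / area
  )
  stats_tbl <- stats_tbl[stats_tbl$area_px > 0, ]
  ctr <- (dim(img) + 1) / 2
  stats_tbl <- dplyr::mutate(
    stats_tbl,
    equivalent_radius_mm = sqrt(.data$area_px * px_area_mm2 / pi),
    center_dist_px = sqrt((.data$cog_row - ctr[1])^2 +
                            (.data$cog_col - ctr[2])^2),
    radius_dev = abs(.data$equivalent_radius_mm - layout$inner_disk_radius_mm) /
      layout$inner_disk_radius_mm
  )
  cand <- dplyr::filter(stats_tbl, .data$radius_dev <= radius_tolerance)
  if (nrow(cand) == 0L) {
    stop(paste0(
      "segmentation failure: no component within ",
      round(100 * radius_tolerance),
      "% of the expected inner-disk radius (",
      layout$inner_disk_radius_mm, " mm); components found:\n",
      paste(utils::capture.output(print(as.data.frame(stats_tbl))),
            collapse = "\n")
    ), call. = FALSE)
  }
  cand <- dplyr::arrange(cand, .data$center_dist_px, dplyr::desc(.data$area_px))
  sel <- cand$label[1]
  mask_img <- EBImage::fillHull(EBImage::Image(labm == sel))
  mask <- EBImage::imageData(mask_img) > 0
  on_px <- which(mask)
  cog <- c(mean(((on_px - 1L) %% nrow(mask)) + 1L),
           mean(((on_px - 1L) %/% nrow(mask)) + 1L))
  structure(
    list(
      mask = mask,
      cog_rowcol_px = cog,
      equivalent_radius_mm = sqrt(sum(mask) * px_area_mm2 / pi),
      pixel_spacing_mm = sp,
      components = stats_tbl
    ),
    class = "disk_mask"
  )
}

#' @export
print.disk_mask <- function(x, ...) {
  cat(sprintf(
    "<disk_mask> %d px, COG (%.2f, %.2f), equivalent radius %.1f mm\n",
    sum(x$mask), x$cog_rowcol_px[1], x$cog_rowcol_px[2],
    x$equivalent_radius_mm))
  invisible(x)
}
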