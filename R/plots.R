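#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial profile
#'
#' Intensity against radius for one extracted profile; if a
#' [build_spoke_template()] is supplied, the hole supports are shaded so
#' profile/template alignment can be judged by eye.
#'
#' @param object A `radial_profile`.
#' @param template Optional `spoke_template` on the same grid.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, template = NULL, ...) {
  df <- tibble::tibble(
    radius_mm = seq(0, object$physical_length_mm,
                    length.out = object$n_samples),
    intensity = object$samples
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$radius_mm, .data$intensity))
  if (!is.null(template)) {
    spec <- template$spec
    holes <- tibble::tibble(
      xmin = spec$hole_centers_mm - spec$diameter_mm / 2,
      xmax = spec$hole_centers_mm + spec$diameter_mm / 2
    )
    p <- p + ggplot2::geom_rect(
      data = holes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.2
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(
      x = "radius from disk COG (mm)", y = "normalized intensity",
      title = sprintf("Radial profile at %.1f deg", object$angle_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an LCOD study as a pass/fail spoke map
#'
#' One tile per spoke and slice, filled by pass/fail, annotated with the
#' per-slice counts. The standard report companion to [score_volume()].
#'
#' @param object An `lcod_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lcod_study
#' @export
autoplot.lcod_study <- function(object, ...) {
  tbl <- tidy(object)
  spokes <- dplyr::distinct(tbl, .data$slice, .data$spoke, .data$spoke_pass)
  counts <- glance_counts(object)
  ggplot2::ggplot(spokes,
                  ggplot2::aes(.data$spoke, factor(.data$slice),
                               fill = .data$spoke_pass)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(
      data = counts,
      ggplot2::aes(x = 11.2, y = factor(.data$slice),
                   label = paste0(.data$n_pass, "/10")),
      inherit.aes = FALSE, hjust = 0, size = 3.4
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey85"),
      labels = c(`TRUE` = "pass", `FALSE` = "fail"), name = NULL
    ) +
    ggplot2::scale_x_continuous(breaks = 1:10, limits = c(0.5, 12.5)) +
    ggplot2::labs(
      x = "spoke (7 mm → 1.5 mm holes)", y = "slice",
      title = sprintf("LCOD score %d / 40", object$total)
    ) +
    ggplot2::theme_minimal()
}

glance_counts <- function(study) {
  tibble::tibble(
    slice = vapply(study$slices, `[[`, integer(1), "slice_index_1based"),
    n_pass = vapply(study$slices, `[[`, numeric(1), "n_pass")
  )
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot: per-item differences against means, with the bias line
#'   (blue) and the 1.96-SD limits of agreement (red).
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(
    mean = attr(object, "means"),
    difference = attr(object, "differences")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff,
                        linetype = "dashed", color = "blue") +
    ggplot2::geom_hline(yintercept = c(object$lower_limit,
                                       object$upper_limit),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "mean of the two scores",
                  y = "difference between scores") +
    ggplot2::theme_minimal()
}

#' QC overlay of a segmented slice
#'
#' Renders the slice with the disk-mask boundary and COG marker, the visual
#' check that segmentation locked onto the contrast insert.
#'
#' @param slice A normalized [phantom_slice()].
#' @param mask Its [segment_inner_disk()] result.
#' @return A ggplot.
#' @export
plot_segmentation <- function(slice, mask) {
  img <- slice$intensities
  df <- tibble::tibble(
    row = as.vector(row(img)),
    col = as.vector(col(img)),
    intensity = as.vector(img)
  )
  edge <- mask$mask & !EBImage::imageData(
    EBImage::erode(EBImage::Image(mask$mask * 1),
                   EBImage::makeBrush(3, "box"))) > 0
  edf <- tibble::tibble(row = row(img)[edge], col = col(img)[edge])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = edf, color = "red", size = 0.1) +
    ggplot2::annotate("point", x = mask$cog_rowcol_px[2],
                      y = mask$cog_rowcol_px[1], color = "yellow",
                      shape = 3, size = 3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
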