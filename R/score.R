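#' Score one LCOD slice
#'
#' Runs the full detection chain on a slice: normalize to `[0, 1]`, segment
#' the inner contrast disk, evaluate all 10 spokes with angular/jitter
#' search, pool the 30 per-hole p-values, apply the Benjamini-Hochberg
#' step-up at the Bonferroni-derived per-slice level (default
#' 0.05 / 4 = 0.0125), and count passing spokes. A hole passes when its
#' p-value is BH-rejected; a spoke passes when all three of its holes pass.
#'
#' A segmentation failure does not abort the study: the slice scores 0 and
#' is flagged (`failed = TRUE` with the failure message), mirroring how a
#' human reader records an unreadable sheet.
#'
#' @param slice A [phantom_slice()] (raw units; normalized internally). Must
#'   be one of the layout's LCOD slices.
#' @param layout A [phantom_layout()].
#' @param config A [detection_config()].
#' @return An `lcod_slice` result: `holes` (30-row tibble with per-hole
#'   `beta`, `t`, `p`, `pass`), `spokes` (10-row tibble), `n_pass`,
#'   `bh_level_used`, `failed`, plus segmentation provenance.
#' @export
score_slice <- function(slice, layout = phantom_layout(),
                        config = detection_config()) {
  stopifnot(inherits(slice, "phantom_slice"))
  idx <- slice$slice_index_1based
  if (!idx %in% layout$lcod_slice_indices_1based) {
    stop("slice ", idx, " is not an LCOD slice", call. = FALSE)
  }
  seg <- tryCatch({
    norm <- normalize_slice(slice)
    list(norm = norm, mask = segment_inner_disk(norm, layout))
  }, error = function(e) e)
  if (inherits(seg, "error")) {
    warning("slice ", idx, " scored 0: ", conditionMessage(seg),
            call. = FALSE)
    return(new_lcod_slice(
      idx, holes = empty_holes_tbl(), config = config,
      failed = TRUE, failure_message = conditionMessage(seg)
    ))
  }
  rows <- purrr::map_dfr(seq_len(layout$n_spokes), function(k) {
    spec <- spoke_spec(k, idx, layout)
    glm <- evaluate_spoke(seg$norm, seg$mask, spec, layout, config)
    tibble::tibble(
      spoke = k,
      hole = seq_len(layout$holes_per_spoke),
      radius_mm = spec$hole_centers_mm,
      diameter_mm = spec$diameter_mm,
      nominal_angle_deg = spec$nominal_angle_deg,
      angle_deg = glm$angle_deg,
      jitter_samples = glm$jitter_samples,
      beta = glm$betas,
      t = glm$t_stats,
      p = glm$p_values
    )
  })
  rows$pass <- benjamini_hochberg(rows$p, config$per_slice_alpha)
  new_lcod_slice(idx, holes = rows, config = config,
                 cog_rowcol_px = seg$mask$cog_rowcol_px,
                 equivalent_radius_mm = seg$mask$equivalent_radius_mm)
}

empty_holes_tbl <- function() {
  tibble::tibble(
    spoke = integer(), hole = integer(), radius_mm = numeric(),
    diameter_mm = numeric(), nominal_angle_deg = numeric(),
    angle_deg = numeric(), jitter_samples = integer(),
    beta = numeric(), t = numeric(), p = numeric(), pass = logical()
  )
}

new_lcod_slice <- function(slice_index, holes, config,
                           failed = FALSE, failure_message = NULL,
                           cog_rowcol_px = NULL,
                           equivalent_radius_mm = NULL) {
  spokes <- if (nrow(holes)) {
    dplyr::summarise(dplyr::group_by(holes, .data$spoke),
                     spoke_pass = all(.data$pass), .groups = "drop")
  } else {
    tibble::tibble(spoke = integer(), spoke_pass = logical())
  }
  n_pass <- count_passes(spokes$spoke_pass, config$scoring_mode)
  structure(
    list(
      slice_index_1based = as.integer(slice_index),
      holes = holes,
      spokes = spokes,
      n_pass = n_pass,
      bh_level_used = config$per_slice_alpha,
      scoring_mode = config$scoring_mode,
      failed = failed,
      failure_message = failure_message,
      cog_rowcol_px = cog_rowcol_px,
      equivalent_radius_mm = equivalent_radius_mm
    ),
    class = "lcod_slice"
  )
}

count_passes <- function(spoke_pass, mode) {
  if (!length(spoke_pass)) return(0L)
  switch(mode,
    "all-passing" = sum(spoke_pass),
    "acr-consecutive" = {
      first_fail <- match(FALSE, spoke_pass, nomatch = length(spoke_pass) + 1L)
      first_fail - 1L
    },
    stop("unknown scoring mode: ", mode)
  )
}

#' @export
print.lcod_slice <- function(x, ...) {
  cat(sprintf("<lcod_slice> slice %d: %d/%d spokes pass (BH q = %.4g, %s)%s\n",
              x$slice_index_1based, x$n_pass, max(10L, nrow(x$spokes)),
              x$bh_level_used, x$scoring_mode,
              if (x$failed) " [SEGMENTATION FAILED]" else ""))
  invisible(x)
}

#' Score a full LCOD study
#'
#' Scores slices 8--11 of a phantom volume with [score_slice()] and sums the
#' per-slice spoke counts into the 0--40 study total. When slice 7 is
#' present its SNR is attached via [compute_snr()]. The result is
#' deterministic: identical input and configuration always yield the
#' identical report.
#'
#' @param volume A [phantom_volume()] containing slices 8--11 (slice 7
#'   optional, for SNR).
#' @param layout A [phantom_layout()].
#' @param config A [detection_config()].
#' @return An `lcod_study`: `slices` (list of `lcod_slice`), `total`
#'   (0--40), `snr` (or `NA`), `config`, `layout` and a `config_digest`
#'   provenance hash. Use [generics::tidy()] / [generics::glance()] for
#'   tabular views.
#' @examples
#' \donttest{
#' vol <- simulate_volume(simulation_config(seed = 1, snr = 200))
#' study <- score_volume(vol)
#' glance(study)
#' }
#' @export
score_volume <- function(volume, layout = phantom_layout(),
                         config = detection_config()) {
  stopifnot(inherits(volume, "phantom_volume"))
  pairs <- lcod_slices(volume, layout)
  slices <- lapply(pairs$slice, score_slice, layout = layout, config = config)
  snr <- if (7L %in% slice_indices(volume)) {
    tryCatch(compute_snr(get_slice(volume, 7L)),
             error = function(e) {
               warning("SNR not computed: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  } else {
    NA_real_
  }
  structure(
    list(
      slices = slices,
      total = as.integer(sum(vapply(slices, `[[`, numeric(1), "n_pass"))),
      snr = snr,
      contrasts_pct = pairs$contrast_pct,
      config = config,
      layout = layout,
      config_digest = rlang::hash(list(config, layout))
    ),
    class = "lcod_study"
  )
}

#' @export
print.lcod_study <- function(x, ...) {
  cat(sprintf("<lcod_study> total %d / %d\n",
              x$total, 10L * length(x$slices)))
  for (s in x$slices) {
    cat(sprintf("  slice %2d (%.1f%% contrast): %d/10%s\n",
                s$slice_index_1based,
                x$contrasts_pct[match(s$slice_index_1based,
                                      vapply(x$slices, `[[`, integer(1),
                                             "slice_index_1based"))],
                s$n_pass, if (s$failed) " [failed]" else ""))
  }
  if (is.finite(x$snr)) cat(sprintf("  SNR (slice 7): %.1f\n", x$snr))
  cat("  config digest: ", x$config_digest, "\n", sep = "")
  invisible(x)
}

#' Image signal-to-noise ratio from slice 7
#'
#' SNR is the mean signal in a circular region of interest in the central
#' portion of the phantom (radius one half of the segmented phantom radius)
#' divided by the standard deviation of the background noise, pooled over
#' four corner boxes (each one sixteenth of the image width) lying fully
#' outside the phantom. The ratio is invariant to constant intensity
#' rescaling. Corner boxes that would touch the phantom are shrunk; a
#' noise-free background returns `Inf` with a warning.
#'
#' @param slice A [phantom_slice()] of the uniform phantom section
#'   (slice 7 of the standard series).
#' @return SNR (unitless scalar).
#' @export
compute_snr <- function(slice) {
  stopifnot(inherits(slice, "phantom_slice"))
  img <- slice$intensities
  norm <- normalize_slice(slice)
  thr <- EBImage::otsu(EBImage::Image(norm$intensities),
                       range = c(0, 1), levels = 256)
  bw <- EBImage::Image(norm$intensities > thr)
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  if (max(lab) < 1L) stop("phantom not segmentable", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  body <- EBImage::imageData(
    EBImage::fillHull(EBImage::Image(lab == which.max(areas)))) > 0
  rows <- row(img); cols <- col(img)
  cog <- c(mean(rows[body]), mean(cols[body]))
  r_px <- sqrt(sum(body) / pi)
  roi <- ((rows - cog[1])^2 + (cols - cog[2])^2) <= (0.5 * r_px)^2
  signal <- mean(img[roi])
  side <- max(4L, floor(ncol(img) / 16))
  repeat {
    boxes <- corner_boxes(dim(img), side)
    touches <- any(vapply(boxes, function(b) any(body[b$rows, b$cols]),
                          logical(1)))
    if (!touches) break
    side <- side - 2L
    if (side < 2L) {
      stop("corner noise boxes cannot avoid the phantom", call. = FALSE)
    }
  }
  noise_px <- unlist(lapply(boxes, function(b) img[b$rows, b$cols]))
  noise <- stats::sd(noise_px)
  if (noise == 0) {
    warning("zero background noise; SNR is infinite", call. = FALSE)
    return(Inf)
  }
  signal / noise
}

corner_boxes <- function(dims, side) {
  nr <- dims[1]; nc <- dims[2]
  list(
    list(rows = 1:side, cols = 1:side),
    list(rows = 1:side, cols = (nc - side + 1):nc),
    list(rows = (nr - side + 1):nr, cols = 1:side),
    list(rows = (nr - side + 1):nr, cols = (nc - side + 1):nc)
  )
}
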