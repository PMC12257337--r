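#' Configuration of a synthetic LCOD phantom acquisition
#'
#' Parameterizes the simulator that renders ground-truth LCOD slices with
#' the structure the detector assumes: an outer phantom body, the inner
#' contrast disk delimited by a thin dark membrane ring (the plastic sheet
#' rim that lets histogram thresholding isolate the insert), 30 anti-aliased
#' holes per sheet at the standard radii and diameters, and configurable
#' contrast, noise, rotation, translation and smooth intensity
#' non-uniformity. Defaults follow the reference acquisition: 256 x 256
#' matrix over a 250 mm field of view, per-slice contrasts
#' 1.4/2.5/3.6/5.1 % on slices 8--11.
#'
#' @param matrix_size Image matrix size in pixels.
#' @param fov_mm Field of view in mm (square).
#' @param disk_radius_mm Inner contrast-disk radius (mm).
#' @param phantom_radius_mm Outer phantom body radius (mm).
#' @param background_intensity Noise-free body intensity (arbitrary units).
#' @param slice_contrasts_pct Hole/background contrasts in percent for
#'   slices 8--11, in slice order.
#' @param snr Target image SNR; the additive noise sigma is
#'   `background_intensity / snr`. `Inf` disables noise.
#' @param noise_model `"gaussian"` (default) or `"rician"`
#'   (magnitude-reconstruction noise; at SNR of 100 and above the two are
#'   nearly indistinguishable).
#' @param rotation_deg In-plane rotation of the hole pattern (clockwise
#'   degrees), emulating phantom set-up rotation.
#' @param translation_px `(row, col)` offset of the phantom center from the
#'   image center, in pixels.
#' @param bias_field Coefficients `(u, v, u^2, uv, v^2)` of a multiplicative
#'   second-order polynomial shading field in normalized image coordinates
#'   `u, v` in `[-1, 1]`, or `NULL` for none.
#' @param base_angles_deg Per-slice spoke-1 angles (named by slice index);
#'   defaults to the layout convention of 90 degrees.
#' @param hole_polarity `1` (default) renders holes hyperintense relative to
#'   the membrane background, `-1` hypointense.
#' @param ring_width_mm,ring_intensity_frac Width and relative intensity of
#'   the membrane ring at the inner-disk boundary.
#' @param seed Integer RNG seed; slice noise is derived deterministically
#'   from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(matrix_size = 256L,
                              fov_mm = 250,
                              disk_radius_mm = 45,
                              phantom_radius_mm = 95,
                              background_intensity = 0.6,
                              slice_contrasts_pct = c(1.4, 2.5, 3.6, 5.1),
                              snr = 200,
                              noise_model = c("gaussian", "rician"),
                              rotation_deg = 0,
                              translation_px = c(0, 0),
                              bias_field = NULL,
                              base_angles_deg = c(`8` = 90, `9` = 90,
                                                  `10` = 90, `11` = 90),
                              hole_polarity = 1,
                              ring_width_mm = 2,
                              ring_intensity_frac = 0.15,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    matrix_size >= 32L, fov_mm > 0,
    disk_radius_mm > 38 + 3.5,
    phantom_radius_mm > disk_radius_mm,
    background_intensity > 0,
    length(slice_contrasts_pct) == 4L, all(slice_contrasts_pct >= 0),
    snr > 0,
    hole_polarity %in% c(-1, 1),
    ring_width_mm >= 0, ring_intensity_frac >= 0, ring_intensity_frac <= 1
  )
  structure(
    list(
      matrix_size = as.integer(matrix_size),
      fov_mm = fov_mm,
      disk_radius_mm = disk_radius_mm,
      phantom_radius_mm = phantom_radius_mm,
      background_intensity = background_intensity,
      slice_contrasts_pct = slice_contrasts_pct,
      snr = snr,
      noise_model = noise_model,
      rotation_deg = rotation_deg,
      translation_px = rep_len(as.numeric(translation_px), 2L),
      bias_field = bias_field,
      base_angles_deg = base_angles_deg,
      hole_polarity = hole_polarity,
      ring_width_mm = ring_width_mm,
      ring_intensity_frac = ring_intensity_frac,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# linear edge coverage: ~fraction of a pixel inside a circle of radius R,
# for pixels whose center sits at distance `dist`
edge_coverage <- function(dist, R, px) {
  out <- pmin(1, pmax(0, (R - dist) / px + 0.5))
  dim(out) <- dim(dist)
  out
}

#' Simulate one LCOD slice
#'
#' Renders the noise-free phantom structure (body, membrane ring, holes with
#' 4 x 4 sub-pixel anti-aliased edges), applies rotation / translation /
#' bias field per the config, then adds seeded noise. Holes sit at intensity
#' `background * (1 + polarity * contrast)`. The RNG seed is derived from
#' `config$seed` and the slice index, so volumes are reproducible and slices
#' mutually independent.
#'
#' @param config A [simulation_config()].
#' @param slice_index_1based LCOD slice index, 8--11 (or 7 for the uniform
#'   SNR slice).
#' @return A list: `slice` (a [phantom_slice()]) and `truth` (tibble of hole
#'   centers in pixel coordinates with diameters, angle, contrast).
#' @export
simulate_slice <- function(config, slice_index_1based) {
  stopifnot(inherits(config, "simulation_config"))
  if (!slice_index_1based %in% 7:11) {
    stop("slice_index_1based must be in 7..11", call. = FALSE)
  }
  n <- config$matrix_size
  spacing <- config$fov_mm / n
  ctr <- (n + 1) / 2 + config$translation_px
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist_mm <- sqrt(((rows - ctr[1]) * spacing)^2 +
                    ((cols - ctr[2]) * spacing)^2)
  img <- config$background_intensity *
    edge_coverage(dist_mm, config$phantom_radius_mm, spacing)
  truth <- tibble::tibble(
    spoke = integer(), hole = integer(), row_px = numeric(),
    col_px = numeric(), radius_mm = numeric(), diameter_mm = numeric(),
    angle_deg = numeric()
  )
  contrast <- 0
  if (slice_index_1based >= 8L) {
    # membrane ring isolating the contrast disk
    if (config$ring_width_mm > 0) {
      annulus <- edge_coverage(dist_mm, config$disk_radius_mm +
                                 config$ring_width_mm, spacing) -
        edge_coverage(dist_mm, config$disk_radius_mm, spacing)
      img <- img * (1 - annulus * (1 - config$ring_intensity_frac))
    }
    contrast <- config$slice_contrasts_pct[slice_index_1based - 7L] / 100
    base <- config$base_angles_deg[[as.character(slice_index_1based)]]
    layout <- phantom_layout()
    for (k in seq_len(layout$n_spokes)) {
      ang <- base - (k - 1) * layout$spoke_angle_step_deg + config$rotation_deg
      d <- hole_diameter(k, layout)
      dirn <- ray_direction(ang)
      for (h in seq_len(layout$holes_per_spoke)) {
        r_mm <- layout$hole_radial_centers_mm[h]
        hc <- ctr + r_mm * dirn / spacing
        img <- add_hole(img, hc, d / 2, spacing,
                        config$background_intensity * contrast *
                          config$hole_polarity)
        truth <- tibble::add_row(
          truth, spoke = k, hole = h, row_px = hc[1], col_px = hc[2],
          radius_mm = r_mm, diameter_mm = d, angle_deg = ang %% 360
        )
      }
    }
  }
  if (!is.null(config$bias_field)) {
    b <- rep_len(config$bias_field, 5L)
    u <- (cols - (n + 1) / 2) / (n / 2)
    v <- (rows - (n + 1) / 2) / (n / 2)
    img <- img * (1 + b[1] * u + b[2] * v + b[3] * u^2 + b[4] * u * v +
                    b[5] * v^2)
  }
  if (is.finite(config$snr)) {
    sigma <- config$background_intensity / config$snr
    seed_slice <- (config$seed %% 2000000L) * 1000L + slice_index_1based
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed_slice)
    if (config$noise_model == "gaussian") {
      img <- img + matrix(stats::rnorm(n * n, 0, sigma), n, n)
    } else {
      img <- sqrt((img + matrix(stats::rnorm(n * n, 0, sigma), n, n))^2 +
                    matrix(stats::rnorm(n * n, 0, sigma), n, n)^2)
    }
  }
  list(
    slice = phantom_slice(img, spacing, slice_index_1based,
                          meta = list(simulated = TRUE,
                                      contrast_pct = contrast * 100,
                                      rotation_deg = config$rotation_deg)),
    truth = truth
  )
}

# add a disk of given amplitude with 4x4 sub-pixel area-weighted edges
add_hole <- function(img, center_px, radius_mm, spacing, amplitude) {
  r_px <- radius_mm / spacing
  rr <- max(1L, floor(center_px[1] - r_px - 1)):
    min(nrow(img), ceiling(center_px[1] + r_px + 1))
  cc <- max(1L, floor(center_px[2] - r_px - 1)):
    min(ncol(img), ceiling(center_px[2] + r_px + 1))
  sub <- (seq_len(4) - 2.5) / 4
  cov <- matrix(0, length(rr), length(cc))
  for (dr in sub) {
    for (dc in sub) {
      d2 <- outer((rr + dr - center_px[1])^2, (cc + dc - center_px[2])^2, "+")
      cov <- cov + (d2 <= r_px^2)
    }
  }
  img[rr, cc] <- img[rr, cc] + amplitude * cov / 16
  img
}

#' Simulate a phantom volume with slices 7--11
#'
#' Slice 7 is the uniform phantom section used for SNR measurement; slices
#' 8--11 carry the LCOD sheets at the configured contrasts (default
#' 1.4/2.5/3.6/5.1 %, increasing toward slice 11). Noise is independent
#' across slices and fully determined by the config seed.
#'
#' @param config A [simulation_config()].
#' @return A [phantom_volume()]; per-slice ground truth is attached as
#'   `meta$truth` (named by slice index) alongside the config.
#' @examples
#' vol <- simulate_volume(simulation_config(seed = 7, snr = 300))
#' @export
simulate_volume <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  sims <- lapply(7:11, simulate_slice, config = config)
  phantom_volume(
    lapply(sims, `[[`, "slice"),
    meta = list(
      truth = stats::setNames(lapply(sims, `[[`, "truth"), 7:11),
      simulation_config = config
    )
  )
}
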