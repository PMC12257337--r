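# Vectorized bilinear interpolation of img at fractional (row, col)
# positions; points outside the pixel-center grid return NA.
bilinear_sample <- function(img, rp, cp) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- rp >= 1 & rp <= nr & cp >= 1 & cp <= nc
  out <- rep(NA_real_, length(rp))
  rp <- rp[ok]; cp <- cp[ok]
  i0 <- pmin(floor(rp), nr - 1L)
  j0 <- pmin(floor(cp), nc - 1L)
  fr <- rp - i0
  fc <- cp - j0
  base <- i0 + (j0 - 1) * nr
  out[ok] <- (1 - fr) * (1 - fc) * img[base] +
    fr * (1 - fc) * img[base + 1] +
    (1 - fr) * fc * img[base + nr] +
    fr * fc * img[base + nr + 1]
  out
}

# Clock-convention ray direction: 0 deg at image 12 o'clock, positive
# clockwise. Rows grow downward, so 12 o'clock is -row.
ray_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(row = -cos(a), col = sin(a))
}

#' Cast a radial ray from the disk centroid
#'
#' Samples the slice along a ray from the mask COG at `angle_deg`, in steps
#' of half the pixel pitch with bilinear interpolation, and truncates at the
#' first step that leaves the segmented disk (the disk edge, where the
#' normalized intensity drops toward zero). The raw profile is later
#' resampled to the fixed detection grid by [resample_profile()].
#'
#' @param slice A normalized [phantom_slice()].
#' @param mask A [segment_inner_disk()] result for the same slice.
#' @param angle_deg Ray direction in the clock convention (0 = 12 o'clock,
#'   positive clockwise).
#' @param min_length_mm Shortest acceptable truncation radius; defaults to
#'   the outer edge of the outermost 7 mm hole (38 + 3.5 mm). A shorter ray
#'   means the profile cannot contain all three holes and is an error.
#' @return A `raw_profile`: `samples`, `step_mm`, `physical_length_mm`,
#'   `angle_deg`, `origin_rowcol_px`.
#' @export
cast_ray <- function(slice, mask, angle_deg, min_length_mm = 41.5) {
  out <- cast_rays(slice, mask, angle_deg, min_length_mm)[[1]]
  if (inherits(out, "error")) stop(out)
  out
}

# batched ray casting: one bilinear-interpolation call for all angles of a
# search fan. Returns a list of raw_profile or error condition objects.
cast_rays <- function(slice, mask, angles_deg, min_length_mm = 41.5) {
  stopifnot(inherits(slice, "phantom_slice"), inherits(mask, "disk_mask"))
  img <- slice$intensities
  sp <- slice$pixel_spacing_mm
  cog <- mask$cog_rowcol_px
  if (!isTRUE(mask$mask[round(cog[1]), round(cog[2])])) {
    stop("COG is not inside the mask", call. = FALSE)
  }
  step_mm <- min(sp) / 2
  # walk until the ray leaves the mask; the (near-circular) mask cannot
  # extend past ~1.5x its equivalent radius from the COG, so cap there
  max_steps <- ceiling(1.5 * mask$equivalent_radius_mm / step_mm) + 2L
  k <- 0:max_steps
  a <- angles_deg * pi / 180
  rr <- cog[1] + (k * step_mm / sp[1]) %o% (-cos(a))
  cc <- cog[2] + (k * step_mm / sp[2]) %o% sin(a)
  ri <- round(rr)
  ci <- round(cc)
  inside <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
  inside[inside] <- mask$mask[cbind(ri[inside], ci[inside])]
  n_in <- colSums(apply(inside * 1, 2, cumprod) > 0)
  # one interpolation pass for every in-mask sample of every ray
  sel <- which(rep(seq_along(k), length(a)) <= rep(n_in, each = length(k)))
  vals_all <- rep(NA_real_, length(rr))
  vals_all[sel] <- bilinear_sample(img, rr[sel], cc[sel])
  dim(vals_all) <- dim(rr)
  lapply(seq_along(a), function(j) {
    if (n_in[j] < 2L) {
      return(simpleError("ray leaves the mask immediately"))
    }
    len <- (n_in[j] - 1L) * step_mm
    if (len < min_length_mm) {
      return(simpleError(sprintf(
        "ray too short: truncated at %.1f mm, need >= %.1f mm (angle %.1f deg)",
        len, min_length_mm, angles_deg[j])))
    }
    structure(
      list(
        samples = vals_all[seq_len(n_in[j]), j],
        step_mm = step_mm,
        physical_length_mm = len,
        angle_deg = angles_deg[j],
        origin_rowcol_px = cog
      ),
      class = "raw_profile"
    )
  })
}

#' Resample a raw radial profile to the fixed detection grid
#'
#' Linear interpolation of the raw ray samples onto `n_samples` evenly
#' spaced points spanning `[0, physical_length_mm]`. With the default
#' 90 samples on a ~45 mm disk the grid resolution is about 0.5 mm, which
#' makes profiles from different fields of view and matrix sizes directly
#' comparable with the geometric templates.
#'
#' @param raw A [cast_ray()] result.
#' @param n_samples Number of output samples (default 90).
#' @return A `radial_profile`: `samples` (length `n_samples`),
#'   `sample_spacing_mm`, `physical_length_mm`, `angle_deg`,
#'   `origin_rowcol_px`.
#' @export
resample_profile <- function(raw, n_samples = 90L) {
  stopifnot(inherits(raw, "raw_profile"), length(raw$samples) >= 2L)
  r_raw <- (seq_along(raw$samples) - 1) * raw$step_mm
  r_out <- seq(0, raw$physical_length_mm, length.out = n_samples)
  vals <- stats::approx(r_raw, raw$samples, xout = r_out)$y
  structure(
    list(
      samples = vals,
      n_samples = as.integer(n_samples),
      sample_spacing_mm = raw$physical_length_mm / (n_samples - 1),
      physical_length_mm = raw$physical_length_mm,
      angle_deg = raw$angle_deg,
      origin_rowcol_px = raw$origin_rowcol_px
    ),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf(
    "<radial_profile> %d samples, %.3f mm/sample, angle %.1f deg, span %.1f mm\n",
    x$n_samples, x$sample_spacing_mm, x$angle_deg, x$physical_length_mm))
  invisible(x)
}

#' Integer-shift (jitter) variants of a profile
#'
#' Residual geometric error (distortion, sub-pixel COG error) can misalign a
#' profile with its template by a sample or two. Jittering shifts the profile
#' by every integer offset in `-max_shift..max_shift` (default 5 samples,
#' about 2.5 mm); the detection search keeps the best-aligned variant.
#' Vacated edge samples are filled by replicating the boundary value, which
#' cannot mimic hole contrast the way zero-padding would.
#'
#' @param profile A [resample_profile()] result.
#' @param max_shift Maximum absolute shift in samples (default 5).
#' @return A list of `2 * max_shift + 1` numeric vectors named by shift
#'   (`"-5"` .. `"5"`); the `"0"` element is the input samples unchanged.
#' @export
jitter_variants <- function(profile, max_shift = 5L) {
  stopifnot(inherits(profile, "radial_profile"))
  n <- profile$n_samples
  if (max_shift < 0L || max_shift >= n / 4) {
    stop("max_shift must be in 0..n_samples/4", call. = FALSE)
  }
  x <- profile$samples
  shifts <- (-max_shift):max_shift
  out <- lapply(shifts, function(s) shift_replicate(x, s))
  names(out) <- as.character(shifts)
  out
}

# shift x by s samples (positive: toward larger radius), replicating edges
shift_replicate <- function(x, s) {
  n <- length(x)
  if (s == 0) return(x)
  if (s > 0) c(rep(x[1], s), x[seq_len(n - s)])
  else c(x[seq.int(1 - s, n)], rep(x[n], -s))
}
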