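#' Geometric layout of the large ACR phantom LCOD insert
#'
#' The low-contrast object detectability (LCOD) insert of the large ACR
#' phantom consists of four plastic sheets imaged on slices 8--11 of the
#' standard 11-slice series. Each sheet carries 30 low-contrast holes in 10
#' radial spokes: three same-diameter holes per spoke at 12.5, 25 and 38 mm
#' from the insert center, with hole diameters shrinking clockwise from 7 mm
#' (spoke 1) to 1.5 mm (spoke 10). Hole depth grades the hole/background
#' contrast across sheets: 1.4, 2.5, 3.6 and 5.1 percent for slices 8--11.
#'
#' Angles use the clock convention: 0 degrees at image 12 o'clock, positive
#' clockwise, matching the clockwise spoke numbering. The physical angle of
#' spoke 1 on each sheet is not standardized in published protocols; the
#' default of 90 degrees (3 o'clock) for every slice is an assumption and
#' should be overridden (here or via [read_layout()]) to match your phantom's
#' orientation.
#'
#' @param n_spokes Number of spokes per sheet.
#' @param holes_per_spoke Holes per spoke.
#' @param hole_radial_centers_mm Radial distances (mm) of the three hole
#'   centers from the insert center, strictly increasing.
#' @param diameter_first_spoke_mm,diameter_last_spoke_mm Hole diameters (mm)
#'   of spokes 1 and `n_spokes`; intermediate spokes are linearly
#'   interpolated.
#' @param spoke_angle_step_deg Clockwise angular step between consecutive
#'   spokes (degrees).
#' @param per_slice_base_angle_deg Named numeric vector mapping LCOD slice
#'   index (as character) to the nominal angle of spoke 1 on that slice.
#' @param lcod_slice_indices_1based 1-based indices of the LCOD slices.
#' @param slice_contrasts_pct Named numeric vector mapping LCOD slice index
#'   to the nominal hole/background contrast in percent.
#' @param inner_disk_radius_mm Radius (mm) of the inner contrast disk; the
#'   physical span of the default 90-sample, 0.5 mm radial profile.
#'
#' @return An object of class `phantom_layout`.
#' @examples
#' layout <- phantom_layout()
#' hole_diameter(1, layout)
#' @export
phantom_layout <- function(n_spokes = 10L,
                           holes_per_spoke = 3L,
                           hole_radial_centers_mm = c(12.5, 25.0, 38.0),
                           diameter_first_spoke_mm = 7.0,
                           diameter_last_spoke_mm = 1.5,
                           spoke_angle_step_deg = 36.0,
                           per_slice_base_angle_deg = c(
                             `8` = 90, `9` = 90, `10` = 90, `11` = 90
                           ),
                           lcod_slice_indices_1based = 8:11,
                           slice_contrasts_pct = c(
                             `8` = 1.4, `9` = 2.5, `10` = 3.6, `11` = 5.1
                           ),
                           inner_disk_radius_mm = 45.0) {
  layout <- structure(
    list(
      n_spokes = as.integer(n_spokes),
      holes_per_spoke = as.integer(holes_per_spoke),
      hole_radial_centers_mm = as.numeric(hole_radial_centers_mm),
      diameter_first_spoke_mm = as.numeric(diameter_first_spoke_mm),
      diameter_last_spoke_mm = as.numeric(diameter_last_spoke_mm),
      spoke_angle_step_deg = as.numeric(spoke_angle_step_deg),
      per_slice_base_angle_deg = per_slice_base_angle_deg,
      lcod_slice_indices_1based = as.integer(lcod_slice_indices_1based),
      slice_contrasts_pct = slice_contrasts_pct,
      inner_disk_radius_mm = as.numeric(inner_disk_radius_mm)
    ),
    class = "phantom_layout"
  )
  validate_layout(layout)
}

validate_layout <- function(layout) {
  with(layout, {
    stopifnot(
      n_spokes >= 1L, holes_per_spoke >= 1L,
      length(hole_radial_centers_mm) == holes_per_spoke,
      all(diff(hole_radial_centers_mm) > 0),
      all(hole_radial_centers_mm < inner_disk_radius_mm),
      diameter_first_spoke_mm > 0, diameter_last_spoke_mm > 0,
      diameter_first_spoke_mm > diameter_last_spoke_mm
    )
    if (abs(n_spokes * spoke_angle_step_deg - 360) > 1e-9) {
      stop("spoke_angle_step_deg must tile the full circle: n_spokes * step = 360",
           call. = FALSE)
    }
    # hole supports along a spoke must not touch
    d <- diameter_first_spoke_mm
    if (any(diff(hole_radial_centers_mm) <= d)) {
      stop("hole supports overlap along the spoke: radial spacing must exceed ",
           "the largest diameter", call. = FALSE)
    }
    missing_angle <- setdiff(as.character(lcod_slice_indices_1based),
                             names(per_slice_base_angle_deg))
    if (length(missing_angle)) {
      stop("per_slice_base_angle_deg lacks slices: ",
           paste(missing_angle, collapse = ", "), call. = FALSE)
    }
    missing_con <- setdiff(as.character(lcod_slice_indices_1based),
                           names(slice_contrasts_pct))
    if (length(missing_con)) {
      stop("slice_contrasts_pct lacks slices: ",
           paste(missing_con, collapse = ", "), call. = FALSE)
    }
  })
  layout
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("<phantom_layout> large ACR LCOD insert\n")
  cat(sprintf("  %d spokes x %d holes; diameters %.1f -> %.1f mm (clockwise)\n",
              x$n_spokes, x$holes_per_spoke,
              x$diameter_first_spoke_mm, x$diameter_last_spoke_mm))
  cat(sprintf("  hole radii: %s mm; inner disk radius %.1f mm\n",
              paste(x$hole_radial_centers_mm, collapse = ", "),
              x$inner_disk_radius_mm))
  cat(sprintf("  LCOD slices %s with contrasts %s %%\n",
              paste(x$lcod_slice_indices_1based, collapse = ","),
              paste(x$slice_contrasts_pct, collapse = ", ")))
  invisible(x)
}

#' Read or write a phantom layout as a YAML config
#'
#' The layout ships with package defaults but every field is user-editable;
#' sites whose phantom orientation differs (in particular the per-slice
#' spoke-1 angles) should persist their own config.
#'
#' @param path File path of a YAML file holding `phantom_layout` fields.
#'   Fields omitted from the file keep their defaults. A complete template
#'   ships at `system.file("extdata", "default_layout.yaml",
#'   package = "acrlcod")`.
#' @return `read_layout()` returns a `phantom_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(phantom_layout))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown layout fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("per_slice_base_angle_deg", "slice_contrasts_pct")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  do.call(phantom_layout, vals)
}

#' @rdname read_layout
#' @param layout A `phantom_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "phantom_layout"))
  x <- unclass(layout)
  x$per_slice_base_angle_deg <- as.list(x$per_slice_base_angle_deg)
  x$slice_contrasts_pct <- as.list(x$slice_contrasts_pct)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Hole diameter of a spoke
#'
#' Diameters shrink linearly with clockwise spoke number, from 7 mm at
#' spoke 1 to 1.5 mm at spoke 10 by default:
#' `d(k) = d1 - (k - 1) * (d1 - d10) / (n_spokes - 1)`.
#'
#' @param spoke_index Spoke number, 1 to `layout$n_spokes`.
#' @param layout A [phantom_layout()].
#' @return Diameter in mm.
#' @examples
#' hole_diameter(10, phantom_layout())  # 1.5
#' @export
hole_diameter <- function(spoke_index, layout = phantom_layout()) {
  if (any(spoke_index < 1L | spoke_index > layout$n_spokes) ||
      any(spoke_index != round(spoke_index))) {
    stop("spoke_index must be an integer in 1..", layout$n_spokes,
         call. = FALSE)
  }
  step <- (layout$diameter_first_spoke_mm - layout$diameter_last_spoke_mm) /
    (layout$n_spokes - 1)
  layout$diameter_first_spoke_mm - (spoke_index - 1) * step
}

#' Geometric specification of one spoke on one LCOD slice
#'
#' @inheritParams hole_diameter
#' @param slice_index_1based One of `layout$lcod_slice_indices_1based`.
#' @return A `spoke_spec` list: `spoke_index`, `diameter_mm`,
#'   `nominal_angle_deg` (clock convention, reduced to `[0, 360)`),
#'   `hole_centers_mm`.
#' @export
spoke_spec <- function(spoke_index, slice_index_1based,
                       layout = phantom_layout()) {
  if (!slice_index_1based %in% layout$lcod_slice_indices_1based) {
    stop("slice ", slice_index_1based, " is not an LCOD slice (",
         paste(layout$lcod_slice_indices_1based, collapse = ", "), ")",
         call. = FALSE)
  }
  d <- hole_diameter(spoke_index, layout)
  base <- layout$per_slice_base_angle_deg[[as.character(slice_index_1based)]]
  ang <- (base - (spoke_index - 1) * layout$spoke_angle_step_deg) %% 360
  structure(
    list(
      spoke_index = as.integer(spoke_index),
      slice_index_1based = as.integer(slice_index_1based),
      diameter_mm = d,
      nominal_angle_deg = ang,
      hole_centers_mm = layout$hole_radial_centers_mm
    ),
    class = "spoke_spec"
  )
}

#' Build the 1-D detection template for a spoke
#'
#' Places one binary indicator column per hole on the radial sample grid of a
#' profile, plus an orthogonalized polynomial nuisance basis (constant,
#' linear, quadratic) that absorbs smooth intensity non-uniformity. Sample
#' `j` (0-based) sits at radius `r_j = j * profile_length_mm / (n_samples-1)`;
#' indicator `i` is 1 where `|r_j - center_i| <= diameter / 2`. Boundary
#' samples are included whole, not fractionally weighted: at the default
#' 0.5 mm grid the fractional coverage at the two edge samples is negligible
#' next to the hole interior.
#'
#' @param spec A [spoke_spec()].
#' @param profile_length_mm Physical span of the profile (mm); must reach
#'   past the outer edge of the outermost hole.
#' @param n_samples Number of profile samples (default 90).
#' @return A `spoke_template`: `hole_indicators` (`n_samples` x 3 binary
#'   matrix), `nuisance_basis` (`n_samples` x 3), `radii_mm`,
#'   `sample_spacing_mm`, `spec`.
#' @export
build_spoke_template <- function(spec, profile_length_mm, n_samples = 90L) {
  stopifnot(inherits(spec, "spoke_spec"), n_samples >= 30L)
  outer_edge <- max(spec$hole_centers_mm) + spec$diameter_mm / 2
  if (profile_length_mm < outer_edge) {
    stop(sprintf(
      "profile length %.1f mm cannot contain the outermost hole (edge at %.1f mm)",
      profile_length_mm, outer_edge), call. = FALSE)
  }
  r <- seq(0, profile_length_mm, length.out = n_samples)
  ind <- vapply(
    spec$hole_centers_mm,
    function(cen) as.numeric(abs(r - cen) <= spec$diameter_mm / 2),
    numeric(n_samples)
  )
  colnames(ind) <- paste0("hole", seq_along(spec$hole_centers_mm))
  nuis <- poly_nuisance_basis(n_samples)
  structure(
    list(
      hole_indicators = ind,
      nuisance_basis = nuis,
      radii_mm = r,
      n_samples = as.integer(n_samples),
      sample_spacing_mm = profile_length_mm / (n_samples - 1),
      spec = spec
    ),
    class = "spoke_template"
  )
}

# Orthogonalized degree-0..2 basis on an evenly spaced grid. stats::poly is
# invariant to affine transforms of its input, so the basis depends only on
# the number of samples; cache it per grid length.
poly_cache <- new.env(parent = emptyenv())
poly_nuisance_basis <- function(n_samples) {
  key <- as.character(n_samples)
  if (is.null(poly_cache[[key]])) {
    nuis <- cbind(1, stats::poly(seq_len(n_samples), degree = 2))
    colnames(nuis) <- c("const", "linear", "quadratic")
    poly_cache[[key]] <- nuis
  }
  poly_cache[[key]]
}

#' Design matrix of a spoke template
#'
#' Binds the three hole indicators and three nuisance columns into the
#' `n_samples` x 6 GLM design.
#'
#' @param template A [build_spoke_template()] result.
#' @return Numeric matrix.
#' @export
template_design <- function(template) {
  stopifnot(inherits(template, "spoke_template"))
  cbind(template$hole_indicators, template$nuisance_basis)
}
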