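#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LCOD slice result
#'
#' @param x An `lcod_slice` from [score_slice()].
#' @param ... Unused.
#' @return A tibble with one row per hole (30 rows on success): `slice`,
#'   `spoke`, `hole`, geometry, selected `angle_deg` / `jitter_samples`,
#'   `beta`, `t`, `p`, `pass`, and the spoke-level `spoke_pass`.
#' @method tidy lcod_slice
#' @export
tidy.lcod_slice <- function(x, ...) {
  if (!nrow(x$holes)) {
    return(dplyr::mutate(empty_holes_tbl(), slice = integer(),
                         spoke_pass = logical(), .before = 1))
  }
  out <- dplyr::left_join(x$holes, x$spokes, by = "spoke")
  dplyr::mutate(out, slice = x$slice_index_1based, .before = 1)
}

#' @rdname tidy.lcod_slice
#' @method glance lcod_slice
#' @export
glance.lcod_slice <- function(x, ...) {
  tibble::tibble(
    slice = x$slice_index_1based,
    n_pass = as.integer(x$n_pass),
    bh_level = x$bh_level_used,
    scoring_mode = x$scoring_mode,
    failed = x$failed
  )
}

#' Tidy an LCOD study result
#'
#' @param x An `lcod_study` from [score_volume()].
#' @param ... Unused.
#' @return `tidy()`: the per-hole detection table across all four LCOD
#'   slices with the slice contrast attached. `glance()`: one row with the
#'   study `total` (0--40), per-slice counts, `snr` and config digest.
#' @method tidy lcod_study
#' @export
tidy.lcod_study <- function(x, ...) {
  tbl <- purrr::map_dfr(x$slices, tidy)
  slice_idx <- vapply(x$slices, `[[`, integer(1), "slice_index_1based")
  tbl$contrast_pct <- x$contrasts_pct[match(tbl$slice, slice_idx)]
  dplyr::relocate(tbl, "contrast_pct", .after = "slice")
}

#' @rdname tidy.lcod_study
#' @method glance lcod_study
#' @export
glance.lcod_study <- function(x, ...) {
  counts <- vapply(x$slices, `[[`, numeric(1), "n_pass")
  idx <- vapply(x$slices, `[[`, integer(1), "slice_index_1based")
  wide <- stats::setNames(as.list(as.integer(counts)),
                          paste0("n_pass_slice", idx))
  tibble::as_tibble(c(
    list(total = as.integer(sum(counts))),
    wide,
    list(snr = x$snr,
         any_failed = any(vapply(x$slices, `[[`, logical(1), "failed")),
         config_digest = x$config_digest)
  ))
}
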