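#' Construct a phantom slice
#'
#' A single axial slice of a phantom acquisition: a numeric intensity matrix
#' (row 1 at the image top) with its pixel spacing and 1-based ACR slice
#' index. Intensities are kept in native stored units; normalization to
#' `[0, 1]` happens downstream in [normalize_slice()].
#'
#' @param intensities Numeric matrix of image values.
#' @param pixel_spacing_mm Length-2 numeric `(row, col)` spacing in mm (a
#'   scalar is recycled).
#' @param slice_index_1based 1-based slice number in the ACR series.
#' @param meta Optional named list of acquisition tags.
#' @return An object of class `phantom_slice`.
#' @export
phantom_slice <- function(intensities, pixel_spacing_mm,
                          slice_index_1based, meta = list()) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (!all(is.finite(intensities))) {
    stop("slice intensities must be finite", call. = FALSE)
  }
  sp <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(sp <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  structure(
    list(
      intensities = intensities,
      pixel_spacing_mm = sp,
      slice_index_1based = as.integer(slice_index_1based),
      meta = meta
    ),
    class = "phantom_slice"
  )
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("<phantom_slice> %d x %d px, %.4g x %.4g mm/px, slice %d\n",
              nrow(x$intensities), ncol(x$intensities),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_index_1based))
  invisible(x)
}

#' Construct a phantom volume
#'
#' An ordered set of [phantom_slice()] objects indexed by their 1-based ACR
#' slice numbers. A standard large ACR series has 11 slices; partial volumes
#' are accepted as long as they can still carry the LCOD slices when scoring
#' is requested.
#'
#' @param slices List of `phantom_slice` objects with distinct slice indices.
#' @param meta Optional named list of series-level tags.
#' @return An object of class `phantom_volume`.
#' @export
phantom_volume <- function(slices, meta = list()) {
  stopifnot(length(slices) >= 1L,
            all(vapply(slices, inherits, logical(1), "phantom_slice")))
  idx <- vapply(slices, `[[`, integer(1), "slice_index_1based")
  if (anyDuplicated(idx)) stop("duplicate slice indices", call. = FALSE)
  slices <- slices[order(idx)]
  sp <- t(vapply(slices, `[[`, numeric(2), "pixel_spacing_mm"))
  if (any(abs(sweep(sp, 2, sp[1, ])) > 1e-6)) {
    stop("pixel spacing differs across slices", call. = FALSE)
  }
  structure(
    list(slices = slices, meta = meta),
    class = "phantom_volume"
  )
}

#' @export
print.phantom_volume <- function(x, ...) {
  idx <- slice_indices(x)
  cat(sprintf("<phantom_volume> %d slices (indices %s)\n",
              length(x$slices),
              paste(range(idx), collapse = "-")))
  invisible(x)
}

slice_indices <- function(volume) {
  vapply(volume$slices, `[[`, integer(1), "slice_index_1based")
}

#' Extract one slice by its ACR index
#'
#' @param volume A [phantom_volume()].
#' @param slice_index_1based 1-based ACR slice number.
#' @return A `phantom_slice`.
#' @export
get_slice <- function(volume, slice_index_1based) {
  idx <- slice_indices(volume)
  pos <- match(slice_index_1based, idx)
  if (is.na(pos)) {
    stop("slice ", slice_index_1based, " not present in volume", call. = FALSE)
  }
  volume$slices[[pos]]
}

#' Read a phantom acquisition from disk
#'
#' Reads a NIfTI volume (any extension RNifti accepts) into a
#' [phantom_volume()]. Slices are taken in stored array order along the
#' third dimension; `slice_order = "reverse"` flips that order for series
#' exported with slice 1 at the opposite end. 1-based ACR indices are
#' assigned from `first_slice_index` along the (possibly flipped) order.
#' Pixel spacing comes from the NIfTI header unless overridden.
#'
#' @param path Path to the volume file.
#' @param first_slice_index ACR index of the first stored slice (default 1;
#'   use e.g. 7 for a cropped volume holding slices 7--11).
#' @param slice_order `"stored"` or `"reverse"`.
#' @param pixel_spacing_mm Optional `(row, col)` spacing override in mm;
#'   required if the header carries no usable spacing.
#' @param require_lcod If `TRUE` (default), error unless slices 8--11 are all
#'   present; a short series otherwise only triggers a warning.
#' @return A `phantom_volume`.
#' @export
read_volume <- function(path, first_slice_index = 1L,
                        slice_order = c("stored", "reverse"),
                        pixel_spacing_mm = NULL,
                        require_lcod = TRUE) {
  slice_order <- match.arg(slice_order)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) {
    stop("expected a 3-D volume, got ", length(dim(arr)), " dimensions",
         call. = FALSE)
  }
  if (is.null(pixel_spacing_mm)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 2L || any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0)) {
      stop("no usable pixel spacing in header; supply pixel_spacing_mm",
           call. = FALSE)
    }
    pixel_spacing_mm <- pd[1:2]
  }
  ord <- seq_len(dim(arr)[3])
  if (slice_order == "reverse") ord <- rev(ord)
  slices <- lapply(seq_along(ord), function(i) {
    phantom_slice(arr[, , ord[i]], pixel_spacing_mm,
                  first_slice_index + i - 1L)
  })
  vol <- phantom_volume(slices, meta = list(path = path))
  have <- slice_indices(vol)
  missing_lcod <- setdiff(8:11, have)
  if (length(missing_lcod)) {
    msg <- paste0("LCOD slices ", paste(missing_lcod, collapse = ", "),
                  " not present")
    if (require_lcod) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (length(have) < 11L) {
    warning("volume has ", length(have),
            " slices; a standard ACR series has 11", call. = FALSE)
  }
  vol
}

#' Write a phantom volume to a NIfTI file
#'
#' Slices are stacked in increasing ACR index along the third dimension and
#' the pixel spacing is stored in the header. The ACR index of the first
#' slice is not representable in NIfTI; pass it back to [read_volume()] as
#' `first_slice_index` when re-reading a cropped volume.
#'
#' @param volume A [phantom_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "phantom_volume"))
  arrs <- lapply(volume$slices, `[[`, "intensities")
  arr <- array(unlist(arrs), dim = c(dim(arrs[[1]]), length(arrs)))
  sp <- volume$slices[[1]]$pixel_spacing_mm
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp[1], sp[2], 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Select the LCOD slices of a volume with their nominal contrasts
#'
#' @param volume A [phantom_volume()] containing slices 8--11.
#' @param layout A [phantom_layout()].
#' @return A tibble with columns `slice_index` (integer), `contrast_pct`
#'   (numeric) and `slice` (list of `phantom_slice`), one row per LCOD slice
#'   in slice order.
#' @export
lcod_slices <- function(volume, layout = phantom_layout()) {
  stopifnot(inherits(volume, "phantom_volume"))
  idx <- layout$lcod_slice_indices_1based
  missing <- setdiff(idx, slice_indices(volume))
  if (length(missing)) {
    stop("LCOD slice(s) missing from volume: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    slice_index = as.integer(idx),
    contrast_pct = unname(layout$slice_contrasts_pct[as.character(idx)]),
    slice = lapply(idx, function(i) get_slice(volume, i))
  )
}
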