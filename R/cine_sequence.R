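#' Cine-angiography sequence container
#'
#' A `cine_sequence` is the pipeline's universal input: an ordered stack of
#' 2-D grayscale frames (numeric matrices with identical dimensions, intensities
#' in `[0, 1]`), plus optional acquisition metadata. Radio-opaque structures
#' (contrast-filled vessels, catheter) are *dark*, as in standard angiographic
#' display.
#'
#' @param frames list of numeric matrices, all with identical dimensions;
#'   values must be finite and inside `[0, 1]`.
#' @param frame_rate optional frames/second (> 0).
#' @param pixel_spacing optional numeric length-2 vector, mm/pixel (row, col).
#' @param source_id opaque provenance string.
#' @return An object of class `cine_sequence`.
#' @examples
#' seq <- cine_sequence(list(matrix(0, 8, 8), matrix(1, 8, 8)))
#' length(seq$frames)
#' @export
cine_sequence <- function(frames, frame_rate = NULL, pixel_spacing = NULL,
                          source_id = "unknown") {
  if (!is.list(frames) || length(frames) < 2L)
    ct_input_error("a cine sequence needs at least 2 frames")
  if (!all(vapply(frames, is.matrix, logical(1))))
    ct_validation_error("all frames must be numeric matrices")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    ct_validation_error("all frames must share identical dimensions")
  vals_ok <- vapply(frames, function(f) all(is.finite(f)) && min(f) >= 0 && max(f) <= 1,
                    logical(1))
  if (!all(vals_ok))
    ct_validation_error("frame intensities must be finite and within [0, 1]")
  if (!is.null(frame_rate)) {
    if (!is_scalar_number(frame_rate) || frame_rate <= 0)
      ct_validation_error("frame_rate must be a positive scalar")
  }
  if (!is.null(pixel_spacing)) {
    if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 2L ||
        any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
      ct_validation_error("pixel_spacing must be two positive numbers (mm/px)")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         pixel_spacing = pixel_spacing, source_id = source_id),
    class = "cine_sequence"
  )
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cine_sequence> %d frames of %dx%d px", length(x$frames), d[1], d[2]))
  if (!is.null(x$frame_rate)) cat(sprintf(", %.3g fps", x$frame_rate))
  cat(sprintf("  [%s]\n", x$source_id))
  invisible(x)
}

#' @export
length.cine_sequence <- function(x) length(x$frames)

frame_dim <- function(sequence) dim(sequence$frames[[1]])

#' Normalize raw frame intensities to the unit interval
#'
#' Min-max normalization is *global* over the whole stack, not per-frame, so
#' that inter-frame brightness dynamics (the contrast bolus washing in and
#' out) survive normalization. Per-frame normalization would erase exactly the
#' signal the bolus detector needs.
#'
#' @param frames list of numeric matrices on an arbitrary common scale.
#' @return list of matrices with global min mapped to 0 and global max to 1.
#' @noRd
normalize_frames <- function(frames) {
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  if (!is.finite(lo) || !is.finite(hi))
    ct_format_error("non-finite intensities in input frames")
  if (hi <= lo)
    ct_input_error("degenerate constant sequence: min-max normalization undefined")
  lapply(frames, function(f) (f - lo) / (hi - lo))
}
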