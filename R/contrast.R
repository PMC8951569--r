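#' Per-frame vessel opacity curve
#'
#' Scores how visible the contrasted coronary tree is in each frame as the
#' pixel count of the cleaned vesselness mask. A count (rather than mean
#' intensity) is robust to global exposure drift: it directly measures how
#' much vessel-like structure is segmentable.
#'
#' @param sequence a [cine_sequence()].
#' @param params [frangi_params()] used for segmentation.
#' @param clean_params list with `threshold_strategy`, `min_component_px`,
#'   `closing_radius_px` (see [binarize_and_clean()]).
#' @return integer vector, one value >= 0 per frame.
#' @export
compute_opacity_curve <- function(sequence, params = frangi_params(),
                                  clean_params = list()) {
  stopifnot(inherits(sequence, "cine_sequence"))
  cp <- utils::modifyList(
    list(threshold_strategy = "otsu", min_component_px = 50L,
         closing_radius_px = 1L),
    clean_params)
  vapply(sequence$frames, function(f) {
    v <- frangi_vesselness(f, params)
    sum(binarize_and_clean(v, cp$threshold_strategy, cp$min_component_px,
                           cp$closing_radius_px))
  }, integer(1))
}

#' Contrast-bolus window
#'
#' Inclusive 0-based frame-index interval during which the vessels are
#' opacified: `start` is the first frame where dye appears, `end` the last
#' frame before washout.
#'
#' @param start,end 0-based inclusive frame indices, `start <= end`.
#' @param frame_count total frames in the sequence (for validation).
#' @export
contrast_window <- function(start, end, frame_count = Inf) {
  if (!is_scalar_count(start) || !is_scalar_count(end))
    ct_validation_error("window endpoints must be non-negative integers")
  if (start > end)
    ct_validation_error(sprintf("invalid contrast window: start %d > end %d", start, end))
  if (end >= frame_count)
    ct_validation_error(sprintf("window end %d outside sequence of %d frames",
                                end, frame_count))
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "contrast_window")
}

#' @export
print.contrast_window <- function(x, ...) {
  cat(sprintf("<contrast_window> frames %d..%d (inclusive, 0-based)\n", x$start, x$end))
  invisible(x)
}

#' Detect the contrast window from an opacity curve
#'
#' Thresholds the curve at `fraction * max(curve)` and returns the longest
#' contiguous run of frames at or above the threshold (ties broken by the
#' earliest run). The paper-style workflow identifies the first injected and
#' last pre-washout frame; this relative-threshold run rule is the package's
#' declared automatic criterion, and can always be overridden manually via
#' [apply_manual_window()].
#'
#' @param curve numeric vector of per-frame opacity scores (>= 0).
#' @param fraction threshold fraction of the curve maximum, in (0, 1).
#' @return a [contrast_window()].
#' @examples
#' detect_contrast_window(c(0, 0, 5, 9, 10, 9, 6, 0, 0), fraction = 0.3)
#' @export
detect_contrast_window <- function(curve, fraction = 0.3) {
  if (!is.numeric(curve) || length(curve) == 0L || any(curve < 0))
    ct_validation_error("curve must be a non-negative numeric vector")
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    ct_parameter_error("fraction must lie strictly inside (0, 1)")
  if (max(curve) <= 0)
    ct_detection_error("no contrast detected: opacity curve is all zero (supply a manual window)")
  thr <- fraction * max(curve)
  above <- curve >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max -> earliest of ties
  contrast_window(starts[best] - 1L, ends[best] - 1L, length(curve))
}

#' Merge an automatically detected window with manual endpoint overrides
#'
#' @param auto a [contrast_window()] or `NULL` when detection failed.
#' @param user_start,user_end optional 0-based overrides.
#' @param frame_count sequence length.
#' @return a valid [contrast_window()].
#' @export
apply_manual_window <- function(auto = NULL, user_start = NULL, user_end = NULL,
                                frame_count) {
  for (u in list(user_start, user_end))
    if (!is.null(u) && (!is_scalar_count(u) || u >= frame_count))
      ct_validation_error("manual window endpoints must be frame indices within the sequence")
  if (is.null(auto) && (is.null(user_start) || is.null(user_end)))
    ct_validation_error("no automatic window: both manual endpoints are required")
  s <- if (!is.null(user_start)) user_start else auto$start
  e <- if (!is.null(user_end)) user_end else auto$end
  contrast_window(s, e, frame_count)
}

#' Indices of the dye-free frames given a contrast window
#'
#' By default only frames strictly before the window (the guaranteed
#' pre-injection cardiac cycle) are tracked; post-washout frames risk residual
#' dye and are excluded unless requested.
#'
#' @param window a [contrast_window()].
#' @param frame_count sequence length.
#' @param include_post_washout also return frames after `window$end`.
#' @return 0-based integer vector (possibly empty).
#' @export
dye_free_indices <- function(window, frame_count, include_post_washout = FALSE) {
  pre <- if (window$start > 0) 0:(window$start - 1L) else integer(0)
  post <- if (include_post_washout && window$end < frame_count - 1L)
    (window$end + 1L):(frame_count - 1L) else integer(0)
  as.integer(c(pre, post))
}
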