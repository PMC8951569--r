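#' Build the bank of segmented template frames
#'
#' Every frame inside the contrast window is segmented (vesselness,
#' binarization, cleanup) and stored as a template carrying its vessel mask,
#' its boundary contours, and a *background mask*: the complement of the
#' dilated vessel mask. Matching against dye-free frames is scored on the
#' background mask by default, because templates contain dye that dye-free
#' frames lack — comparing on (and around) the vessel pixels would bias every
#' score. The dilation excludes the dye-gradient halo around the lumen, so the
#' background region covers dye-independent anatomy (ribs, diaphragm,
#' catheter).
#'
#' Frames whose cleaned mask is empty (faintly opacified window edges) are
#' dropped with a warning rather than failing the bank.
#'
#' @param sequence a [cine_sequence()].
#' @param window a [contrast_window()].
#' @param params [frangi_params()] for segmentation.
#' @param clean_params list passed to [binarize_and_clean()] (see
#'   [compute_opacity_curve()] for defaults).
#' @param dilation_radius_px dilation of the vessel mask defining the
#'   background exclusion zone; default 5 px.
#' @return a `template_bank`: list with `templates` (each a `template_frame`
#'   holding `frame_index`, `image`, `mask`, `contour`, `background_mask`) and
#'   `window`.
#' @export
build_template_bank <- function(sequence, window, params = frangi_params(),
                                clean_params = list(), dilation_radius_px = 5L) {
  stopifnot(inherits(sequence, "cine_sequence"), inherits(window, "contrast_window"))
  if (!is_scalar_count(dilation_radius_px))
    ct_parameter_error("dilation_radius_px must be a count >= 0")
  n <- length(sequence$frames)
  if (window$end >= n)
    ct_validation_error("contrast window outside sequence")
  cp <- utils::modifyList(
    list(threshold_strategy = "otsu", min_component_px = 50L,
         closing_radius_px = 1L),
    clean_params)

  templates <- list()
  frame_px <- prod(frame_dim(sequence))
  for (idx in window$start:window$end) {
    img <- sequence$frames[[idx + 1L]]
    v <- frangi_vesselness(img, params)
    mask <- binarize_and_clean(v, cp$threshold_strategy, cp$min_component_px,
                               cp$closing_radius_px)
    if (!any(mask)) {
      ct_warn(sprintf("template frame %d dropped: empty vessel mask", idx))
      next
    }
    bg <- !dilate_mask(mask, dilation_radius_px)
    if (sum(bg) < 0.2 * frame_px)
      ct_warn(sprintf(
        "template frame %d: background region is only %.0f%% of the frame; matching quality may degrade",
        idx, 100 * sum(bg) / frame_px))
    templates[[length(templates) + 1L]] <- structure(
      list(frame_index = as.integer(idx), image = img, mask = mask,
           contour = extract_contours(mask, idx), background_mask = bg),
      class = "template_frame")
  }
  if (length(templates) == 0L)
    ct_bank_error("no usable template frames: every frame in the window segmented empty")
  structure(list(templates = templates, window = window), class = "template_bank")
}

#' Build a template bank from externally supplied vessel masks
#'
#' Bypasses segmentation: each frame in the window is paired with a given
#' binary mask (e.g. simulator ground truth, or cached masks from an earlier
#' run). Useful for isolating the matching stage from segmentation quality.
#'
#' @param sequence a [cine_sequence()].
#' @param window a [contrast_window()].
#' @param masks list of logical matrices, one per frame of the *whole*
#'   sequence (indexed by frame), or one per window frame.
#' @param dilation_radius_px background-mask dilation radius.
#' @return a `template_bank`.
#' @export
template_bank_from_masks <- function(sequence, window, masks,
                                     dilation_radius_px = 5L) {
  stopifnot(inherits(sequence, "cine_sequence"), inherits(window, "contrast_window"))
  n <- length(sequence$frames)
  idx <- window$start:window$end
  if (length(masks) == n) masks <- masks[idx + 1L]
  if (length(masks) != length(idx))
    ct_validation_error("need one mask per window frame (or per sequence frame)")
  templates <- list()
  for (k in seq_along(idx)) {
    mask <- masks[[k]] & TRUE
    if (!any(mask)) next
    templates[[length(templates) + 1L]] <- structure(
      list(frame_index = as.integer(idx[k]), image = sequence$frames[[idx[k] + 1L]],
           mask = mask, contour = extract_contours(mask, idx[k]),
           background_mask = !dilate_mask(mask, dilation_radius_px)),
      class = "template_frame")
  }
  if (length(templates) == 0L)
    ct_bank_error("no usable template frames: all masks empty")
  structure(list(templates = templates, window = window), class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d templates from frames %d..%d\n",
              length(x$templates), x$window$start, x$window$end))
  invisible(x)
}

#' Frame indices of a bank's templates (ascending)
#' @param bank a `template_bank`.
#' @export
bank_frame_indices <- function(bank) {
  vapply(bank$templates, function(t) t$frame_index, integer(1))
}

#' Serialize a template bank to a directory (inspection/caching)
#'
#' Writes per-template mask PNGs, contour JSON, and a manifest JSON.
#' @param bank a `template_bank`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_template_bank <- function(bank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in bank$templates) {
    stem <- file.path(dir, sprintf("template_%04d", t$frame_index))
    png::writePNG(t$mask * 1, paste0(stem, "_mask.png"))
    write_contours_json(list(t$contour), paste0(stem, "_contour.json"))
  }
  manifest <- list(
    window = list(start = bank$window$start, end = bank$window$end),
    frame_indices = bank_frame_indices(bank))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
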