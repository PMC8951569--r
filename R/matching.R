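#' Normalized cross-correlation between two frames
#'
#' Pearson correlation of the two images' intensities over the region pixels:
#' \deqn{r = \frac{\sum (a - \bar a)(b - \bar b)}
#'            {\sqrt{\sum (a - \bar a)^2 \sum (b - \bar b)^2}}}
#' with means taken over the region. Zero spatial lag: frames are compared
#' wholesale, with no translation search. The score is symmetric and invariant
#' to affine intensity rescaling of either input.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param region optional logical matrix (same dimensions, >= 2 `TRUE` pixels)
#'   restricting the comparison; `NULL` means all pixels.
#' @return scalar r in `[-1, 1]`.
#' @export
normalized_cross_correlation <- function(a, b, region = NULL) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b)))
    ct_validation_error("a and b must be matrices of identical dimensions")
  if (!is.null(region)) {
    if (!identical(dim(region), dim(a)))
      ct_validation_error("region must share the frame dimensions")
    if (sum(region) < 2L)
      ct_validation_error("region must contain at least 2 pixels")
    av <- a[region]; bv <- b[region]
  } else {
    av <- as.vector(a); bv <- as.vector(b)
  }
  av <- av - mean(av); bv <- bv - mean(bv)
  va <- sum(av * av); vb <- sum(bv * bv)
  if (va == 0 || vb == 0)
    ct_degenerate_error("zero intensity variance over the region")
  r <- sum(av * bv) / sqrt(va * vb)
  max(-1, min(1, r))
}

ncc_or_zero <- function(a, b, region, query_index, template_index) {
  tryCatch(
    normalized_cross_correlation(a, b, region),
    corotrack_degenerate_error = function(e) {
      ct_warn(sprintf("degenerate NCC (frame %s vs template %s): scored 0",
                      query_index, template_index))
      0
    })
}

#' Associate a dye-free frame with its most similar template
#'
#' Scores the query frame against every template by zero-lag normalized
#' cross-correlation and returns the arg-max. This similarity arg-max *is* the
#' cardiac-phase association: the template acquired at the same phase shows
#' the (moving) anatomy in the same configuration and therefore correlates
#' highest. Ties are broken by the lowest template frame index; degenerate
#' (zero-variance) comparisons score 0.
#'
#' @param query numeric matrix, same dimensions as the bank frames.
#' @param bank a `template_bank` from [build_template_bank()].
#' @param region_mode `"background"` (default: score on each template's
#'   dye-independent background mask) or `"full"` (all pixels).
#' @param query_index 0-based index of the query frame (provenance for the
#'   result and logs).
#' @return a `match_result`: list with `query_frame_index`,
#'   `best_template_index` (frame index of the winner), `score`, `all_scores`
#'   (named by template frame index), and `transferred_contour` (the winner's
#'   contour re-tagged with the query index).
#' @export
match_frame <- function(query, bank, region_mode = c("background", "full"),
                        query_index = NA_integer_) {
  region_mode <- match.arg(region_mode)
  if (!inherits(bank, "template_bank") || length(bank$templates) == 0L)
    ct_validation_error("bank must be a non-empty template_bank")
  if (!identical(dim(query), dim(bank$templates[[1]]$image)))
    ct_validation_error("query dimensions do not match the template bank")
  scores <- vapply(bank$templates, function(t) {
    region <- if (region_mode == "background") t$background_mask else NULL
    ncc_or_zero(query, t$image, region, query_index, t$frame_index)
  }, numeric(1))
  best <- which.max(scores)               # earliest index wins ties
  win <- bank$templates[[best]]
  contour <- win$contour
  contour$source_frame_index <- as.integer(query_index)
  structure(list(
    query_frame_index = as.integer(query_index),
    best_template_index = win$frame_index,
    score = scores[best],
    all_scores = stats::setNames(scores, bank_frame_indices(bank)),
    transferred_contour = contour
  ), class = "match_result")
}

#' Track the vessel contour through the dye-free frames
#'
#' Runs [match_frame()] for every requested dye-free frame, transferring the
#' winning template's vessel contour onto it.
#'
#' @param sequence a [cine_sequence()].
#' @param bank a `template_bank`.
#' @param dye_free_indices 0-based frame indices to track; must not intersect
#'   the bank's contrast window.
#' @param region_mode see [match_frame()].
#' @return list of `match_result`, in the order of `dye_free_indices`.
#' @export
track_sequence <- function(sequence, bank, dye_free_indices,
                           region_mode = c("background", "full")) {
  region_mode <- match.arg(region_mode)
  stopifnot(inherits(sequence, "cine_sequence"))
  n <- length(sequence$frames)
  if (length(dye_free_indices) == 0L) return(list())
  if (any(dye_free_indices < 0L) || any(dye_free_indices >= n))
    ct_validation_error("dye_free_indices outside the sequence")
  if (any(dye_free_indices >= bank$window$start & dye_free_indices <= bank$window$end))
    ct_validation_error("dye_free_indices must be disjoint from the contrast window")
  lapply(dye_free_indices, function(i)
    match_frame(sequence$frames[[i + 1L]], bank, region_mode, query_index = i))
}
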