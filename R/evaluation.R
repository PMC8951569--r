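#' Dice overlap coefficient between two binary masks
#'
#' \eqn{D = 2|A \cap B| / (|A| + |B|)}; defined as 1 when both masks are
#' empty.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b)))
    ct_validation_error("dice: masks must be matrices of identical dimensions")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate tracking results against synthetic ground truth
#'
#' For every tracked dye-free frame: Dice overlap between the filled
#' transferred contour and the true vessel mask, and whether the assigned
#' template's true cardiac phase is within `phase_tolerance` frames (modulo
#' the period) of the query frame's true phase. Also reports the signed error
#' of the detected bolus window endpoints.
#'
#' @param results list of `match_result` from [track_sequence()].
#' @param truth a `synthetic_ground_truth` from [generate_synthetic_cine()].
#' @param bank the `template_bank` used for tracking.
#' @param detected the detected [contrast_window()] (or `NULL` to omit window
#'   errors).
#' @param phase_tolerance allowed |assigned - true| phase difference in frames
#'   (cyclic); default 1, since exact-frame equality is too strict for a
#'   discretized continuous cycle.
#' @return a `tracking_report`: list with `per_frame_dice`, `mean_dice`,
#'   `phase_hit_rate`, `bolus_start_error`, `bolus_end_error`,
#'   `per_frame` (data.frame detail).
#' @export
evaluate_tracking <- function(results, truth, bank, detected = NULL,
                              phase_tolerance = 1L) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  P <- truth$period_frames
  n <- length(truth$true_masks)
  dims <- dim(truth$true_masks[[1]])

  if (length(results) == 0L) {
    rep <- list(per_frame_dice = numeric(0), mean_dice = NULL,
                phase_hit_rate = NULL,
                bolus_start_error = if (is.null(detected)) NULL else
                  detected$start - truth$true_bolus_window$start,
                bolus_end_error = if (is.null(detected)) NULL else
                  detected$end - truth$true_bolus_window$end,
                per_frame = data.frame())
    return(structure(rep, class = "tracking_report"))
  }

  qidx <- vapply(results, function(r) r$query_frame_index, integer(1))
  if (any(qidx < 0L) || any(qidx >= n))
    ct_validation_error("result frame indices inconsistent with ground truth")

  d <- numeric(length(results))
  hit <- logical(length(results))
  tmpl <- integer(length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    pred <- fill_contours(r$transferred_contour, dims)
    d[i] <- dice(pred, truth$true_masks[[qidx[i] + 1L]])
    assigned_phase <- truth$true_phase[r$best_template_index + 1L]
    true_phase <- truth$true_phase[qidx[i] + 1L]
    dphi <- abs(assigned_phase - true_phase) %% P
    dphi <- min(dphi, P - dphi)
    hit[i] <- dphi <= phase_tolerance
    tmpl[i] <- r$best_template_index
  }
  structure(list(
    per_frame_dice = d,
    mean_dice = mean(d),
    phase_hit_rate = mean(hit),
    bolus_start_error = if (is.null(detected)) NULL else
      detected$start - truth$true_bolus_window$start,
    bolus_end_error = if (is.null(detected)) NULL else
      detected$end - truth$true_bolus_window$end,
    per_frame = data.frame(query = qidx, template = tmpl, dice = d, phase_hit = hit)
  ), class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("<tracking_report>\n")
  if (length(x$per_frame_dice) == 0L) {
    cat("  no tracked frames\n")
  } else {
    cat(sprintf("  frames tracked : %d\n", length(x$per_frame_dice)))
    cat(sprintf("  mean Dice      : %.3f\n", x$mean_dice))
    cat(sprintf("  phase hit rate : %.3f\n", x$phase_hit_rate))
  }
  if (!is.null(x$bolus_start_error))
    cat(sprintf("  bolus window error: start %+d, end %+d frames\n",
                x$bolus_start_error, x$bolus_end_error))
  invisible(x)
}
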