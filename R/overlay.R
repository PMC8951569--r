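#' Overlay rendering style
#'
#' Default colors follow angiographic display convention: yellow for the
#' predicted (transferred) contour on dye-free frames, green for the reference
#' contour segmented from contrasted frames.
#'
#' @param predicted_color,reference_color RGB triples, components in 0..255.
#' @param line_thickness line thickness in pixels (>= 1).
#' @export
overlay_style <- function(predicted_color = c(255, 255, 0),
                          reference_color = c(0, 255, 0),
                          line_thickness = 1L) {
  for (col in list(predicted_color, reference_color))
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      ct_validation_error("colors must be RGB triples with components in [0, 255]")
  if (!is_scalar_count(line_thickness) || line_thickness < 1L)
    ct_validation_error("line_thickness must be an integer >= 1")
  structure(list(predicted_color = as.numeric(predicted_color),
                 reference_color = as.numeric(reference_color),
                 line_thickness = as.integer(line_thickness)),
            class = "overlay_style")
}

#' Pixels covered by rasterizing contour polylines
#'
#' Dense segment sampling (step 0.25 px) rounded to the pixel grid, thickened
#' by a disk of radius `(thickness - 1) / 2`.
#'
#' @return integer matrix with columns (row, col), 1-based, unique.
#' @noRd
rasterize_polylines <- function(polylines, dims, thickness = 1L) {
  pts_r <- numeric(0); pts_c <- numeric(0)
  for (pl in polylines) {
    if (is.null(pl) || nrow(pl) < 2L) next
    for (i in seq_len(nrow(pl) - 1L)) {
      p <- pl[i, ]; q <- pl[i + 1L, ]
      nstep <- max(1L, ceiling(max(abs(q - p)) / 0.25))
      tt <- seq(0, 1, length.out = nstep + 1L)
      pts_r <- c(pts_r, p[1] + tt * (q[1] - p[1]))
      pts_c <- c(pts_c, p[2] + tt * (q[2] - p[2]))
    }
  }
  if (length(pts_r) == 0L) return(matrix(integer(0), 0, 2))
  r <- pmin(dims[1] - 1L, pmax(0L, as.integer(floor(pts_r + 0.5))))
  c <- pmin(dims[2] - 1L, pmax(0L, as.integer(floor(pts_c + 0.5))))
  px <- unique(cbind(r, c))
  if (thickness > 1L) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[px + 1L] <- TRUE
    m <- dilate_mask(m, (thickness - 1) / 2)
    w <- which(m)
    px <- cbind(((w - 1L) %% dims[1]), ((w - 1L) %/% dims[1]))
  }
  px
}

check_contour_bounds <- function(contour, dims, frame_index) {
  polylines <- if (inherits(contour, "vessel_contour")) contour$polylines else contour
  for (pl in polylines) {
    if (is.null(pl) || nrow(pl) == 0L) next
    if (min(pl[, 1]) < -0.5 || max(pl[, 1]) > dims[1] - 0.5 ||
        min(pl[, 2]) < -0.5 || max(pl[, 2]) > dims[2] - 0.5)
      ct_validation_error(sprintf(
        "contour vertex outside frame bounds at frame %d", frame_index))
  }
}

#' Write frames with colored contour overlays as a PNG sequence
#'
#' Each output frame is the grayscale input replicated to RGB with the
#' predicted and/or reference contour polylines rasterized in the style
#' colors. The input sequence is not modified. Files are named
#' `frame_0000.png`, ... in `path`.
#'
#' @param sequence a [cine_sequence()].
#' @param contours_per_frame list with one element per frame; each element is
#'   a list with optional members `predicted` and `reference`, each a
#'   `vessel_contour` (or bare polyline list), or `NULL`/empty for no overlay.
#' @param style an [overlay_style()].
#' @param path output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_overlay <- function(sequence, contours_per_frame, style = overlay_style(),
                          path) {
  stopifnot(inherits(sequence, "cine_sequence"))
  n <- length(sequence$frames)
  if (length(contours_per_frame) != n)
    ct_validation_error("contours_per_frame must have one entry per frame")
  dims <- frame_dim(sequence)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(n)
  for (i in seq_len(n)) {
    g <- sequence$frames[[i]]
    img <- array(g, dim = c(dims[1], dims[2], 3L))
    sets <- contours_per_frame[[i]]
    for (role in c("reference", "predicted")) {
      ct <- sets[[role]]
      if (is.null(ct)) next
      check_contour_bounds(ct, dims, i - 1L)
      polylines <- if (inherits(ct, "vessel_contour")) ct$polylines else ct
      px <- rasterize_polylines(polylines, dims, style$line_thickness)
      if (nrow(px) == 0L) next
      col <- style[[paste0(role, "_color")]] / 255
      for (ch in 1:3)
        img[cbind(px[, 1] + 1L, px[, 2] + 1L, ch)] <- col[ch]
    }
    files[i] <- file.path(path, sprintf("frame_%04d.png", i - 1L))
    png::writePNG(img, files[i])
  }
  invisible(files)
}

#' Write per-frame contour polylines as JSON
#'
#' Shared interchange format: a list with one entry per frame, each holding
#' `frame_index` and `polylines` (arrays of `[row, col]` 0-based floats).
#'
#' @param contours list of `vessel_contour` objects (or `NULL`s).
#' @param path output file.
#' @export
write_contours_json <- function(contours, path) {
  out <- lapply(contours, function(ct) {
    if (is.null(ct)) return(list(frame_index = NULL, polylines = list()))
    list(frame_index = ct$source_frame_index,
         polylines = lapply(ct$polylines, function(pl) unname(as.matrix(pl))))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the JSON contour format back into `vessel_contour` objects
#' @param path JSON file written by [write_contours_json()].
#' @export
read_contours_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(entry) {
    polylines <- lapply(entry$polylines, function(pl) {
      m <- do.call(rbind, lapply(pl, function(v) as.numeric(unlist(v))))
      colnames(m) <- c("row", "col")
      m
    })
    structure(list(polylines = polylines,
                   source_frame_index = as.integer(
                     if (is.null(entry$frame_index)) -1L else entry$frame_index)),
              class = "vessel_contour")
  })
}
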