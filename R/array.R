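#' Compose a flanked stimulus array
#'
#' Places a left flanker, target and right flanker on one horizontal line,
#' centred in the flanked-task fixation box (6.4 x 2.9 degrees by default),
#' with the canonical edge-to-edge gap of 0.1 degrees (condensed) or 1.0
#' degrees (spaced). Under the reverse polarity condition the flankers'
#' contrast sign is flipped while the target is left unchanged.
#'
#' Gaps are measured edge-to-edge between ink bounding boxes; the canvas
#' width is snapped down by at most one pixel so the left and right margins
#' are exactly equal, which makes composition exactly mirror-symmetric.
#'
#' @param target,left_flanker,right_flanker [render_glyph()] objects sharing
#'   the target's raster height.
#' @param spacing_condition `"condensed"` (0.1 deg) or `"spaced"` (1.0 deg).
#' @param polarity_condition `"same"` or `"reverse"`.
#' @param geometry A [viewing_geometry()].
#' @param gap_deg Override the canonical gap (degrees, edge to edge).
#' @param fixation_box_deg Width/height of the fixation box in degrees.
#' @return An object of class `stimulus_array` containing the composed
#'   signed-contrast canvas and the placement metadata.
#' @export
build_array <- function(target, left_flanker, right_flanker,
                        spacing_condition = c("condensed", "spaced"),
                        polarity_condition = c("same", "reverse"),
                        geometry = viewing_geometry(), gap_deg = NULL,
                        fixation_box_deg = c(6.4, 2.9)) {
  spacing_condition <- match.arg(spacing_condition)
  polarity_condition <- match.arg(polarity_condition)
  stopifnot(inherits(target, "glyph"), inherits(left_flanker, "glyph"),
            inherits(right_flanker, "glyph"))
  if (nrow(left_flanker$raster) != nrow(target$raster) ||
      nrow(right_flanker$raster) != nrow(target$raster)) {
    stop("flanker rasters must match the target raster height",
         call. = FALSE)
  }
  if (is.null(gap_deg)) {
    gap_deg <- if (spacing_condition == "condensed") 0.1 else 1.0
  }
  if (polarity_condition == "reverse") {
    left_flanker <- .flip_polarity(left_flanker)
    right_flanker <- .flip_polarity(right_flanker)
  }

  trim <- function(g) {
    cr <- .ink_cols(g$raster)
    g$raster[, cr[1]:cr[2], drop = FALSE]
  }
  rl <- trim(left_flanker); rt <- trim(target); rr <- trim(right_flanker)
  gap_px <- deg_to_px(gap_deg, geometry)
  box_w <- deg_to_px(fixation_box_deg[1], geometry)
  box_h <- deg_to_px(fixation_box_deg[2], geometry)
  total_w <- ncol(rl) + ncol(rt) + ncol(rr) + 2L * gap_px
  h <- nrow(rt)
  if (total_w > box_w || h > box_h) {
    stop("geometry overflow: stimulus array exceeds the fixation box",
         call. = FALSE)
  }
  margin <- (box_w - total_w) %/% 2L
  canvas_w <- total_w + 2L * margin
  top <- (box_h - h) %/% 2L
  canvas <- matrix(0, box_h, canvas_w)
  x <- margin
  put <- function(canvas, r, x) {
    canvas[top + seq_len(nrow(r)), x + seq_len(ncol(r))] <-
      canvas[top + seq_len(nrow(r)), x + seq_len(ncol(r))] + r
    canvas
  }
  offsets <- c(left = x, target = x + ncol(rl) + gap_px,
               right = x + ncol(rl) + ncol(rt) + 2L * gap_px)
  canvas <- put(canvas, rl, offsets["left"])
  canvas <- put(canvas, rt, offsets["target"])
  canvas <- put(canvas, rr, offsets["right"])

  structure(
    list(target = target, left_flanker = left_flanker,
         right_flanker = right_flanker, gap_deg = gap_deg,
         spacing_condition = spacing_condition,
         polarity_condition = polarity_condition,
         fixation_box_deg = fixation_box_deg, canvas = canvas,
         offsets = offsets, gap_px = gap_px, geometry = geometry),
    class = "stimulus_array"
  )
}

.flip_polarity <- function(g) {
  g$raster <- -g$raster
  g$polarity <- -g$polarity
  g
}

#' Measured edge-to-edge ink gaps of a composed array
#'
#' @param array A [build_array()] result.
#' @return Named vector with the left and right gaps in pixels.
#' @export
measure_gaps <- function(array) {
  stopifnot(inherits(array, "stimulus_array"))
  ink <- which(colSums(abs(array$canvas)) > 0)
  runs <- split(ink, cumsum(c(1, diff(ink) != 1)))
  if (length(runs) != 3L) {
    stop("canvas does not contain three separated glyphs", call. = FALSE)
  }
  c(left = min(runs[[2]]) - max(runs[[1]]) - 1L,
    right = min(runs[[3]]) - max(runs[[2]]) - 1L)
}

#' @export
print.stimulus_array <- function(x, ...) {
  cat(sprintf(
    "<stimulus_array %s-%s-%s, %s/%s, gap %.2f deg, canvas %d x %d px>\n",
    x$left_flanker$symbol, x$target$symbol, x$right_flanker$symbol,
    x$spacing_condition, x$polarity_condition, x$gap_deg,
    nrow(x$canvas), ncol(x$canvas)))
  invisible(x)
}
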