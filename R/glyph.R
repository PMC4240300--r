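#' Permitted symbol sets for the flanked letter identification tasks
#'
#' The target alphabet is uppercase A--Z excluding I, J, O, Q, W and X
#' (20 letters). Flanker pools are the full uppercase alphabet (letter
#' flankers), the digits 2--9 (number flankers) and outline triangles at
#' three orientations (shape flankers).
#'
#' @return An object of class `alphabet_spec` with elements
#'   `permitted_targets`, `letters`, `digits` and `triangle_orientations`.
#' @examples
#' length(alphabet_spec()$permitted_targets) # 20
#' @export
alphabet_spec <- function() {
  structure(
    list(
      permitted_targets = setdiff(LETTERS, c("I", "J", "O", "Q", "W", "X")),
      letters = LETTERS,
      digits = as.character(2:9),
      # an equilateral outline is invariant under 120-degree rotation, so
      # distinct orientations must differ modulo 120
      triangle_orientations = c(0, 40, 80)
    ),
    class = "alphabet_spec"
  )
}

#' Render a single glyph as a signed-contrast raster
#'
#' Draws one symbol from the package's deterministic bitmap font at the
#' pixel size implied by the requested visual angle and viewing geometry.
#' Ink pixels carry the value `polarity` (+1 dark ink, -1 light ink) and
#' background pixels are 0, so that averaged composites of opposite-polarity
#' glyphs attenuate naturally.
#'
#' @param symbol Single character: an uppercase letter, a digit `"2"`--`"9"`,
#'   or `"triangle"` for the shape category.
#' @param category One of `"letter"`, `"digit"`, `"shape"`.
#' @param polarity `+1` or `-1`.
#' @param height_deg Glyph height in degrees of visual angle (default 1.2).
#' @param geometry A [viewing_geometry()].
#' @param orientation Triangle orientation in degrees (shapes only).
#' @param role `"target"` or `"flanker"`. The six letters excluded from the
#'   target set (I, J, O, Q, W, X) raise an error when requested as targets
#'   but are legal flankers.
#' @return An object of class `glyph`: a list with the raster (rows x cols,
#'   origin top-left), symbol metadata and pixel height.
#' @export
render_glyph <- function(symbol, category = c("letter", "digit", "shape"),
                         polarity = 1, height_deg = 1.2,
                         geometry = viewing_geometry(), orientation = 0,
                         role = c("target", "flanker")) {
  category <- match.arg(category)
  role <- match.arg(role)
  stopifnot(inherits(geometry, "viewing_geometry"),
            polarity %in% c(-1, 1), height_deg > 0)
  height_px <- max(7L, as.integer(round(
    deg_to_mm(height_deg, geometry$distance_mm) / geometry$pixel_pitch_mm)))
  if (category == "letter") {
    if (!symbol %in% LETTERS) {
      stop("unknown letter symbol: ", symbol, call. = FALSE)
    }
    if (role == "target" &&
        !symbol %in% alphabet_spec()$permitted_targets) {
      stop("excluded symbol: '", symbol,
           "' is not in the permitted target alphabet", call. = FALSE)
    }
    raster <- .scale_bitmap(.font5x7[[symbol]], height_px)
  } else if (category == "digit") {
    if (!symbol %in% as.character(2:9)) {
      stop("invalid flanker: digits must lie in 2-9, got ", symbol,
           call. = FALSE)
    }
    raster <- .scale_bitmap(.font5x7[[symbol]], height_px)
  } else {
    raster <- triangle_raster(height_px, orientation)
    symbol <- sprintf("triangle%d", as.integer(orientation) %% 360L)
  }
  structure(
    list(symbol = symbol, category = category, polarity = polarity,
         raster = raster * polarity, height_deg = height_deg,
         height_px = height_px),
    class = "glyph"
  )
}

#' @export
print.glyph <- function(x, ...) {
  cat(sprintf("<glyph '%s' (%s), polarity %+d, %d x %d px, %.2f deg>\n",
              x$symbol, x$category, x$polarity,
              nrow(x$raster), ncol(x$raster), x$height_deg))
  invisible(x)
}

# Column range containing ink; used for edge-to-edge gap placement.
.ink_cols <- function(raster) {
  cols <- which(colSums(abs(raster)) > 0)
  if (length(cols) == 0L) stop("blank raster", call. = FALSE)
  range(cols)
}
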