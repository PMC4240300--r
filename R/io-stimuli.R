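#' Export stimulus rasters
#'
#' Signed-contrast rasters are written as greyscale images with the
#' background at mid-grey: dark ink (+1) maps to black, light ink (-1) to
#' white. `write_pgm()` writes a plain-text PGM (P2); `write_png()` an
#' 8-bit PNG. `write_array_metadata()` writes the JSON sidecar describing
#' a composed array (symbols, gap, polarity, geometry).
#'
#' @param x A raster matrix, `glyph` or `stimulus_array`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pgm <- function(x, path) {
  r <- .as_raster(x)
  g <- round(127.5 * (1 - r))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
write_png <- function(x, path) {
  r <- .as_raster(x)
  png::writePNG((1 - r) / 2, path)
  invisible(path)
}

#' @param array A `stimulus_array`.
#' @rdname write_pgm
#' @export
write_array_metadata <- function(array, path) {
  stopifnot(inherits(array, "stimulus_array"))
  meta <- list(
    target = array$target$symbol,
    flanker_left = array$left_flanker$symbol,
    flanker_right = array$right_flanker$symbol,
    gap_deg = array$gap_deg,
    spacing_condition = array$spacing_condition,
    polarity_condition = array$polarity_condition,
    fixation_box_deg = array$fixation_box_deg,
    canvas_px = dim(array$canvas),
    geometry = list(distance_mm = array$geometry$distance_mm,
                    pixel_pitch_mm = array$geometry$pixel_pitch_mm)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
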