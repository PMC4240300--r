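#' Pixel-overlap similarity between two images
#'
#' The core similarity measure of the error analysis: a fuzzy Jaccard
#' coefficient on ink magnitude,
#' \deqn{S(a, b) = \frac{\sum_{ij} \min(|a_{ij}|, |b_{ij}|)}
#'                     {\sum_{ij} \max(|a_{ij}|, |b_{ij}|)},}
#' which reduces exactly to intersection-over-union pixel counting on binary
#' masks. Scores are symmetric, bounded in `[0, 1]`, equal 1 only for
#' magnitude-identical images and 0 only for disjoint ink supports.
#' Similarity is computed on contrast magnitude, so polarity enters the
#' analysis only through averaged composites, not through the metric.
#'
#' With `align = TRUE` (default) the second image is shifted by the
#' integer-pixel difference of the ink centres of mass before comparison
#' (letter identity, not position, drives the construct); half-pixel ties
#' round toward zero shift.
#'
#' @param image_a,image_b Signed-contrast rasters (matrices) or `glyph`
#'   objects.
#' @param align Centre-of-mass align before comparison?
#' @param metric `"jaccard"` (default, normalised) or `"intersection"`
#'   (raw overlapping ink, \eqn{\sum \min(|a|,|b|)}).
#' @return A single numeric similarity.
#' @export
pixel_overlap <- function(image_a, image_b, align = TRUE,
                          metric = c("jaccard", "intersection")) {
  metric <- match.arg(metric)
  a <- abs(.as_raster(image_a))
  b <- abs(.as_raster(image_b))
  if (sum(a) == 0 && sum(b) == 0) {
    stop("undefined similarity: both images are blank", call. = FALSE)
  }
  if (align && sum(a) > 0 && sum(b) > 0) {
    a <- .crop_ink(a)
    b <- .crop_ink(b)
    # integer shift aligning b's ink centre of mass onto a's; ties -> 0
    d <- .com(a) - .com(b)
    sh <- sign(d) * floor(abs(d) + 0.5 - 1e-12)
    # union extent of a at (0, 0) and b at sh
    i0 <- min(0, sh[1]); j0 <- min(0, sh[2])
    H <- max(nrow(a), nrow(b) + sh[1]) - i0
    W <- max(ncol(a), ncol(b) + sh[2]) - j0
    A <- matrix(0, H, W); B <- matrix(0, H, W)
    A[seq_len(nrow(a)) - i0, seq_len(ncol(a)) - j0] <- a
    B[seq_len(nrow(b)) + sh[1] - i0, seq_len(ncol(b)) + sh[2] - j0] <- b
    a <- A; b <- B
  } else if (!identical(dim(a), dim(b))) {
    H <- max(nrow(a), nrow(b)); W <- max(ncol(a), ncol(b))
    a <- .pad_center(a, H, W)
    b <- .pad_center(b, H, W)
  }
  inter <- sum(pmin(a, b))
  if (metric == "intersection") return(inter)
  inter / sum(pmax(a, b))
}

.crop_ink <- function(m) {
  ri <- range(which(rowSums(m) > 0))
  ci <- range(which(colSums(m) > 0))
  m[ri[1]:ri[2], ci[1]:ci[2], drop = FALSE]
}

.com <- function(m) {
  w <- sum(m)
  c(sum(row(m) * m), sum(col(m) * m)) / w
}

.as_raster <- function(x) {
  if (inherits(x, "glyph")) return(x$raster)
  if (inherits(x, "stimulus_array")) return(x$canvas)
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

.pad_center <- function(r, H, W) {
  out <- matrix(0, H, W)
  i0 <- (H - nrow(r)) %/% 2L
  j0 <- (W - ncol(r)) %/% 2L
  out[i0 + seq_len(nrow(r)), j0 + seq_len(ncol(r))] <- r
  out
}

# Shift raster contents by (di, dj), zero-filling; used in tests of
# translation invariance.
.shift_raster <- function(r, di, dj) {
  out <- matrix(0, nrow(r), ncol(r))
  src_i <- seq_len(nrow(r)) - di
  src_j <- seq_len(ncol(r)) - dj
  ok_i <- src_i >= 1 & src_i <= nrow(r)
  ok_j <- src_j >= 1 & src_j <= ncol(r)
  out[ok_i, ok_j] <- r[src_i[ok_i], src_j[ok_j]]
  out
}

#' Per-pixel average of target and flanker glyphs
#'
#' Builds the averaged composite image used by the compulsory-averaging
#' error model: the three signed-contrast rasters are centre-aligned on a
#' common canvas and averaged pixel-wise. Averaging three copies of one
#' glyph returns that glyph; where opposite-polarity flankers overlap the
#' target their contributions cancel, attenuating the composite.
#'
#' @param target A `glyph` or raster.
#' @param flankers List or pair of two `glyph`s/rasters.
#' @return A signed-contrast raster (matrix).
#' @export
composite_average <- function(target, flankers) {
  stopifnot(length(flankers) == 2L)
  rs <- lapply(list(target, flankers[[1]], flankers[[2]]), .as_raster)
  H <- max(vapply(rs, nrow, 1L)); W <- max(vapply(rs, ncol, 1L))
  rs <- lapply(rs, .pad_center, H = H, W = W)
  (rs[[1]] + rs[[2]] + rs[[3]]) / 3
}

#' Render the candidate letter glyphs for similarity scoring
#'
#' @param symbols Character vector of candidate letters (defaults to the
#'   20-letter permitted target alphabet).
#' @param height_deg,geometry Rendering geometry, matching the reference.
#' @return Named list of `glyph` objects.
#' @export
candidate_glyphs <- function(symbols = alphabet_spec()$permitted_targets,
                             height_deg = 1.2,
                             geometry = viewing_geometry()) {
  g <- lapply(symbols, render_glyph, category = "letter", polarity = 1,
              height_deg = height_deg, geometry = geometry,
              role = "flanker")
  names(g) <- symbols
  g
}

#' Similarity profile of a reference image against a candidate alphabet
#'
#' Computes one [pixel_overlap()] value per candidate letter and reports the
#' best-matching candidate. This is the readout used to ask which letter a
#' given image (an individual glyph or an averaged target/flanker composite)
#' most resembles.
#'
#' @param reference Raster, `glyph` or `stimulus_array`.
#' @param candidates Named list of candidate glyphs from
#'   [candidate_glyphs()].
#' @param reference_label Description stored with the profile.
#' @param align,metric Passed to [pixel_overlap()].
#' @return An object of class `similarity_profile`: data frame of
#'   `candidate`, `value` plus attributes `argmax` and `reference_label`.
#' @export
similarity_profile <- function(reference,
                               candidates = candidate_glyphs(),
                               reference_label = "reference",
                               align = TRUE,
                               metric = c("jaccard", "intersection")) {
  metric <- match.arg(metric)
  if (length(candidates) == 0L) stop("empty candidate alphabet", call. = FALSE)
  ref <- .as_raster(reference)
  if (sum(abs(ref)) == 0) {
    stop("undefined similarity: blank reference image", call. = FALSE)
  }
  vals <- vapply(candidates, function(g) {
    pixel_overlap(ref, g, align = align, metric = metric)
  }, numeric(1))
  out <- data.frame(candidate = names(candidates), value = unname(vals),
                    stringsAsFactors = FALSE)
  structure(out, class = c("similarity_profile", "data.frame"),
            argmax = out$candidate[which.max(out$value)],
            reference_label = reference_label)
}

#' Full letter-by-letter similarity matrix
#'
#' @param symbols Candidate letters (default: the 20-letter target set).
#' @inheritParams candidate_glyphs
#' @param align,metric Passed to [pixel_overlap()].
#' @return Square numeric matrix of pairwise pixel-overlap similarities.
#' @export
similarity_matrix <- function(symbols = alphabet_spec()$permitted_targets,
                              height_deg = 1.2,
                              geometry = viewing_geometry(),
                              align = TRUE, metric = "jaccard") {
  gl <- candidate_glyphs(symbols, height_deg, geometry)
  n <- length(gl)
  m <- matrix(1, n, n, dimnames = list(symbols, symbols))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) m[i, j] <- pixel_overlap(gl[[i]], gl[[j]], align = align,
                                          metric = metric)
      if (j < i) m[i, j] <- m[j, i]
    }
  }
  m
}

#' Write a similarity profile or matrix as TSV
#'
#' @param x A `similarity_profile` or a matrix from [similarity_matrix()].
#' @param path Output file.
#' @export
write_similarity_tsv <- function(x, path) {
  if (inherits(x, "similarity_profile")) {
    out <- data.frame(reference_label = attr(x, "reference_label"),
                      candidate = x$candidate, value = x$value)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (is.matrix(x)) {
    utils::write.table(data.frame(reference_label = rownames(x), x,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  invisible(path)
}
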