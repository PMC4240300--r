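# Bundled 5x7 sans-serif-style bitmap font. Generated programmatically from
# the string patterns below so rasters are bit-identical across platforms;
# '#' marks ink, '.' background. Triangles are drawn procedurally (see
# triangle_raster) so their height and stroke match the letters.

.font5x7 <- local({
  pat <- list(
    A = c(".###.", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    B = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
    C = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
    D = c("####.", "#...#", "#...#", "#...#", "#...#", "#...#", "####."),
    E = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
    F = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
    G = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".###."),
    H = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
    I = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
    J = c("....#", "....#", "....#", "....#", "....#", "#...#", ".###."),
    K = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
    L = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
    M = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
    N = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
    O = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    P = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
    Q = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
    R = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
    S = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
    T = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
    U = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
    V = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
    W = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
    X = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
    Y = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
    Z = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
    `2` = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
    `3` = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
    `4` = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
    `5` = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
    `6` = c("..##.", ".#...", "#....", "####.", "#...#", "#...#", ".###."),
    `7` = c("#####", "....#", "...#.", "..#..", ".#...", ".#...", ".#..."),
    `8` = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
    `9` = c(".###.", "#...#", "#...#", ".####", "....#", "...#.", ".##..")
  )
  lapply(pat, function(rows) {
    m <- do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "#"))
    storage.mode(m) <- "double"
    m
  })
})

# Nearest-neighbour upscale of a base bitmap to height_px rows, preserving
# the 5:7 aspect ratio.
.scale_bitmap <- function(base, height_px) {
  stopifnot(height_px >= nrow(base))
  width_px <- max(1L, as.integer(round(height_px * ncol(base) / nrow(base))))
  ri <- pmin(nrow(base), floor(seq_len(height_px) * nrow(base) / height_px -
                                 1e-9) + 1L)
  ci <- pmin(ncol(base), floor(seq_len(width_px) * ncol(base) / width_px -
                                 1e-9) + 1L)
  base[ri, ci, drop = FALSE]
}

# Outline equilateral triangle at orientation 0/120/240 degrees, stroke
# thickness matched to the scaled font stroke (height_px / 7, the scale
# factor of one base-font pixel).
triangle_raster <- function(height_px, orientation_deg = 0) {
  stopifnot(height_px >= 7)
  w <- height_px
  stroke <- max(1, height_px / 7)
  cx <- (w + 1) / 2
  cy <- (height_px + 1) / 2
  r <- (height_px - stroke) / 2
  th <- (orientation_deg + c(90, 210, 330)) * pi / 180
  vx <- cx + r * cos(th)
  vy <- cy - r * sin(th)
  xs <- matrix(rep(seq_len(w), each = height_px), nrow = height_px)
  ys <- matrix(rep(seq_len(height_px), times = w), nrow = height_px)
  out <- matrix(0, height_px, w)
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    t <- ((px - x1) * dx + (py - y1) * dy) / (dx^2 + dy^2)
    t <- pmin(1, pmax(0, t))
    sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  }
  for (k in 1:3) {
    j <- if (k == 3) 1 else k + 1
    d <- seg_dist(xs, ys, vx[k], vy[k], vx[j], vy[j])
    out[d <= stroke / 2] <- 1
  }
  out
}
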