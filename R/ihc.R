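# Tile-grid co-localization of stain channels.

#' Partition an image into a rectangular tile grid
#'
#' Axis-aligned integer-pixel tiles; remainder pixels are absorbed by the
#' last row/column so tiles partition the image exactly. The atlas layout
#' is 45 x 34 = 1530 tiles sized to approximate one tumor cell.
#'
#' @param width,height image size in pixels (width >= n_cols,
#'   height >= n_rows).
#' @param n_cols,n_rows grid dimensions.
#' @return object of class `tile_grid`: `n_cols`, `n_rows`, `width`,
#'   `height`, `tiles` (data.frame: tile, col, row, x0, x1, y0, y1 with
#'   inclusive 1-based pixel bounds).
#' @export
grid_tiles <- function(width, height, n_cols = 45L, n_rows = 34L) {
  if (width <= 0 || height <= 0 || n_cols <= 0 || n_rows <= 0)
    stop_cfg("dimensions must be positive")
  if (width < n_cols || height < n_rows)
    stop_cfg("image smaller than the tile grid")
  xb <- floor(seq(0, width, length.out = n_cols + 1))
  xb[n_cols + 1] <- width
  yb <- floor(seq(0, height, length.out = n_rows + 1))
  yb[n_rows + 1] <- height
  tiles <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  tiles <- tiles[order(tiles$row, tiles$col), ]
  tiles$tile <- seq_len(nrow(tiles))
  tiles$x0 <- xb[tiles$col] + 1L
  tiles$x1 <- xb[tiles$col + 1L]
  tiles$y0 <- yb[tiles$row] + 1L
  tiles$y1 <- yb[tiles$row + 1L]
  rownames(tiles) <- NULL
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 width = as.integer(width), height = as.integer(height),
                 tiles = tiles[, c("tile", "col", "row", "x0", "x1", "y0", "y1")]),
            class = "tile_grid")
}

#' Annotate tile positivity for one stain channel
#'
#' A tile is positive iff the fraction of its pixels above
#' `intensity_threshold` is at least `positive_fraction`. The default
#' threshold is Otsu's method on the channel.
#'
#' @param image height x width numeric matrix in [0, 1].
#' @param grid a [grid_tiles()] matching the image dimensions.
#' @param intensity_threshold scalar cutoff, or `NULL` for Otsu.
#' @param positive_fraction minimum above-threshold pixel fraction.
#' @return logical vector over tiles, with attribute `threshold`.
#' @export
annotate_tiles <- function(image, grid, intensity_threshold = NULL,
                           positive_fraction = 0.1) {
  stopifnot(inherits(grid, "tile_grid"))
  if (nrow(image) != grid$height || ncol(image) != grid$width)
    stop_cfg("image dimensions do not match the grid")
  thr <- intensity_threshold %||% otsu_threshold(image)
  rng <- range(image)
  if (thr < rng[1] || thr > rng[2])
    warning(sprintf("threshold %.3g outside intensity range [%.3g, %.3g]",
                    thr, rng[1], rng[2]))
  tb <- grid$tiles
  pos <- vapply(seq_len(nrow(tb)), function(i) {
    px <- image[tb$y0[i]:tb$y1[i], tb$x0[i]:tb$x1[i]]
    mean(px > thr) >= positive_fraction
  }, TRUE)
  attr(pos, "threshold") <- thr
  pos
}

#' Double-positive tiles of two channels
#'
#' @param positivity_a,positivity_b logical tile vectors from
#'   [annotate_tiles()] on the same grid.
#' @param grid the shared [grid_tiles()] (for the overlay export).
#' @return list with `tiles` (indices positive in both), `count`, and
#'   `overlay` (height x width integer matrix: 0 background, 1/2 single
#'   positive, 3 double positive) when `grid` is supplied.
#' @export
overlap_tiles <- function(positivity_a, positivity_b, grid = NULL) {
  if (length(positivity_a) != length(positivity_b))
    stop_cfg("tile grids do not match")
  both <- which(positivity_a & positivity_b)
  overlay <- NULL
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "tile_grid"))
    if (nrow(grid$tiles) != length(positivity_a))
      stop_cfg("tile grids do not match")
    overlay <- matrix(0L, grid$height, grid$width)
    tb <- grid$tiles
    for (i in seq_len(nrow(tb))) {
      code <- positivity_a[i] + 2L * positivity_b[i]
      if (code > 0L)
        overlay[tb$y0[i]:tb$y1[i], tb$x0[i]:tb$x1[i]] <- code
    }
  }
  list(tiles = both, count = length(both), overlay = overlay)
}
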