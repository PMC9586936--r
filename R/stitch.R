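#' Average tile positions onto a regular grid
#'
#' Recovers a regular mosaic layout from individually registered (hence
#' jittered) tile positions by averaging: the mean horizontal and
#' vertical displacements between grid-adjacent tiles give the grid
#' spacings, and tiles are snapped to the regular grid defined by those
#' means, anchored so the mean position is preserved. A `"raw"` mode
#' passes the recorded positions through untouched.
#'
#' @param positions numeric matrix with columns `(x, y)`: 0-based tile
#'   offsets.
#' @param grid integer matrix with columns `(row, col)` giving each
#'   tile's grid index.
#' @param tile_size `c(h, w)` of one tile in pixels.
#' @param mode `"average"` (snap to mean-spacing grid) or `"raw"`.
#' @return object of class `mosaic_layout`: list with `offsets`,
#'   `canvas` (`c(h, w)`), `grid`, `tile_size`, `spacing` (`c(sx, sy)`,
#'   `NA` for raw mode or a single tile).
#' @export
average_layout <- function(positions, grid, tile_size,
                           mode = c("average", "raw")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  grid <- as.matrix(grid)
  n <- nrow(positions)
  if (n < 1) stop_invalid("need at least one tile position")
  offsets <- positions
  spacing <- c(sx = NA_real_, sy = NA_real_)
  if (mode == "average" && n > 1) {
    sx <- sy <- c()
    for (i in seq_len(n)) {
      right <- which(grid[, 1] == grid[i, 1] & grid[, 2] == grid[i, 2] + 1)
      below <- which(grid[, 1] == grid[i, 1] + 1 & grid[, 2] == grid[i, 2])
      if (length(right)) sx <- c(sx, positions[right, 1] - positions[i, 1])
      if (length(below)) sy <- c(sy, positions[below, 2] - positions[i, 2])
    }
    sx <- if (length(sx)) mean(sx) else 0
    sy <- if (length(sy)) mean(sy) else 0
    spacing <- c(sx = sx, sy = sy)
    # anchor the regular grid at the mean origin implied by the positions
    ox <- mean(positions[, 1] - (grid[, 2] - 1) * sx)
    oy <- mean(positions[, 2] - (grid[, 1] - 1) * sy)
    offsets <- cbind(x = ox + (grid[, 2] - 1) * sx,
                     y = oy + (grid[, 1] - 1) * sy)
  }
  canvas <- c(h = ceiling(unname(max(offsets[, 2]) + tile_size[1])),
              w = ceiling(unname(max(offsets[, 1]) + tile_size[2])))
  if (any(offsets < -1e-9) || any(!is.finite(offsets)))
    offsets <- pmax(offsets, 0)
  structure(list(offsets = offsets, canvas = canvas, grid = grid,
                 tile_size = tile_size, spacing = spacing),
            class = "mosaic_layout")
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("Mosaic layout: %d tiles of %d x %d on a %d x %d canvas\n",
              nrow(x$offsets), x$tile_size[1], x$tile_size[2],
              x$canvas["h"], x$canvas["w"]))
  if (!any(is.na(x$spacing)))
    cat(sprintf("  grid spacing: %.2f px (x), %.2f px (y)\n",
                x$spacing["sx"], x$spacing["sy"]))
  invisible(x)
}

#' Compose tiles into a mosaic
#'
#' Pastes tiles at their layout offsets; overlapping pixels are averaged
#' without weighting, except that zero-valued (filtered, dark
#' background) pixels are excluded from overlap averages so they do not
#' dim tissue. An optional background image is composited beneath the
#' mosaic with weight `1 - alpha`.
#'
#' @param tiles list of images (all grey or all RGB, equal sizes).
#' @param layout [average_layout()] result.
#' @param background optional image at canvas size.
#' @param alpha mosaic weight over the background where tiles exist.
#' @return composed image.
#' @export
compose_mosaic <- function(tiles, layout, background = NULL, alpha = 1) {
  stopifnot(inherits(layout, "mosaic_layout"))
  n <- length(tiles)
  if (n != nrow(layout$offsets)) stop_invalid("layout does not cover all tiles")
  chans <- n_channels(tiles[[1]])
  th <- unname(layout$tile_size[1]); tw <- unname(layout$tile_size[2])
  H <- unname(layout$canvas["h"]); W <- unname(layout$canvas["w"])
  acc <- array(0, dim = c(H, W, chans))
  cnt <- array(0, dim = c(H, W, chans))
  for (i in seq_len(n)) {
    x0 <- round(layout$offsets[i, 1]); y0 <- round(layout$offsets[i, 2])
    if (x0 < 0 || y0 < 0 || x0 + tw > W || y0 + th > H)
      stop_invalid("tile %d falls outside the canvas", i)
    rows <- y0 + seq_len(th); cols <- x0 + seq_len(tw)
    for (ch in seq_len(chans)) {
      t_ch <- if (chans > 1L) tiles[[i]][, , ch] else tiles[[i]]
      nz <- t_ch != 0
      acc[rows, cols, ch] <- acc[rows, cols, ch] + t_ch
      cnt[rows, cols, ch] <- cnt[rows, cols, ch] + nz
    }
  }
  out <- acc / pmax(cnt, 1)
  covered <- cnt > 0
  if (!is.null(background)) {
    bg <- if (chans > 1L) grey_to_rgb(background) else background
    bgarr <- array(bg, dim = c(H, W, chans))
    out <- ifelse(covered, alpha * out + (1 - alpha) * bgarr, bgarr)
    out <- array(out, dim = c(H, W, chans))
  }
  if (chans == 1L) matrix(out, H, W) else out
}

#' Spectral lifetime profile of an annotated cell
#'
#' Per wavelength, the mean lifetime over the centred 5 x 5 pixel
#' neighbourhood of the annotated position — cells span several pixels,
#' so the neighbourhood mean is reported as the absolute lifetime of the
#' cell.
#'
#' @param stack [spectral_stack] (typically a stitched mosaic stack).
#' @param location `c(x, y)` 0-based pixel position of the cell centre.
#' @param band_range optional wavelength range `c(lo, hi)` in nm to
#'   report (default: the stack's full grid).
#' @param half window half-size (default 2, i.e. 5 x 5).
#' @return data.frame with columns `wavelength_nm`, `lifetime_ns`.
#' @export
cell_profile <- function(stack, location, band_range = NULL, half = 2L) {
  stopifnot(inherits(stack, "spectral_stack"))
  d <- dim(stack$lifetime)
  x <- location[1]; y <- location[2]
  if (x - half < 0 || y - half < 0 || x + half > d[2] - 1 || y + half > d[1] - 1)
    stop_invalid("location (%s, %s) too close to the border for a %dx%d window",
                 x, y, 2 * half + 1, 2 * half + 1)
  rows <- (y - half):(y + half) + 1L
  cols <- (x - half):(x + half) + 1L
  sel <- if (is.null(band_range)) seq_len(d[3])
  else which(stack$wavelengths_nm >= band_range[1] &
               stack$wavelengths_nm <= band_range[2])
  prof <- vapply(sel, function(s) mean(stack$lifetime[rows, cols, s]),
                 numeric(1))
  data.frame(wavelength_nm = stack$wavelengths_nm[sel], lifetime_ns = prof)
}
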