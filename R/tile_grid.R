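# Tile-scene geometry: a wall region (7 rows x 11 columns = 77 tiles) and a
# floor region (7 rows x 9 columns = 63 tiles) spanning the stimulus image.
# Edge-column tiles are partially visible; the grid stores a visible-area
# fraction so area-weighted image means account for partial tiles.

#' Construct the tile grid
#'
#' @param image_deg Width and height of the stimulus image in degrees of
#'   visual angle.
#' @param wall_rows,wall_cols Wall grid dimensions (77 tiles).
#' @param floor_rows,floor_cols Floor grid dimensions (63 tiles).
#' @param edge_fraction Visible-area fraction of tiles in the outermost
#'   columns of each region.
#' @return Object of class `tile_grid`: a data frame with one row per tile
#'   (`tile_id`, `region`, `row`, `col`, `x`, `y`, `width`, `height`,
#'   `visible_fraction`, `area`) plus the image extent as attributes. `x`, `y`
#'   are tile-center positions in degrees, image-centered.
#' @export
make_tile_grid <- function(image_deg = c(20, 16.7),
                           wall_rows = 7, wall_cols = 11,
                           floor_rows = 7, floor_cols = 9,
                           edge_fraction = 0.85) {
  w <- image_deg[1]; h <- image_deg[2]
  wall_h <- 0.55 * h; floor_h <- 0.45 * h
  region_grid <- function(region, rows, cols, y_lo, y_hi) {
    tw <- w / cols
    th <- (y_hi - y_lo) / rows
    g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    vf <- ifelse(g$col == 1 | g$col == cols, edge_fraction, 1)
    data.frame(
      region = region, row = g$row, col = g$col,
      x = -w / 2 + (g$col - 0.5) * tw,
      y = y_lo + (g$row - 0.5) * th,
      width = tw, height = th,
      visible_fraction = vf,
      area = tw * th * vf
    )
  }
  tiles <- rbind(
    region_grid("wall", wall_rows, wall_cols, h / 2 - wall_h, h / 2),
    region_grid("floor", floor_rows, floor_cols, -h / 2, -h / 2 + floor_h)
  )
  tiles <- cbind(tile_id = seq_len(nrow(tiles)), tiles)
  structure(tiles, class = c("tile_grid", "data.frame"),
            image_deg = image_deg)
}

#' Image extent of a tile grid
#'
#' @param grid A [make_tile_grid()] object.
#' @return `c(width, height)` in degrees.
#' @export
grid_extent <- function(grid) attr(grid, "image_deg")

#' Smooth illumination gain field over the tile grid
#'
#' The simulated room light sits on the ceiling, so the floor receives more
#' illumination than the top of the back wall. Modeled as a linear vertical
#' gradient in image coordinates: gain 1 at the bottom of the image falling to
#' `1 - amplitude` at the top.
#'
#' @param grid A [make_tile_grid()] object.
#' @param amplitude Total top-to-bottom gain drop (0 = uniform).
#' @return Numeric vector of per-tile gains aligned with `grid` rows.
#' @export
gain_field <- function(grid, amplitude = 0.15) {
  h <- grid_extent(grid)[2]
  1 - amplitude * (grid$y + h / 2) / h
}

#' Locate the tile containing a point
#'
#' @param grid A [make_tile_grid()] object.
#' @param x,y Positions in degrees (vectors of equal length).
#' @return Integer vector of `tile_id`s (`NA` where the point falls outside
#'   every tile).
#' @export
locate_tile <- function(grid, x, y) {
  ids <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    hit <- which(abs(x[i] - grid$x) <= grid$width / 2 &
                 abs(y[i] - grid$y) <= grid$height / 2)
    if (length(hit)) ids[i] <- grid$tile_id[hit[1]]
  }
  ids
}
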