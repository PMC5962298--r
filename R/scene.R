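# Reflectance-to-tile assignment and scene colors. Assignment balances tile
# counts per reflectance within each region (max-min difference of one tile)
# and grows contiguous same-reflectance patches by seeded multi-source region
# growing, emulating the irregular constant-reflectance groupings of the
# rendered scenes. Colors come from a flat forward model: illuminant spectrum
# times surface reflectance times a per-tile illumination gain.

#' Assign reflectances to tiles
#'
#' Within each region, each of the `n_refl` reflectances receives
#' `floor(N/n_refl)` or `ceiling(N/n_refl)` tiles (remainder spread over a
#' seeded random subset), and same-reflectance tiles form contiguous patches
#' (4-neighbor adjacency) grown from random seed tiles. Growth can wall
#' itself in; bounded reseeded retries recover.
#'
#' @param grid A [make_tile_grid()] object.
#' @param n_refl Number of reflectances (14).
#' @param seed Integer seed; one seed gives one deterministic assignment.
#' @param max_retries Region-growing retries before erroring.
#' @return Integer vector over tiles (aligned with `grid` rows): reflectance
#'   index in `1..n_refl`.
#' @export
assign_reflectances <- function(grid, n_refl = 14, seed = 1, max_retries = 50) {
  out <- integer(nrow(grid))
  for (region in unique(grid$region)) {
    idx <- which(grid$region == region)
    sub <- grid[idx, ]
    for (attempt in seq_len(max_retries)) {
      res <- with_seed(derive_seed(seed, match(region, c("wall", "floor")), attempt),
                       grow_region(sub, n_refl))
      if (!is.null(res)) break
      res <- NULL
    }
    if (is.null(res)) {
      stop(sprintf("assignment error: region growing failed in %s after %d retries",
                   region, max_retries), call. = FALSE)
    }
    out[idx] <- res
  }
  out
}

# size-safe sample: never expands a length-1 x into 1:x
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# One assignment attempt on a single region. A serpentine path through the
# region lattice is cut into consecutive runs of quota length (consecutive
# path cells are lattice neighbours, so every run is contiguous); the banded
# shapes are then scrambled by connectivity-preserving boundary swaps between
# adjacent patches, which keeps counts exact while making patch outlines
# irregular. Returns NULL only on a (rare) degenerate lattice.
grow_region <- function(sub, n_refl, n_swaps = 300) {
  n <- nrow(sub)
  quota <- rep(n %/% n_refl, n_refl)
  extra <- sample.int(n_refl, n %% n_refl)
  quota[extra] <- quota[extra] + 1
  key <- function(r, c) paste(r, c)
  cell_of <- stats::setNames(seq_len(n), key(sub$row, sub$col))
  nb <- lapply(seq_len(n), function(i) {
    cand <- rbind(c(sub$row[i] - 1, sub$col[i]), c(sub$row[i] + 1, sub$col[i]),
                  c(sub$row[i], sub$col[i] - 1), c(sub$row[i], sub$col[i] + 1))
    unname(stats::na.omit(cell_of[key(cand[, 1], cand[, 2])]))
  })

  # serpentine path: along rows or columns, random start corner
  by_row <- stats::runif(1) < 0.5
  major <- if (by_row) sub$row else sub$col
  minor <- if (by_row) sub$col else sub$row
  if (stats::runif(1) < 0.5) major <- -major
  flip <- stats::runif(1) < 0.5
  snake <- order(major, ifelse(xor(major %% 2 == 0, flip), minor, -minor))
  run_order <- sample.int(n_refl)
  path_labels <- rep(run_order, times = quota[run_order])
  assigned <- integer(n)
  assigned[snake] <- path_labels

  # boundary scramble: swap adjacent-patch boundary cells when both patches
  # stay connected, preserving counts
  for (it in seq_len(n_swaps)) {
    c1 <- sample.int(n, 1)
    p <- assigned[c1]
    nbr <- nb[[c1]]
    other <- nbr[assigned[nbr] != p]
    if (!length(other)) next
    c2 <- resample(other, 1)
    q <- assigned[c2]
    pc <- which(assigned == p)
    qc <- which(assigned == q)
    new_p <- c(setdiff(pc, c1), c2)
    new_q <- c(setdiff(qc, c2), c1)
    if (patch_connected(new_p, nb) && patch_connected(new_q, nb)) {
      assigned[c1] <- q
      assigned[c2] <- p
    }
  }
  assigned
}

# is the cell set connected under the neighbour lists?
patch_connected <- function(cells, nb) {
  if (length(cells) <= 1) return(TRUE)
  seen <- cells[1]
  frontier <- cells[1]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(nb[frontier])), cells), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(cells)
}

#' Scene specification
#'
#' @param scene_id Identifier.
#' @param condition `"fixed"` or `"shuffled"`.
#' @param role `"target"` or `"test"`.
#' @param direction,nominal_step Test-illuminant key (`NULL` for targets).
#' @param assignment Integer tile-to-reflectance vector.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(scene_id, condition, role, direction = NULL,
                       nominal_step = NULL, assignment) {
  stopifnot(condition %in% c("fixed", "shuffled"),
            role %in% c("target", "test"))
  structure(list(scene_id = scene_id, condition = condition, role = role,
                 direction = direction, nominal_step = nominal_step,
                 assignment = assignment),
            class = "scene_spec")
}

#' Enumerate the stimulus set for a condition
#'
#' `n_target_versions` target scenes plus one test scene per (direction,
#' nominal step) in the series: 230 scenes with the defaults. In the fixed
#' condition every scene reuses one canonical assignment; in the shuffled
#' condition every scene draws its own.
#'
#' @param condition `"fixed"` or `"shuffled"`.
#' @param series An `illuminant_series`.
#' @param grid A [make_tile_grid()] object.
#' @param n_target_versions Number of target-scene versions (30).
#' @param seed Integer seed.
#' @return List of [scene_spec()] objects.
#' @export
build_stimulus_set <- function(condition, series, grid,
                               n_target_versions = 30, seed = 1) {
  canonical <- assign_reflectances(grid, seed = derive_seed(seed, 0))
  next_assignment <- function(i) {
    if (condition == "fixed") canonical
    else assign_reflectances(grid, seed = derive_seed(seed, i))
  }
  specs <- list()
  i <- 0
  for (v in seq_len(n_target_versions)) {
    i <- i + 1
    specs[[i]] <- scene_spec(sprintf("target_%02d", v), condition, "target",
                             assignment = next_assignment(i))
  }
  for (dir in series$directions) {
    for (k in seq_len(series$n_steps)) {
      i <- i + 1
      specs[[i]] <- scene_spec(sprintf("test_%s_%02d", dir, k), condition,
                               "test", direction = dir, nominal_step = k,
                               assignment = next_assignment(i))
    }
  }
  specs
}

#' Compute per-tile and mean scene colors
#'
#' Tile XYZ is the tristimulus of (illuminant x reflectance) scaled by the
#' tile's illumination gain; the scene mean is the visible-area-weighted
#' average over tiles. No interreflection modeling.
#'
#' @param spec A [scene_spec()].
#' @param series An `illuminant_series` resolving the scene's illuminant.
#' @param refl Reflectance set from [make_reflectance_set()].
#' @param grid A [make_tile_grid()] object.
#' @param gain Per-tile gain vector (default: uniform 1).
#' @param noise_sd Optional zero-mean multiplicative rendering noise SD
#'   (applied per tile; default off).
#' @return Object of class `scene_colors`: list with `tiles` (data frame:
#'   `tile_id`, `region`, `x`, `y`, `area`, `reflectance`, `X`, `Y`, `Z`) and
#'   `mean_xyz`.
#' @export
render_scene_colors <- function(spec, series, refl, grid, gain = NULL,
                                noise_sd = 0) {
  illum <- if (spec$role == "target") series$target
           else series_spectrum(series, spec$direction, spec$nominal_step)
  base_xyz <- t(vapply(refl, function(r) spectrum_to_xyz(r, illum), numeric(3)))
  if (is.null(gain)) gain <- rep(1, nrow(grid))
  stopifnot(length(gain) == nrow(grid),
            length(spec$assignment) == nrow(grid))
  xyz <- base_xyz[spec$assignment, , drop = FALSE] * gain
  if (noise_sd > 0) xyz <- xyz * (1 + stats::rnorm(nrow(xyz), sd = noise_sd))
  tiles <- data.frame(tile_id = grid$tile_id, region = grid$region,
                      x = grid$x, y = grid$y, area = grid$area,
                      reflectance = names(refl)[spec$assignment],
                      X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3])
  mean_xyz <- colSums(xyz * grid$area) / sum(grid$area)
  names(mean_xyz) <- c("X", "Y", "Z")
  structure(list(tiles = tiles, mean_xyz = mean_xyz, scene_id = spec$scene_id),
            class = "scene_colors")
}

#' Pairwise mean-image variation across target scenes
#'
#' Computes each target scene's area-weighted mean XYZ, converts to CIELUV
#' with the image-based white point (the average of the target-scene means),
#' and summarizes all-pairs Delta E.
#'
#' @param specs List of target [scene_spec()]s (length >= 2).
#' @param series,refl,grid,gain As in [render_scene_colors()].
#' @return List with `mean`, `sd`, `max` of pairwise Delta E and the
#'   per-scene `luv` matrix.
#' @export
shuffle_mean_variation <- function(specs, series, refl, grid, gain = NULL) {
  if (length(specs) < 2) stop("need at least 2 target scenes", call. = FALSE)
  means <- t(vapply(specs, function(sp) {
    render_scene_colors(sp, series, refl, grid, gain)$mean_xyz
  }, numeric(3)))
  white <- colMeans(means)
  luv <- t(apply(means, 1, xyz_to_luv, white = white))
  pairs <- utils::combn(nrow(luv), 2)
  de <- sqrt(rowSums((luv[pairs[1, ], , drop = FALSE] -
                      luv[pairs[2, ], , drop = FALSE])^2))
  list(mean = mean(de), sd = stats::sd(de), max = max(de), luv = luv)
}
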