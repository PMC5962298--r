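test_that("tile grid has the wall/floor counts and stores visible areas", {
  g <- the_grid
  expect_equal(sum(g$region == "wall"), 77)
  expect_equal(sum(g$region == "floor"), 63)
  ext <- grid_extent(g)
  expect_true(all(abs(g$x) <= ext[1] / 2 & abs(g$y) <= ext[2] / 2))
  expect_true(all(g$visible_fraction > 0 & g$visible_fraction <= 1))
})

test_that("reflectance set: 14 bounded samples, deterministic, pale members brightest", {
  r1 <- make_reflectance_set(seed = 3)
  r2 <- make_reflectance_set(seed = 3)
  expect_length(r1, 14)
  expect_identical(r1, r2)
  for (s in r1) {
    expect_true(all(s$values >= 0 & s$values <= 1))
  }
  lum <- reflectance_luminance(r1, the_series$target)
  top4 <- names(sort(lum, decreasing = TRUE))[1:4]
  expect_setequal(top4, pale_reflectance_names())
})

test_that("assignment balances counts per region and forms contiguous patches", {
  neighbours <- function(sub) {
    key <- function(r, c) paste(r, c)
    cell_of <- setNames(seq_len(nrow(sub)), key(sub$row, sub$col))
    lapply(seq_len(nrow(sub)), function(i) {
      cand <- rbind(c(sub$row[i] - 1, sub$col[i]), c(sub$row[i] + 1, sub$col[i]),
                    c(sub$row[i], sub$col[i] - 1), c(sub$row[i], sub$col[i] + 1))
      unname(na.omit(cell_of[key(cand[, 1], cand[, 2])]))
    })
  }
  connected <- function(cells, nb) {
    if (length(cells) <= 1) return(TRUE)
    seen <- cells[1]; frontier <- cells[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unique(unlist(nb[frontier])), cells), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(cells)
  }
  for (seed in c(2, 9, 31)) {
    a <- assign_reflectances(the_grid, seed = seed)
    wall <- tabulate(a[the_grid$region == "wall"], 14)
    floor <- tabulate(a[the_grid$region == "floor"], 14)
    expect_equal(mean(wall), 77 / 14) # 5.5 tiles per reflectance
    expect_lte(max(wall) - min(wall), 1)
    expect_true(all(floor %in% c(4, 5))) # 63 = 14*4 + 7
    for (region in c("wall", "floor")) {
      sub <- the_grid[the_grid$region == region, ]
      av <- a[the_grid$region == region]
      nb <- neighbours(sub)
      for (r in 1:14) expect_true(connected(which(av == r), nb))
    }
  }
  # reseeding changes the assignment
  expect_false(identical(assign_reflectances(the_grid, seed = 1),
                         assign_reflectances(the_grid, seed = 2)))
  # same seed reproduces it
  expect_identical(assign_reflectances(the_grid, seed = 5),
                   assign_reflectances(the_grid, seed = 5))
})

test_that("scene colors are linear in gain and constant for constant scenes", {
  spec <- scene_spec("s1", "fixed", "target",
                     assignment = rep(1L, nrow(the_grid)))
  sc <- render_scene_colors(spec, the_series, the_refl, the_grid)
  expect_equal(length(unique(sc$tiles$X)), 1) # all tiles identical
  gain <- rep(1, nrow(the_grid))
  gain[17] <- 2
  sc2 <- render_scene_colors(spec, the_series, the_refl, the_grid, gain)
  expect_equal(sc2$tiles$X[17], 2 * sc$tiles$X[17])
  expect_equal(sc2$tiles$X[-17], sc$tiles$X[-17])
  # mean equals the area-weighted average of tile values
  a <- assign_reflectances(the_grid, seed = 4)
  sc3 <- render_scene_colors(scene_spec("s3", "shuffled", "target",
                                        assignment = a),
                             the_series, the_refl, the_grid)
  expect_equal(unname(sc3$mean_xyz["Y"]),
               sum(sc3$tiles$Y * sc3$tiles$area) / sum(sc3$tiles$area))
})

test_that("stimulus set enumerates 230 scenes with per-condition assignment policy", {
  shuffled <- build_stimulus_set("shuffled", the_series, the_grid, seed = 6)
  fixed <- build_stimulus_set("fixed", the_series, the_grid, seed = 6)
  expect_length(shuffled, 230) # 30 targets + 4 x 50 tests
  expect_length(fixed, 230)
  expect_equal(sum(vapply(shuffled, function(s) s$role == "target", logical(1))), 30)
  # fixed: all assignments identical
  ref <- fixed[[1]]$assignment
  expect_true(all(vapply(fixed, function(s) identical(s$assignment, ref),
                         logical(1))))
  # shuffled: assignments pairwise distinct (probability ~ 1)
  keys <- vapply(shuffled, function(s) paste(s$assignment, collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("fixed-condition target scenes show no mean-image variation", {
  fixed <- build_stimulus_set("fixed", the_series, the_grid, seed = 6)
  sv <- shuffle_mean_variation(fixed[1:10], the_series, the_refl, the_grid,
                               gain_field(the_grid))
  expect_lt(sv$max, 0.1)
})

test_that("shuffled-condition mean-image variation is positive and amplitude-monotone in the gain field", {
  shuffled <- build_stimulus_set("shuffled", the_series, the_grid,
                                 seed = 6)[1:12]
  sv <- shuffle_mean_variation(shuffled, the_series, the_refl, the_grid,
                               gain_field(the_grid))
  expect_gt(sv$mean, 0)
  # equal-area grid + uniform gain: shuffled means are identical
  eq_grid <- make_tile_grid(wall_rows = 7, wall_cols = 10,
                            floor_rows = 7, floor_cols = 8,
                            edge_fraction = 1)
  # 70 and 56 tiles: both divisible by 14
  specs <- lapply(1:6, function(i) {
    scene_spec(paste0("t", i), "shuffled", "target",
               assignment = assign_reflectances(eq_grid, seed = i))
  })
  # regions have different tile areas; restrict to per-region equality by
  # using a uniform-area grid: wall and floor tiles equal via square rows
  sv0 <- shuffle_mean_variation(specs, the_series, the_refl, eq_grid)
  amp_means <- vapply(c(0.15, 0.45), function(a) {
    shuffle_mean_variation(specs, the_series, the_refl, eq_grid,
                           gain_field(eq_grid, a))$mean
  }, numeric(1))
  expect_gt(amp_means[1], sv0$mean - 1e-9)
  expect_gt(amp_means[2], amp_means[1])
})
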