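test_that("spiral offsets match the independent ring-walk oracle", {
  expect_equal(spiral_offsets(1), oracle_spiral(1), ignore_attr = TRUE)
  for (n in c(2, 5, 9, 10, 25, 100, 441))
    expect_equal(unname(spiral_offsets(n)), oracle_spiral(n))
  expect_error(spiral_offsets(0), "n must be")
})

test_that("spiral offsets walk outward with unit steps and tile full squares", {
  s9 <- spiral_offsets(9)
  expect_equal(s9[1, ], c(i = 0L, j = 0L))
  steps <- abs(diff(s9))
  expect_true(all(rowSums(steps) == 1))              # unit-step adjacency
  grid3 <- expand.grid(i = -1:1, j = -1:1)
  expect_setequal(paste(s9[, 1], s9[, 2]), paste(grid3$i, grid3$j))
  s25 <- spiral_offsets(25)
  grid5 <- expand.grid(i = -2:2, j = -2:2)
  expect_setequal(paste(s25[, 1], s25[, 2]), paste(grid5$i, grid5$j))
  expect_equal(max(pmax(abs(s25[, 1]), abs(s25[, 2]))), 2)  # max ring
})

test_that("spiral_offsets(m) is a prefix of spiral_offsets(n) for m < n", {
  set.seed(13)
  for (k in 1:25) {
    n <- sample(2:400, 1)
    m <- sample(seq_len(n - 1), 1)
    expect_identical(spiral_offsets(n)[seq_len(m), , drop = FALSE],
                     spiral_offsets(m))
  }
})

test_that("a single-tile mosaic is centred at the start position", {
  depot <- small_depot()
  store <- run_mosaic(tile_store(), macro_position(150, 150, 0), 1, 0, depot)
  expect_length(store$tiles, 1L)
  expect_position_equal(store$tiles[[1]]$centre, 150, 150, 0)
  expect_position_equal(depot_position(depot), 150, 150, 0)  # returned home
})

test_that("a 3x3 zero-overlap mosaic forms a lattice spaced by the sensor", {
  depot <- small_depot()
  store <- run_mosaic(tile_store(), macro_position(150, 150, 0), 9, 0, depot)
  offs <- spiral_offsets(9)
  for (k in 1:9) {   # geometry oracle from the spiral offsets
    expect_equal(store$tiles[[k]]$centre$x_um,
                 unname(150 + offs[k, "i"] * 32))
    expect_equal(store$tiles[[k]]$centre$y_um,
                 unname(150 + offs[k, "j"] * 32))
    expect_equal(store$tiles[[k]]$seq, k)
  }
  xs <- sort(unique(vapply(store$tiles, function(t) t$centre$x_um, numeric(1))))
  expect_equal(xs, c(118, 150, 182))
  # overlap shrinks the step
  store2 <- run_mosaic(tile_store(), macro_position(150, 150, 0), 2, 0.25,
                       depot)
  expect_equal(store2$tiles[[2]]$centre$x_um - store2$tiles[[1]]$centre$x_um,
               32 * 0.75)
})

test_that("successive mosaics accumulate; earlier tiles are never removed", {
  depot <- small_depot()
  store <- run_mosaic(tile_store(), macro_position(150, 150, 0), 4, 0, depot)
  first <- store$tiles
  store <- mark_point(store, macro_position(1, 2, 3), "roi")
  store <- run_mosaic(store, macro_position(100, 100, 0), 3, 0, depot)
  expect_length(store$tiles, 7L)
  expect_identical(store$tiles[seq_along(first)], first)
  ids <- vapply(store$tiles, `[[`, integer(1), "mosaic_id")
  expect_setequal(unique(ids), c(1L, 2L))
  expect_equal(list_marked(store)$label, "roi")   # marks survive new mosaics
})

test_that("a mosaic hitting the soft limits keeps the tiles it acquired", {
  depot <- small_depot()
  # start near the +x soft limit so an eastward tile move must fail
  start <- macro_position(24990, 0, 0)
  expect_warning(
    store <- run_mosaic(tile_store(), start, 9, 0, depot),
    "mosaic stopped")
  expect_gte(length(store$tiles), 1L)
  expect_lt(length(store$tiles), 9L)
})

test_that("mosaics save as a dv stack with a parseable XYZ sidecar", {
  depot <- small_depot()
  store <- run_mosaic(tile_store(), macro_position(150, 150, 0), 9, 0, depot)
  path <- file.path(withr::local_tempdir(), "mosaic.dv")
  paths <- save_mosaic(store, attr(store, "mosaic_id"), path)
  lines <- readLines(paths$sidecar)
  expect_length(grep("^[^#]", lines), 9L)
  side <- read_mosaic_sidecar(paths$sidecar)
  for (k in 1:9) {
    expect_equal(side$x_um[k], store$tiles[[k]]$centre$x_um, tolerance = 1e-3)
    expect_equal(side$y_um[k], store$tiles[[k]]$centre$y_um, tolerance = 1e-3)
  }
  back <- read_dv(paths$dv)
  expect_equal(dim(back$data)[3], 9L)
  for (k in 1:9)
    expect_equal(matrix(back$data[1, 1, k, , ], 32L), store$tiles[[k]]$image,
                 ignore_attr = TRUE)
  expect_error(save_mosaic(store, 99L, path), "no mosaic with id")
})

test_that("render_region composites tiles with later-over-earlier painting", {
  expect_true(all(render_region(tile_store(), c(0, 10, 0, 10), 1) == 0))
  depot <- small_depot()
  store <- run_mosaic(tile_store(), macro_position(150, 150, 0), 1, 0, depot)
  tile <- store$tiles[[1]]
  fp <- scopekit:::tile_footprint(tile)
  out <- render_region(store, c(fp["x0"], fp["x1"], fp["y0"], fp["y1"]), 1)
  expect_equal(out, matrix(as.numeric(tile$image), 32L), ignore_attr = TRUE)
  # idempotent for a frozen store
  out2 <- render_region(store, c(fp["x0"], fp["x1"], fp["y0"], fp["y1"]), 1)
  expect_identical(out, out2)
  # a later tile overpaints the overlap region
  store <- run_mosaic(store, macro_position(166, 150, 0), 1, 0, depot)
  out3 <- render_region(store, c(fp["x0"], fp["x1"], fp["y0"], fp["y1"]), 1)
  t2 <- store$tiles[[2]]
  expect_equal(out3[16, 32], as.numeric(t2$image[16, 16]))
  expect_equal(out3[16, 1], as.numeric(tile$image[16, 1]))  # outside overlap
})

test_that("marked points are append-only and order-preserving", {
  store <- tile_store()
  expect_equal(nrow(list_marked(store)), 0L)
  store <- mark_point(store, macro_position(1, 2, 3), "a")
  expect_equal(nrow(list_marked(store)), 1L)
  store <- mark_point(store, macro_position(1, 2, 3), "b")
  df <- list_marked(store)
  expect_equal(df$label, c("a", "b"))   # same position, both retained
  expect_equal(df$x_um, c(1, 1))
})
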