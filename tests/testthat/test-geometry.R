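test_that("a full-column river splits a 5x5 grid into two 10-cell regions", {
  geo <- column_river_geom(5, 5, 3)
  expect_equal(geo$n_regions, 2L)
  expect_equal(geo$region_sizes, c(10L, 10L))
  expect_true(all(geo$label[, 1:2] >= 1))
  expect_equal(unname(geo$label[, 3]), rep(0L, 5))
})

test_that("empty and full river masks give one and zero regions", {
  g <- grid_spec(4, 6)
  none <- label_regions(matrix(FALSE, 4, 6), g)
  expect_equal(none$n_regions, 1L)
  expect_equal(none$region_sizes, 24L)
  all_river <- label_regions(matrix(TRUE, 4, 6), g)
  expect_equal(all_river$n_regions, 0L)
  expect_length(all_river$region_sizes, 0L)
})

test_that("region labelling agrees with label-propagation flood fill on random masks", {
  for (seed in 0:99) {
    set.seed(seed)
    M <- sample(2:8, 1); N <- sample(2:8, 1)
    mask <- matrix(runif(M * N) < 0.35, M, N)
    geo <- label_regions(mask, grid_spec(M, N))
    ref <- oracle_components(mask)
    # same partition: the package label and the oracle id are in bijection
    ids <- unique(ref[!mask])
    expect_equal(geo$n_regions, length(ids))
    for (id in ids) {
      labs <- unique(geo$label[!mask & ref == id])
      expect_length(labs, 1)
    }
    # partition invariant and deterministic size ordering
    expect_equal(sum(mask) + sum(geo$region_sizes), M * N)
    expect_true(all(diff(geo$region_sizes) <= 0))
  }
})

test_that("region numbering is deterministic: size-descending, ties by first row-major cell", {
  # two single-cell regions at the grid corners, separated by a cross river
  mask <- matrix(TRUE, 3, 3)
  mask[1, 1] <- FALSE; mask[3, 3] <- FALSE
  geo <- label_regions(mask, grid_spec(3, 3))
  expect_equal(geo$n_regions, 2L)
  expect_equal(geo$label[1, 1], 1L)  # row-major first cell wins the tie
  expect_equal(geo$label[3, 3], 2L)
})

test_that("river distance follows the horizontal-then-vertical decomposition", {
  # 1x5 grid, river in column 0: pure horizontal offsets
  geo <- column_river_geom(1, 5, 1)
  df <- distance_field(geo)
  expect_equal(df$d[1, ], c(0, 1, 2, 3, 4))
  expect_equal(df$M_horiz[1, 4], 3)
  expect_equal(df$A_vert[1, 4], 0)

  # 4x4 grid, single river cell at (0, 1) (matrix (1, 2)): the cell at
  # (2, 2) has column offset 1 and row offset 2 -> d = 3
  mask <- matrix(FALSE, 4, 4); mask[1, 2] <- TRUE
  geo2 <- label_regions(mask, grid_spec(4, 4))
  df2 <- distance_field(geo2)
  expect_equal(df2$M_horiz[3, 3], 1)
  expect_equal(df2$A_vert[3, 3], 2)
  expect_equal(df2$d[3, 3], 3)
})

test_that("river distance is 0 exactly on the river and >= 1 elsewhere", {
  for (seed in c(1, 7, 23)) {
    mask <- make_river(12, 14, width = 1, bifurcate = seed == 23, seed = seed)
    geo <- label_regions(mask, grid_spec(12, 14))
    df <- distance_field(geo)
    expect_true(all(df$d[geo$river] == 0))
    expect_true(all(df$d[!geo$river] >= 1))
    expect_equal(df$d, df$M_horiz + df$A_vert)
    expect_equal(df$d, oracle_distance(geo))
  }
})

test_that("a full-row river reduces the distance to the absolute row offset", {
  mask <- matrix(FALSE, 6, 4); mask[3, ] <- TRUE
  geo <- label_regions(mask, grid_spec(6, 4))
  df <- distance_field(geo)
  expect_equal(df$d, matrix(abs(seq_len(6) - 3), 6, 4))
  expect_true(all(df$M_horiz == 0))
})

test_that("distance field requires at least one river cell", {
  geo <- label_regions(matrix(FALSE, 3, 3), grid_spec(3, 3))
  expect_error(distance_field(geo), "river")
})

test_that("UTM conversion reproduces the five published parcel coordinates", {
  pre <- tacana_preset()
  utm <- rbind(c(595008.5, 1668868.5), c(595048.5, 1668903.5),
               c(595068.5, 1668948.5), c(595113.5, 1668973.5),
               c(595163.5, 1668998.5))
  got <- utm_to_grid(utm[, 1], utm[, 2], pre$grid)
  expect_equal(unname(got), unname(pre$parcels$cells))
  # anchor corner maps to (0, 0)
  corner <- utm_to_grid(pre$grid$utm_sw[1], pre$grid$utm_ne[2], pre$grid)
  expect_equal(unname(corner), cbind(0L, 0L))
})

test_that("UTM conversion rejects points outside the rectangle and missing anchors", {
  pre <- tacana_preset()
  expect_error(utm_to_grid(1, 1, pre$grid), "outside")
  expect_error(utm_to_grid(595000, 1668900, grid_spec(10, 10)), "anchor")
})

test_that("dimension mismatches are input errors", {
  expect_error(label_regions(matrix(FALSE, 3, 3), grid_spec(4, 4)), "3 x 3")
})

test_that("geometry validation passes constructive labels and flags planted defects", {
  mask <- make_river(10, 12, seed = 5)
  geo <- label_regions(mask, grid_spec(10, 12))
  expect_true(validate_geometry(geo)$ok)

  # two adjacent cells in different regions
  broken <- geo
  cells2 <- which(broken$label == 2L)
  broken$label[cells2[1]] <- 1L
  rep1 <- validate_geometry(broken)
  expect_false(rep1$ok)
  expect_true(any(grepl("different regions|disconnected|size", rep1$failures$rule)))

  # an unlabeled cell
  broken2 <- geo
  broken2$label[5, 5] <- NA_integer_
  rep2 <- validate_geometry(broken2)
  expect_false(rep2$ok)
  expect_true(any(rep2$failures$rule == "unlabeled cell"))
})

test_that("parcel sets reject duplicates and negative counts", {
  expect_error(parcel_set(rbind(c(1, 1), c(1, 1))), "distinct")
  expect_error(parcel_set(rbind(c(1, 1)), total_year_count = -1), "nonnegative")
  p <- parcel_set(rbind(c(2, 3), c(4, 5)), total_year_count = 3, n_trips = 10)
  expect_equal(p$n_trips, 10L)
})
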