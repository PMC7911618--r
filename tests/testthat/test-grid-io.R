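test_that("ESRI ASCII values land on the right cells and nodata is masked", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 20",
               "cellsize 0.5", "NODATA_value -9999",
               "1 2", "3 -9999"), path)
  lyr <- read_esri_ascii(path)
  expect_equal(lyr$spec$n_rows, 2L)
  expect_equal(lyr$spec$cell_size, 0.5)
  expect_equal(lyr$values[1, 1], 1)  # row 1 = north
  expect_equal(lyr$values[1, 2], 2)
  expect_equal(lyr$values[2, 1], 3)
  expect_true(is.na(lyr$values[2, 2]))
  # masked cells excluded from statistics
  expect_equal(nrow(tibble::as_tibble(lyr)), 3)
})

test_that("write/read ESRI ASCII round-trips values and geometry exactly", {
  set.seed(7)
  spec <- grid_spec(5, 7, x_ll = 99.123456789, y_ll = -3.5,
                    cell_size = 1 / 3, nodata = -1234)
  m <- matrix(rnorm(35) * 1e3, 5, 7)
  m[sample(35, 6)] <- NA
  lyr <- raster_layer("z", spec, m, units = "mm")
  path <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(lyr, path)
  back <- read_esri_ascii(path, name = "z")
  expect_identical(back$spec$n_rows, spec$n_rows)
  expect_identical(back$spec$cell_size, spec$cell_size)  # full precision
  expect_identical(back$spec$x_ll, spec$x_ll)
  expect_identical(back$values, lyr$values)

  # all-nodata layer still round-trips
  empty <- raster_layer("e", spec, matrix(NA_real_, 5, 7))
  write_esri_ascii(empty, path)
  expect_true(all(is.na(read_esri_ascii(path)$values)))
})

test_that("malformed ESRI ASCII inputs produce informative parse errors", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize oops", "NODATA_value -9999", "1 2 3 4"), path)
  expect_error(read_esri_ascii(path), "line 5")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2 3"), path)
  expect_error(read_esri_ascii(path), "3 values")
})

test_that("occurrence tables parse header-driven with count preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,latitude,species,longitude,extra",
               "1,20.5,wasp,100.1,a",
               "2,21.0,wasp,100.9,b",
               "3,22.5,wasp,103.0,c"), path)
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3)
  expect_equal(occ$longitude, c(100.1, 100.9, 103.0))
  expect_equal(occ$latitude[1], 20.5)

  # a typical full-size record set survives a write/read cycle intact
  big <- tibble::tibble(species = "wasp",
                        longitude = runif(194, 100, 120),
                        latitude = runif(194, 18, 30))
  write_occurrences(big, path)
  expect_equal(nrow(read_occurrences(path)), 194)

  writeLines(c("species,longitude,latitude", "wasp,abc,20"), path)
  expect_error(read_occurrences(path), "Non-numeric")
  writeLines(c("species,lon,lat", "wasp,100,20"), path)
  expect_error(read_occurrences(path), "missing columns")
})

test_that("extract_values maps points to containing cells like a per-point oracle", {
  set.seed(11)
  spec <- grid_spec(6, 8, x_ll = 100, y_ll = 20, cell_size = 0.25)
  mk <- function(nm) {
    v <- matrix(rnorm(48), 6, 8)
    v[2, 3] <- NA
    raster_layer(nm, spec, v)
  }
  st <- raster_stack(list(mk("a"), mk("b")))

  # exact centre of matrix cell (1,1) = NW corner cell
  ctr <- extract_values(st, tibble::tibble(longitude = 100.125,
                                           latitude = 21.375))
  expect_true(ctr$valid)
  expect_equal(ctr$a, st[["a"]]$values[1, 1])

  # 1e-9 degrees outside the extent is invalid
  out <- extract_values(st, tibble::tibble(longitude = 100 - 1e-9,
                                           latitude = 20.5))
  expect_false(out$valid)

  # boundary ownership: east of a vertical boundary, south of a horizontal one
  bnd <- extract_values(st, tibble::tibble(
    longitude = c(100.25, 100.1), latitude = c(20.1, 20.25)))
  expect_equal(bnd$col[1], 2)  # east cell
  expect_equal(bnd$row[1], 6)
  expect_equal(bnd$row[2], 6)  # south cell
  expect_equal(bnd$col[2], 1)

  # brute-force interval-scan oracle on 100 random points
  pts <- tibble::tibble(longitude = runif(100, 99.8, 102.2),
                        latitude = runif(100, 19.8, 21.8))
  got <- extract_values(st, pts)
  for (i in seq_len(100)) {
    lon <- pts$longitude[i]; lat <- pts$latitude[i]
    col <- NA; row_s <- NA
    for (cc in seq_len(8)) {
      left <- 100 + (cc - 1) * 0.25; right <- left + 0.25
      if ((lon >= left && lon < right) || (cc == 8 && lon == right)) col <- cc
    }
    for (rr in seq_len(6)) {  # rows counted from south in the oracle
      bot <- 20 + (rr - 1) * 0.25; top <- bot + 0.25
      if ((lat > bot && lat <= top) || (rr == 1 && lat == bot)) row_s <- rr
    }
    if (is.na(col) || is.na(row_s)) {
      expect_false(got$valid[i])
    } else {
      expect_equal(got$col[i], col)
      expect_equal(got$row[i], 6 - row_s + 1)
    }
  }

  # nodata in any layer invalidates the sample
  nod <- extract_values(st, tibble::tibble(longitude = 100.625,
                                           latitude = 21.125))
  expect_equal(nod$row, 2)
  expect_equal(nod$col, 3)
  expect_false(nod$valid)
})

test_that("stacks reject layers with mismatched geometry", {
  a <- tiny_layer(matrix(1:4, 2), "a")
  b <- tiny_layer(matrix(1:4, 2), "b", cell = 0.25)
  expect_error(raster_stack(list(a, b)), "not aligned")
  c2 <- tiny_layer(matrix(1:4, 2), "a")
  expect_error(raster_stack(list(a, c2)), "unique")
  expect_error(extract_values(raster_stack(a),
                              tibble::tibble(x = 1, y = 2)),
               "longitude")
})
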