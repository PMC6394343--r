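test_that("stack construction computes the intersection mask and r", {
  a <- matrix(rnorm(100), 10, 10)
  b <- matrix(rnorm(100), 10, 10)
  st <- covariate_stack(list(a = a, b = b), "continuous")
  expect_equal(st$r, 100L)

  b2 <- b
  b2[sample(100, 7)] <- NA
  st2 <- covariate_stack(list(a = a, b = b2), "continuous")
  expect_equal(st2$r, 93L)
  # r is invariant under layer reordering
  st3 <- covariate_stack(list(b = b2, a = a), "continuous")
  expect_equal(st3$r, st2$r)
  expect_setequal(valid_cells(st3), valid_cells(st2))
})

test_that("misaligned or degenerate stacks are rejected with the layer named", {
  a <- matrix(0, 10, 10)
  b <- matrix(0, 10, 11)
  expect_error(covariate_stack(list(a = a, bad = b), "continuous"),
               "alignment error.*bad")
  expect_error(covariate_stack(list(a = matrix(NA_real_, 3, 3)), "continuous"),
               "empty stack")
  expect_error(covariate_stack(list(a = a), "continuous",
                               crs = "+proj=longlat +datum=WGS84"),
               "geographic CRS")
})

test_that("point-to-cell mapping follows the half-open cell convention", {
  st <- seq_stack(4, 5, cellsize = 10)  # extent x [0,50], y [0,40]
  # cell centers map to their own cell
  expect_equal(xy_cell(st, 5, 35), 1L)         # row 1, col 1
  expect_equal(xy_cell(st, 45, 5), 4L + 4L * 4L)
  # a point on an interior edge belongs to the cell right/below
  expect_equal(xy_cell(st, 10, 35), 5L)        # x on edge -> col 2
  expect_equal(xy_cell(st, 5, 30), 2L)         # y on edge -> row 2
  # outer boundary still maps inside
  expect_equal(xy_cell(st, 50, 0), 20L)
  expect_error(xy_cell(st, -1, 5), "out-of-bounds.*1")
})

test_that("extract_table reads the containing cell and flags nodata points", {
  m <- matrix(as.numeric(1:20), 4, 5)
  m[2, 2] <- NA
  st <- tiny_stack(a = m, cellsize = 1)
  d <- extract_table(st, data.frame(x = 0.5, y = 3.5))
  expect_s3_class(d, "sample_design")
  expect_equal(d$a, m[1, 1])
  # a point on a nodata cell is dropped with a warning and recorded
  expect_warning(
    d2 <- extract_table(st, data.frame(x = c(0.5, 1.5), y = c(3.5, 2.5))),
    "nodata")
  expect_equal(nrow(d2), 1L)
  expect_equal(attr(d2, "dropped"), 2L)
  expect_error(suppressWarnings(
    extract_table(st, data.frame(x = 1.5, y = 2.5))), "no point")
})

test_that("write_points round-trips CSV and GeoJSON", {
  st <- tiny_stack(a = matrix(rnorm(20), 4, 5), b = matrix(rnorm(20), 4, 5),
                   cellsize = 2.5)
  d <- sample_design(st, c(1L, 7L, 18L), provenance = "grid")
  csv <- tempfile(fileext = ".csv")
  gj <- tempfile(fileext = ".geojson")
  write_points(d, csv, "csv")
  write_points(d, gj, "geojson")
  back_csv <- extract_table(st, read_points(csv))
  back_gj <- extract_table(st, read_points(gj))
  for (back in list(back_csv, back_gj)) {
    expect_equal(back$cell, d$cell)
    expect_equal(back$a, d$a, tolerance = 1e-9)
    expect_equal(back$b, d$b, tolerance = 1e-9)
  }
  expect_equal(read_points(gj)$x, d$x, tolerance = 1e-9)
  # empty designs refuse to write
  expect_error(write_points(d[0, ], tempfile(), "csv"), "empty")
})

test_that("ASCII-grid raster I/O round-trips values, geometry and nodata", {
  m <- matrix(rnorm(30), 5, 6)
  m[c(3, 14)] <- NA
  p <- tempfile(fileext = ".asc")
  write_asc(m, p, xmin = 100, ymax = 300, cellsize = 25)
  r <- read_asc(p)
  expect_equal(r$values, m, tolerance = 1e-12)
  expect_equal(r$xmin, 100)
  expect_equal(r$ymax, 300)
  expect_equal(r$cellsize, 25)
})

test_that("read_stack enforces co-registration and read_manifest wires kinds", {
  dir <- tempfile()
  dir.create(dir)
  m1 <- matrix(rnorm(24), 4, 6)
  m2 <- matrix(rep(1:3, 8), 4, 6)
  write_asc(m1, file.path(dir, "elev.asc"), cellsize = 10)
  write_asc(m2, file.path(dir, "geol.asc"), cellsize = 10)
  write_asc(m1, file.path(dir, "off.asc"), cellsize = 20)
  st <- read_stack(file.path(dir, c("elev.asc", "geol.asc")),
                   kinds = c("continuous", "categorical"))
  expect_equal(st$r, 24L)
  expect_equal(unname(st$kinds), c("continuous", "categorical"))
  expect_error(read_stack(file.path(dir, c("elev.asc", "off.asc"))),
               "alignment error.*off")
  yaml::write_yaml(list(layers = list(
    list(path = "elev.asc", name = "elevation", kind = "continuous"),
    list(path = "geol.asc", name = "geology", kind = "categorical"))),
    file.path(dir, "covars.yml"))
  st2 <- read_manifest(file.path(dir, "covars.yml"))
  expect_equal(names(st2$layers), c("elevation", "geology"))
  expect_equal(st2$layers$elevation, m1, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("write_stack + read_manifest is the identity on a stack", {
  st <- make_landscape(nrow = 8, ncol = 9, n_continuous = 2,
                       n_categorical = 1, nodata_fraction = 0.1,
                       range = 2, seed = 5)
  dir <- tempfile()
  man <- write_stack(st, dir)
  back <- read_manifest(man)
  expect_equal(back$r, st$r)
  expect_equal(back$kinds, st$kinds)
  for (nm in names(st$layers)) {
    a <- st$layers[[nm]]; a[!st$mask] <- NA
    expect_equal(back$layers[[nm]], a, tolerance = 1e-9, ignore_attr = TRUE)
  }
})
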