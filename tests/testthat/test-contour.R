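## minimal fitted-model stand-in for the scatter/threshold plumbing
stub_model <- function(coef, kept, fields, grid, sd_scaled = 1) {
  n_p <- n_grid_points(grid)
  columns <- tibble::tibble(
    field = rep(fields, each = n_p),
    grid_index = rep(seq_len(n_p), times = length(fields)),
    kept = kept
  )
  columns$sd_scaled <- ifelse(columns$kept, sd_scaled, NA_real_)
  structure(
    list(coefficients = coef, columns = columns, fields = fields, grid = grid),
    class = "comsia_qsar"
  )
}

line_grid <- function(n = 10) {
  structure(
    list(origin = c(0, 0, 0), spacing = 1, dims = c(n, 1L, 1L), padding = 0),
    class = "comsia_grid"
  )
}

test_that("coefficient maps scatter kept columns and zero-fill dropped ones", {
  g <- line_grid(10)
  kept <- rep(TRUE, 20)
  kept[5] <- FALSE  # drop S column at grid point 5
  model <- stub_model(coef = rep(0, 19), kept = kept, fields = c("S", "E"), grid = g)
  expect_equal(as.numeric(coefficient_map(model, "S")$values), rep(0, 10))

  model2 <- stub_model(coef = rep(0, 20), kept = rep(TRUE, 20),
                       fields = c("S", "E"), grid = g, sd_scaled = 2)
  model2$coefficients[5] <- 1.0  # b*s = 2.0 at S grid point 5
  map <- coefficient_map(model2, "S")
  expected <- rep(0, 10); expected[5] <- 2.0
  expect_equal(as.numeric(map$values), expected)
  ## gather back: flattening in grid order returns the scattered vector
  expect_equal(as.numeric(map$values)[model2$columns$grid_index[1:10]],
               model2$coefficients[1:10] * 2)
  expect_error(coefficient_map(model2, "D"), "not part of the model")
})

test_that("percentile thresholds use linear-interpolation quantiles of nonzero values", {
  g <- line_grid(200)
  model <- stub_model(coef = rep(0, 200), kept = rep(TRUE, 200), fields = "S", grid = g)
  model$coefficients[1:100] <- 1:100  # plus 100 structural zeros elsewhere
  map <- coefficient_map(model, "S")
  thr <- percentile_thresholds(map, 0.05)
  expect_equal(unname(thr["high"]), 95.05)
  expect_equal(unname(thr["low"]), 5.95)

  ## symmetric values give symmetric thresholds
  model$coefficients[1:100] <- c(-(1:50), 1:50)
  thr2 <- percentile_thresholds(coefficient_map(model, "S"), 0.05)
  expect_equal(unname(thr2["low"]), -unname(thr2["high"]))

  expect_error(percentile_thresholds(map, 0.5), "between 0 and 0.5")
  flat <- stub_model(coef = rep(0, 200), kept = rep(TRUE, 200), fields = "S", grid = g)
  expect_error(percentile_thresholds(coefficient_map(flat, "S"), 0.05),
               "no contourable signal")
})

test_that("isosurfaces recover the analytic Gaussian level set", {
  ## field exp(-alpha r^2); at half max the level set is a sphere of radius
  ## sqrt(ln 2 / alpha)
  alpha <- 0.3
  spacing <- 0.5
  ax <- seq(-3, 3, by = spacing)
  n <- length(ax)
  grid <- structure(
    list(origin = c(-3, -3, -3), spacing = spacing, dims = rep(n, 3L), padding = 0),
    class = "comsia_grid"
  )
  pts <- grid_points(grid)
  vals <- exp(-alpha * rowSums(pts^2))
  map <- structure(
    list(values = array(vals, grid$dims), field = "S", grid = grid),
    class = "comsia_coefmap"
  )
  ct <- extract_isosurfaces(map, c(low = 0.01, high = 0.5))
  expect_s3_class(ct, "comsia_contour")
  radii <- sqrt(rowSums(ct$high$vertices^2))
  expect_equal(mean(radii), sqrt(log(2) / alpha), tolerance = spacing)
  ## every vertex lies within the grid bounding box
  for (a in 1:3) {
    expect_true(all(ct$high$vertices[, a] >= grid$origin[a] - 1e-9))
    expect_true(all(ct$high$vertices[, a] <=
                      grid$origin[a] + (grid$dims[a] - 1) * spacing + 1e-9))
  }
  ## faces index real vertices
  expect_true(all(ct$high$faces >= 1 & ct$high$faces <= nrow(ct$high$vertices)))

  ## thresholds outside the range give an empty mesh plus a warning
  expect_warning(ct2 <- extract_isosurfaces(map, c(low = -5, high = 0.5)),
                 "outside the map range")
  expect_equal(nrow(ct2$low$faces), 0L)

  ## an all-zero map yields empty meshes (threshold never inside the range)
  zmap <- map; zmap$values[] <- 0
  ctz <- extract_isosurfaces(zmap, c(low = -1, high = 1))
  expect_equal(nrow(ctz$high$vertices), 0L)
  expect_equal(nrow(ctz$low$vertices), 0L)
})

test_that("mesh export round-trips through OBJ and emits one file per surface", {
  alpha <- 0.3
  grid <- structure(
    list(origin = c(-2, -2, -2), spacing = 0.5, dims = c(9L, 9L, 9L), padding = 0),
    class = "comsia_grid"
  )
  vals <- exp(-alpha * rowSums(grid_points(grid)^2))
  mk_contour <- function(f) {
    map <- structure(list(values = array(vals, grid$dims), field = f, grid = grid),
                     class = "comsia_coefmap")
    extract_isosurfaces(map, c(low = 0.3, high = 0.7))
  }
  contours <- lapply(c("S", "E", "H", "A", "D"), mk_contour)
  dir <- withr::local_tempdir()
  paths <- export_contours(contours, dir, format = "obj")
  expect_length(list.files(dir, pattern = "\\.obj$"), 10L)  # high + low per field

  back <- comsia:::read_obj(file.path(dir, "contour_S_high.obj"))
  expect_equal(nrow(back$vertices), nrow(contours[[1]]$high$vertices))
  expect_equal(back$vertices, contours[[1]]$high$vertices, tolerance = 1e-4)

  ## an empty mesh still writes a valid, readable file
  empty <- list(field = "S", high_threshold = 9, low_threshold = -9,
                high = list(vertices = matrix(numeric(0), 0, 3),
                            faces = matrix(integer(0), 0, 3)),
                low = list(vertices = matrix(numeric(0), 0, 3),
                           faces = matrix(integer(0), 0, 3)))
  class(empty) <- "comsia_contour"
  d2 <- withr::local_tempdir()
  export_contours(empty, d2, format = c("obj", "vtk"))
  eb <- comsia:::read_obj(file.path(d2, "contour_S_high.obj"))
  expect_equal(nrow(eb$faces), 0L)
  vtk <- readLines(file.path(d2, "contour_S_high.vtk"))
  expect_true(any(grepl("POLYGONS 0 0", vtk)))
})

test_that("cube volumes export with the grid geometry intact", {
  grid <- line_grid(4)
  grid$dims <- c(2L, 2L, 2L)
  vals <- 1:8
  path <- withr::local_tempfile(fileext = ".cube")
  comsia:::write_cube_volume(vals, grid, path)
  lines <- readLines(path)
  expect_equal(length(lines), 7 + 4)  # header block + one z-row per (x, y)
  expect_match(lines[3], "^\\s*1 ")
})
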