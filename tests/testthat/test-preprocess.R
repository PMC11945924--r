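## hand-built field tensors: preprocessing is pure array arithmetic, so the
## tests drive it with exact small inputs
fake_fields <- function(values, fields, role = "train", activities = NULL, grid = NULL) {
  n_mol <- dim(values)[1]
  nms <- sprintf("%s_%02d", role, seq_len(n_mol))
  grid <- grid %||% structure(
    list(origin = c(0, 0, 0), spacing = 1,
         dims = c(dim(values)[3], 1L, 1L), padding = 0),
    class = "comsia_grid"
  )
  structure(
    list(
      values = values, fields = fields, grid = grid,
      molecule_names = nms,
      activities = activities %||% rep(NA_real_, n_mol),
      role = role
    ),
    class = "comsia_fields"
  )
}

test_that("combining sets stacks rows train-first and validates the grid", {
  tr <- fake_fields(array(1, c(5, 2, 4)), c("S", "E"), "train", activities = 1:5)
  te <- fake_fields(array(2, c(3, 2, 4)), c("S", "E"), "test", activities = 6:8)
  comb <- combine_sets(tr, te)
  expect_equal(dim(comb$values), c(8L, 2L, 4L))
  expect_equal(comb$roles, rep(c("train", "test"), c(5, 3)))
  expect_equal(combine_sets(tr)$values, tr$values)

  bad <- fake_fields(array(0, c(2, 2, 5)), c("S", "E"), "test")
  expect_error(combine_sets(tr, bad), "share one grid")
  bad2 <- fake_fields(array(0, c(2, 1, 4)), "S", "test",
                      grid = tr$grid)
  expect_error(combine_sets(tr, bad2), "share one grid")
})

test_that("the range filter keeps exactly the columns spanning the threshold", {
  v <- array(0, c(3, 1, 3))
  v[, 1, 1] <- c(1, 1, 1)   # range 0
  v[, 1, 2] <- c(0, 2, 1)   # range 2
  v[, 1, 3] <- c(0, 0.4, 0) # range 0.4
  ff <- fake_fields(v, "S")
  expect_equal(column_filter(ff, 0), rep(TRUE, 3))
  expect_equal(column_filter(ff, 0.5), c(FALSE, TRUE, FALSE))
  expect_equal(column_filter(ff, 1.0), c(FALSE, TRUE, FALSE))
  expect_equal(column_filter(ff, 2.0), c(FALSE, TRUE, FALSE))
  expect_equal(column_filter(ff, 2.0001), c(FALSE, FALSE, FALSE))
})

test_that("block scaling gives each field zero mean and unit variance", {
  set.seed(1)
  v <- array(rnorm(6 * 2 * 10, mean = 3, sd = 4), c(6, 2, 10))
  ff <- fake_fields(v, c("S", "E"))
  sc <- scale_fields(ff)
  for (f in c("S", "E")) {
    block <- sc$X[, sc$columns$field[sc$columns$kept] == f]
    expect_equal(mean(block), 0, tolerance = 1e-8)
    expect_equal(mean((block - mean(block))^2), 1, tolerance = 1e-8)
  }
  ## idempotence: scaling an already-standardized block changes nothing
  ## invert the field-major flatten: columns are (field block) x (grid point)
  v2 <- aperm(array(sc$X, c(6, 10, 2)), c(1, 3, 2))
  ff2 <- fake_fields(v2, c("S", "E"))
  sc2 <- scale_fields(ff2)
  expect_equal(sc2$X, sc$X, tolerance = 1e-10)

  ## population variance: {0, 2} scales to {-1, +1}
  one <- fake_fields(array(c(0, 2), c(2, 1, 1)), "S")
  expect_equal(as.numeric(scale_fields(one)$X), c(-1, 1))

  ## zero-variance field is an explicit error naming the field
  flat <- fake_fields(array(5, c(3, 1, 2)), "H")
  expect_error(scale_fields(flat), "field H")
})

test_that("assembly centers on training statistics only", {
  set.seed(2)
  v <- array(rnorm(8 * 1 * 6), c(8, 1, 6))
  tr <- fake_fields(v[1:5, , , drop = FALSE], "S", "train", activities = c(5, 6, 7, 8, 9))
  te <- fake_fields(v[6:8, , , drop = FALSE], "S", "test", activities = c(6, 6, 6))
  comb <- combine_sets(tr, te)
  fm <- assemble_features(scale_fields(comb), comb)
  expect_equal(unname(colMeans(fm$X)), rep(0, ncol(fm$X)), tolerance = 1e-10)
  expect_equal(mean(fm$y), 0, tolerance = 1e-10)
  expect_equal(fm$y_mean, 7)
  ## test rows are centered with the training means, not their own
  expect_false(isTRUE(all.equal(unname(colMeans(fm$X_new)), rep(0, ncol(fm$X)))))

  ## constant activities center to an exact zero vector
  trc <- fake_fields(v[1:5, , , drop = FALSE], "S", "train", activities = rep(4.2, 5))
  combc <- combine_sets(trc)
  fmc <- assemble_features(scale_fields(combc), combc)
  expect_equal(fmc$y, rep(0, 5))

  ## a missing training activity is an error
  trm <- fake_fields(v[1:5, , , drop = FALSE], "S", "train",
                     activities = c(5, NA, 7, 8, 9))
  combm <- combine_sets(trm)
  expect_error(assemble_features(scale_fields(combm), combm), "lack activities")
})

test_that("with filtering off the kept columns cover every field/grid pair", {
  fm <- small_feature_matrix()
  fx <- small_fixture()
  expect_equal(ncol(fm$X), length(fx$spec$fields) * n_grid_points(fx$grid))
  expect_true(all(fm$columns$kept))
  ## per-column metadata identifies each column uniquely
  expect_false(anyDuplicated(fm$columns[, c("field", "grid_index")]) > 0)
})
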