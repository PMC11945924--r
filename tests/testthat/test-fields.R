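tiny_grid <- function(extent = 2, spacing = 1) {
  build_grid(
    molecule_set(list(molecule("o", tibble::tibble(
      element = "C", x = 0, y = 0, z = 0
    ))), role = "predict"),
    spacing = spacing, padding = extent
  )
}

test_that("the Gaussian kernel honours its closed form and additivity", {
  g <- tiny_grid()
  pts <- grid_points(g)
  v <- gaussian_accumulate(matrix(c(0, 0, 0), 1, 3), 2.5, g, alpha = 0.3)
  at_origin <- which(rowSums(abs(pts)) == 0)
  expect_equal(v[at_origin], 2.5)  # exp(0) = 1 at the source itself
  at_1A <- which(pts[, 1] == 1 & pts[, 2] == 0 & pts[, 3] == 0)
  expect_equal(v[at_1A] / 2.5, exp(-0.3), tolerance = 1e-12)

  ## two identical sources double the field everywhere
  v2 <- gaussian_accumulate(matrix(0, 2, 3), c(2.5, 2.5), g, alpha = 0.3)
  expect_equal(v2, 2 * v, tolerance = 1e-12)

  ## empty source list gives a zero field
  expect_equal(gaussian_accumulate(NULL, numeric(0), g, 0.3), numeric(nrow(pts)))
})

test_that("single-source fields decay monotonically and sharpen with alpha", {
  g <- tiny_grid(extent = 4)
  pts <- grid_points(g)
  v <- gaussian_accumulate(matrix(0, 1, 3), 1, g, alpha = 0.3)
  r <- sqrt(rowSums(pts^2))
  ord <- order(r)
  expect_true(all(diff(v[ord][!duplicated(sort(r))]) <= 0))
  v_sharp <- gaussian_accumulate(matrix(0, 1, 3), 1, g, alpha = 0.6)
  off <- r > 0
  expect_true(all(v_sharp[off] < v[off]))
})

test_that("vectorized field values match the naive triple-loop evaluation", {
  set.seed(3)
  centers <- matrix(rnorm(15, sd = 1.5), 5, 3)
  weights <- rnorm(5, 2)
  g <- tiny_grid(extent = 2)
  expect_equal(
    gaussian_accumulate(centers, weights, g, alpha = 0.3),
    naive_gaussian_field(centers, weights, g, alpha = 0.3),
    tolerance = 1e-12
  )
})

test_that("atomic sources carry the documented weights", {
  m <- annotated_methane()
  s <- steric_sources(m)
  expect_equal(nrow(s$centers), nrow(m$atoms))
  expect_equal(s$weights[1], 1.7^3)        # carbon vdW radius cubed
  expect_equal(s$weights[2], 1.2^3)        # hydrogen

  e <- electrostatic_sources(annotated_formaldehyde())
  expect_lt(abs(sum(e$weights)), 1e-3)     # neutral molecule
  expect_gt(e$weights[1], 0)               # carbonyl C
  expect_lt(e$weights[2], 0)               # carbonyl O

  h <- hydrophobic_sources(annotated_butane())
  expect_equal(sum(h$weights), molecule_logp(annotated_butane()), tolerance = 1e-9)
  dme <- annotated_dme()
  expect_lt(hydrophobic_sources(dme)$weights[1], 0)  # ether O

  ## suppressing nonpolar hydrogens removes exactly the C-H sources
  cfg <- field_config(include_nonpolar_h = FALSE)
  s2 <- steric_sources(m, cfg)
  expect_equal(nrow(s2$centers), 1L)
})

test_that("donor pseudoatoms sit on the X-H ray at the configured distance", {
  w <- annotated_water()
  d <- donor_pseudoatoms(w)
  expect_equal(nrow(d$centers), 2L)
  o_pos <- unlist(w$atoms[1, c("x", "y", "z")])
  for (r in 1:2) {
    expect_equal(sqrt(sum((d$centers[r, ] - o_pos)^2)), 1.9, tolerance = 1e-6)
    ## collinear with one O-H bond
    h_pos <- unlist(w$atoms[1 + r, c("x", "y", "z")])
    cosang <- sum((d$centers[r, ] - o_pos) * (h_pos - o_pos)) /
      (1.9 * sqrt(sum((h_pos - o_pos)^2)))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
  expect_equal(d$weights, c(1, 1))

  expect_equal(nrow(donor_pseudoatoms(annotated_methane())$centers), 0L)

  ## beyond-the-hydrogen placement variant
  cfg <- field_config(donor_placement = "beyond_h")
  d2 <- donor_pseudoatoms(w, cfg)
  hd <- sqrt(sum((d2$centers[1, ] - unlist(w$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(hd, 1.9, tolerance = 1e-6)
})

test_that("acceptor pseudoatoms follow idealized lone-pair geometry", {
  f <- annotated_formaldehyde()
  a <- acceptor_pseudoatoms(f)
  expect_equal(nrow(a$centers), 2L)
  o <- unlist(f$atoms[2, c("x", "y", "z")])
  cpos <- unlist(f$atoms[1, c("x", "y", "z")])
  for (r in 1:2) {
    expect_equal(sqrt(sum((a$centers[r, ] - o)^2)), 1.9, tolerance = 1e-6)
    ## 120 degrees from the O->C bond, in the molecular plane (z = 0)
    ang <- acos(sum((a$centers[r, ] - o) * (cpos - o)) / (1.9 * sqrt(sum((cpos - o)^2))))
    expect_equal(ang * 180 / pi, 120, tolerance = 1)
    expect_equal(a$centers[r, 3], 0, tolerance = 1e-9)
  }

  ## sp3 ether oxygen: two tetrahedral lone pairs out of the C-O-C plane
  dme <- annotated_dme()
  ad <- acceptor_pseudoatoms(dme)
  expect_equal(nrow(ad$centers), 2L)
  lp1 <- ad$centers[1, ] - c(0, 0, 0)
  lp2 <- ad$centers[2, ] - c(0, 0, 0)
  ang <- acos(sum(lp1 * lp2) / (1.9 * 1.9)) * 180 / pi
  expect_equal(ang, 109.47, tolerance = 2)

  expect_equal(nrow(acceptor_pseudoatoms(annotated_methane())$centers), 0L)
})

test_that("clash-filtered pseudoatoms keep their distance from other atoms", {
  ## crowded fixture: the donor O-H ray points straight at a carbon
  crowded <- molecule(
    "crowded",
    atoms = tibble::tibble(
      element = c("O", "H", "C"),
      x = c(0, 0.96, 1.9),
      y = c(0, 0, 0),
      z = c(0, 0, 0)
    ),
    bonds = tibble::tibble(from = c(1L, 1L), to = c(2L, 3L), order = 1L)
  )
  crowded <- annotate_atoms(crowded)
  d <- donor_pseudoatoms(crowded)
  expect_equal(nrow(d$centers), 0L)  # pseudoatom lands on the carbon: rejected

  ## property: surviving pseudoatoms of a fixture molecule respect the filter
  fx <- small_fixture()
  cfg <- field_config()
  for (mol in fx$train$molecules[1:4]) {
    xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
    for (ps in list(donor_pseudoatoms(mol, cfg), acceptor_pseudoatoms(mol, cfg))) {
      for (r in seq_len(nrow(ps$centers))) {
        parent <- ps$parents[r]
        expect_equal(sqrt(sum((ps$centers[r, ] - xyz[parent, ])^2)), 1.9,
                     tolerance = 1e-6)
        nb <- comsia:::neighbor_list(mol)[[parent]]
        exempt <- c(parent, nb[mol$atoms$element[nb] == "H"])
        others <- setdiff(seq_len(nrow(xyz)), exempt)
        d <- sqrt(rowSums((xyz[others, , drop = FALSE] -
                             matrix(ps$centers[r, ], length(others), 3, byrow = TRUE))^2))
        expect_true(all(d >= cfg$clash_factor * mol$atoms$vdw_radius[others]))
      }
    }
  }
})

test_that("the field tensor has the right shape and no degenerate layers", {
  fx <- small_fixture()
  g9 <- tiny_grid(extent = 4)
  cfg <- field_config(fields = "SEH")
  w <- molecule_set(list(annotated_water()), role = "predict")
  ft <- compute_all_fields(w, g9, cfg)
  expect_equal(dim(ft$values), c(1L, 3L, 729L))

  cfg_all <- field_config()
  ft_all <- suppressWarnings(compute_all_fields(fx$train[1:3], fx$grid, cfg_all))
  expect_true(all(is.finite(ft_all$values)))
  ## every enabled field layer varies over space for these molecules
  for (f in seq_along(ft_all$fields)) {
    expect_gt(max(apply(ft_all$values[, f, , drop = FALSE], 1, stats::sd)), 0)
  }
})

test_that("fields are equivariant under joint lattice translations", {
  fx <- small_fixture()
  cfg <- field_config(fields = "SE")
  set1 <- fx$train[1:2]
  g1 <- build_grid(set1, spacing = 1, padding = 3)
  t1 <- suppressWarnings(compute_all_fields(set1, g1, cfg))
  shift <- c(2, -1, 3)  # integer multiple of the spacing
  set2 <- set1
  for (i in seq_along(set2$molecules)) {
    m <- set2$molecules[[i]]
    m$atoms$x <- m$atoms$x + shift[1]
    m$atoms$y <- m$atoms$y + shift[2]
    m$atoms$z <- m$atoms$z + shift[3]
    set2$molecules[[i]] <- m
  }
  g2 <- build_grid(set2, spacing = 1, padding = 3)
  t2 <- suppressWarnings(compute_all_fields(set2, g2, cfg))
  expect_equal(g2$origin, g1$origin + shift)
  expect_equal(t2$values, t1$values, tolerance = 1e-12)
})
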