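## Small molecules with exact literature geometry, built in code so no
## binary fixtures are needed. All are annotation-ready (explicit hydrogens).

water_molecule <- function(name = "water", activity = NA_real_) {
  ## gas-phase geometry: r(OH) 0.9572 A, angle 104.52 deg
  a <- 104.52 * pi / 180
  molecule(
    name,
    atoms = tibble::tibble(
      element = c("O", "H", "H"),
      x = c(0, 0.9572, 0.9572 * cos(a)),
      y = c(0, 0, 0.9572 * sin(a)),
      z = c(0, 0, 0)
    ),
    bonds = tibble::tibble(from = c(1L, 1L), to = c(2L, 3L), order = 1L),
    activity = activity
  )
}

methane_molecule <- function(name = "methane", activity = NA_real_) {
  r <- 1.09 / sqrt(3)
  molecule(
    name,
    atoms = tibble::tibble(
      element = c("C", "H", "H", "H", "H"),
      x = c(0, r, -r, r, -r),
      y = c(0, r, -r, -r, r),
      z = c(0, r, r, -r, -r)
    ),
    bonds = tibble::tibble(from = 1L, to = 2:5, order = 1L),
    activity = activity
  )
}

formaldehyde_molecule <- function(name = "formaldehyde") {
  molecule(
    name,
    atoms = tibble::tibble(
      element = c("C", "O", "H", "H"),
      x = c(0, 1.205, -0.55, -0.55),
      y = c(0, 0, 0.94, -0.94),
      z = c(0, 0, 0, 0)
    ),
    bonds = tibble::tibble(from = c(1L, 1L, 1L), to = c(2L, 3L, 4L),
                           order = c(2L, 1L, 1L))
  )
}

dimethyl_ether_molecule <- function(name = "dme") {
  ## C-O-C angle ~111 deg, r(CO) 1.41 A; hydrogens placed tetrahedrally
  ang <- 111 * pi / 180
  c1 <- c(1.41, 0, 0)
  c2 <- c(1.41 * cos(ang), 1.41 * sin(ang), 0)
  h_of <- function(cpos, u) {
    ## three hydrogens around the C-O axis
    v <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    w1 <- v - sum(v * u) * u; w1 <- w1 / sqrt(sum(w1^2))
    t(sapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      d <- u * cos(70.5 * pi / 180) +
        (cos(phi) * w1 + sin(phi) * c(u[2] * w1[3] - u[3] * w1[2],
                                      u[3] * w1[1] - u[1] * w1[3],
                                      u[1] * w1[2] - u[2] * w1[1])) * sin(70.5 * pi / 180)
      cpos + 1.09 * d
    }))
  }
  u1 <- c1 / sqrt(sum(c1^2))
  u2 <- c2 / sqrt(sum(c2^2))
  h1 <- h_of(c1, u1)
  h2 <- h_of(c2, u2)
  molecule(
    name,
    atoms = tibble::tibble(
      element = c("O", "C", "C", rep("H", 6)),
      x = c(0, c1[1], c2[1], h1[, 1], h2[, 1]),
      y = c(0, c1[2], c2[2], h1[, 2], h2[, 2]),
      z = c(0, c1[3], c2[3], h1[, 3], h2[, 3])
    ),
    bonds = tibble::tibble(
      from = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L),
      to = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
      order = 1L
    )
  )
}

## butane-like all-anti carbon chain with explicit hydrogens
butane_molecule <- function(name = "butane") {
  cc <- 1.53
  cpos <- cbind((0:3) * cc * sin(54.75 * pi / 180) * 2 / 2,
                rep(c(0, 0.4), 2), 0)
  atoms <- tibble::tibble(element = rep("C", 4),
                          x = cpos[, 1], y = cpos[, 2], z = cpos[, 3])
  bonds <- tibble::tibble(from = 1:3, to = 2:4, order = 1L)
  ## hydrogens: coarse tetrahedral placement (geometry is not under test)
  hs <- NULL
  for (i in 1:4) {
    n_h <- if (i %in% c(1, 4)) 3 else 2
    for (j in seq_len(n_h)) {
      hs <- rbind(hs, cpos[i, ] + 1.09 * c(cos(j * 2), sin(j * 2), (-1)^(i + j) * 0.8) /
                    sqrt(cos(j * 2)^2 + sin(j * 2)^2 + 0.64))
    }
  }
  n_c <- 4L
  h_parent <- rep(1:4, times = c(3, 2, 2, 3))
  atoms <- dplyr::bind_rows(atoms, tibble::tibble(
    element = "H", x = hs[, 1], y = hs[, 2], z = hs[, 3]
  ))
  bonds <- dplyr::bind_rows(bonds, tibble::tibble(
    from = h_parent, to = n_c + seq_along(h_parent), order = 1L
  ))
  molecule(name, atoms, bonds)
}

## annotated version, memoised per session to save obabel calls
local_annotated <- local({
  cache <- new.env(parent = emptyenv())
  function(builder, key) {
    if (is.null(cache[[key]])) cache[[key]] <- annotate_atoms(builder())
    cache[[key]]
  }
})

annotated_water <- function() local_annotated(water_molecule, "water")
annotated_methane <- function() local_annotated(methane_molecule, "methane")
annotated_formaldehyde <- function() local_annotated(formaldehyde_molecule, "formaldehyde")
annotated_dme <- function() local_annotated(dimethyl_ether_molecule, "dme")
annotated_butane <- function() local_annotated(butane_molecule, "butane")
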