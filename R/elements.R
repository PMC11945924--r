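## Element data and atom typing.
##
## vdW radii are a fixed published table (Bondi 1964, with the Mantina 2009
## main-group extensions) shipped in the package so that field values do not
## depend on the version of any external chemistry library.

BONDI_VDW <- c(
  H = 1.20, He = 1.40,
  Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88,
  K = 2.75, Ca = 2.31, Zn = 1.39, Ga = 1.87, Ge = 2.11, As = 1.85, Se = 1.90,
  Br = 1.85, Kr = 2.02, Rb = 3.03, Sr = 2.49, I = 1.98, Xe = 2.16
)

ATOMIC_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34, Br = 35,
  Kr = 36, Rb = 37, Sr = 38, I = 53, Xe = 54
)

#' Van der Waals radius of an element
#'
#' Fixed Bondi-style lookup; unknown elements are an error so that a typo in
#' an input file cannot silently produce a zero-weight steric source.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- BONDI_VDW[element]
  if (anyNA(r)) {
    abort(sprintf("unknown element(s): %s",
                  paste(unique(element[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

## ---------------------------------------------------------------------------
## Hybridization from bond orders: triple bond or two+ double bonds -> sp;
## any double or aromatic bond -> sp2; else sp3. Hydrogens and isolated
## atoms report "other".
assign_hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep("sp3", n)
  n_double <- integer(n)
  n_triple <- integer(n)
  n_arom <- integer(n)
  degree <- integer(n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    f <- b$from[i]; t <- b$to[i]; o <- b$order[i]
    degree[c(f, t)] <- degree[c(f, t)] + 1L
    if (o == 2) n_double[c(f, t)] <- n_double[c(f, t)] + 1L
    if (o == 3) n_triple[c(f, t)] <- n_triple[c(f, t)] + 1L
    if (o == 4) n_arom[c(f, t)] <- n_arom[c(f, t)] + 1L
  }
  hyb[n_arom > 0 | n_double == 1] <- "sp2"
  hyb[n_triple > 0 | n_double >= 2] <- "sp"
  hyb[mol$atoms$element == "H" | degree == 0] <- "other"
  list(hybridization = hyb, degree = degree,
       n_double = n_double, n_arom = n_arom)
}

## ---------------------------------------------------------------------------
## Hydrogen-bond donor / acceptor rules.
##
## The default classification is the graph-rule equivalent of the documented
## SMARTS set:
##   donors:    [#7!H0], [#8!H0], [#16!H0]        (N-H, O-H, S-H)
##   acceptors: [#8;!$([#8+])] minus aromatic O   (carbonyl, hydroxyl, ether O)
##              [#7;!$([#7+]);!$([#7H]a);!$([NX3][CX3]=[OX1])]
##              (N not positively charged, not pyrrole-type aromatic N-H,
##               not amide N)
## Custom classifiers can be supplied to annotate_atoms().

default_donor_rule <- function(mol, ctx) {
  el <- mol$atoms$element
  el %in% c("N", "O", "S") & ctx$n_h > 0
}

default_acceptor_rule <- function(mol, ctx) {
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  acc <- rep(FALSE, nrow(mol$atoms))
  ## oxygen: anything not positively charged and not an aromatic ring O
  acc[el == "O" & fc <= 0 & ctx$n_arom == 0] <- TRUE
  ## nitrogen: exclude positive N, pyrrole-type aromatic N-H, amide N
  is_n <- el == "N" & fc <= 0
  pyrrole <- is_n & ctx$n_arom > 0 & ctx$n_h > 0
  amide <- is_n & ctx$amide_n
  acc[is_n & !pyrrole & !amide] <- TRUE
  acc
}

## N single-bonded to a carbonyl carbon
flag_amide_n <- function(mol, nb) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  carbonyl_c <- rep(FALSE, n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    if (b$order[i] == 2) {
      f <- b$from[i]; t <- b$to[i]
      if (el[f] == "C" && el[t] == "O") carbonyl_c[f] <- TRUE
      if (el[t] == "C" && el[f] == "O") carbonyl_c[t] <- TRUE
    }
  }
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (el[i] == "N" && length(nb[[i]])) {
      out[i] <- any(carbonyl_c[nb[[i]]])
    }
  }
  out
}

## ---------------------------------------------------------------------------
## Atomic hydrophobicity contributions.
##
## A fixed Wildman-Crippen-type atomic contribution table: every atom is
## assigned to a coarse class from its element and bonded environment and
## contributes a signed increment to the molecular logP. The whole-molecule
## logP of this scheme is by construction the sum of the per-atom values,
## which is the quantity the hydrophobic field spreads over the lattice.

HYDROPHOBIC_CONTRIB <- c(
  C_sp3 = 0.1441, C_sp3_het = -0.2035,
  C_unsat = 0.1551, C_unsat_het = -0.0516, C_carbonyl = -0.2783,
  C_arom = 0.1581, C_arom_het = 0.0000,
  N_amine_h = -1.0190, N_tert = -0.3187, N_arom = -0.3239,
  N_amide = -0.4458, N_unsat = -0.3396, N_pos = -1.9500,
  O_hydroxyl = -0.2893, O_ether = -0.0684, O_carbonyl = -0.2500,
  O_arom = 0.1552, O_neg = -0.5700,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
  S = 0.6482, P = 0.8612,
  H_on_c = 0.1230, H_polar = -0.2677,
  other = 0.0000
)

hydrophobic_class <- function(mol, ctx, nb) {
  n <- nrow(mol$atoms)
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  hyb <- ctx$hybridization
  cls <- character(n)
  hetero <- !(el %in% c("C", "H"))
  has_het_nb <- vapply(seq_len(n), function(i) {
    length(nb[[i]]) > 0 && any(hetero[nb[[i]]])
  }, logical(1))
  for (i in seq_len(n)) {
    e <- el[i]
    cls[i] <- if (e == "C") {
      if (ctx$n_arom[i] > 0) {
        if (has_het_nb[i]) "C_arom_het" else "C_arom"
      } else if (ctx$carbonyl_c[i]) {
        "C_carbonyl"
      } else if (hyb[i] %in% c("sp2", "sp")) {
        if (has_het_nb[i]) "C_unsat_het" else "C_unsat"
      } else {
        if (has_het_nb[i]) "C_sp3_het" else "C_sp3"
      }
    } else if (e == "N") {
      if (fc[i] > 0) "N_pos"
      else if (ctx$amide_n[i]) "N_amide"
      else if (ctx$n_arom[i] > 0) "N_arom"
      else if (hyb[i] %in% c("sp2", "sp")) "N_unsat"
      else if (ctx$n_h[i] > 0) "N_amine_h"
      else "N_tert"
    } else if (e == "O") {
      if (fc[i] < 0) "O_neg"
      else if (ctx$n_arom[i] > 0) "O_arom"
      else if (ctx$n_double[i] > 0) "O_carbonyl"
      else if (ctx$n_h[i] > 0) "O_hydroxyl"
      else "O_ether"
    } else if (e == "H") {
      parent <- if (length(nb[[i]])) el[nb[[i]][1]] else "C"
      if (parent == "C") "H_on_c" else "H_polar"
    } else if (e %in% c("F", "Cl", "Br", "I", "S", "P")) {
      e
    } else {
      "other"
    }
  }
  cls
}

#' Whole-molecule logP of the package's atomic contribution scheme
#'
#' Sum of the per-atom hydrophobicity contributions assigned by
#' [annotate_atoms()].
#'
#' @param mol an annotated `comsia_mol`.
#' @return single numeric.
#' @export
molecule_logp <- function(mol) {
  if (!is_annotated(mol)) mol <- annotate_atoms(mol)
  sum(mol$atoms$hydrophobicity)
}
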