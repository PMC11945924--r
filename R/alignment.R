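## Maximum-common-substructure alignment.
##
## Molecules are compared as heavy-atom graphs (element-labelled vertices,
## bond-order-labelled edges). The maximum common connected induced subgraph
## is found by McGregor-style backtracking, folded pairwise across the set;
## the resulting core is matched into every molecule and used as the rigid
## superposition frame.

## heavy-atom graph: elements, adjacency matrix of bond orders, and the
## original atom indices each vertex maps to
mol_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  idx <- match(seq_len(nrow(mol$atoms)), heavy)
  n <- length(heavy)
  adj <- matrix(0L, n, n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    f <- idx[b$from[i]]; t <- idx[b$to[i]]
    if (!is.na(f) && !is.na(t)) {
      adj[f, t] <- adj[t, f] <- as.integer(b$order[i])
    }
  }
  list(elements = mol$atoms$element[heavy], adj = adj, atom_index = heavy)
}

subgraph_of <- function(g, vertices) {
  list(
    elements = g$elements[vertices],
    adj = g$adj[vertices, vertices, drop = FALSE],
    atom_index = g$atom_index[vertices]
  )
}

## maximum common connected induced subgraph between two graphs; returns the
## g1 vertex vector and its g2 image (both in g1-exploration order)
mccs_pair <- function(g1, g2, match_order = TRUE) {
  n1 <- length(g1$elements); n2 <- length(g2$elements)
  best <- list(size = 0L, v1 = integer(0), v2 = integer(0))
  order_ok <- function(o1, o2) if (match_order) o1 == o2 else (o1 > 0) == (o2 > 0)
  ## upper bound on extension: compatible element multiset overlap
  compat_bound <- function(used1, used2) {
    e1 <- table(g1$elements[!used1])
    e2 <- table(g2$elements[!used2])
    common <- intersect(names(e1), names(e2))
    sum(pmin(as.integer(e1[common]), as.integer(e2[common])))
  }
  extend <- function(v1, v2, used1, used2) {
    size <- length(v1)
    if (size > best$size) best <<- list(size = size, v1 = v1, v2 = v2)
    if (size + compat_bound(used1, used2) <= best$size) return(invisible())
    ## frontier candidate pairs
    cand <- NULL
    for (a in seq_len(n1)) {
      if (used1[a]) next
      touches <- any(g1$adj[a, v1] > 0)
      if (!touches) next
      for (b in seq_len(n2)) {
        if (used2[b] || g1$elements[a] != g2$elements[b]) next
        ok <- TRUE
        for (m in seq_len(size)) {
          if (!order_ok(g1$adj[a, v1[m]], g2$adj[b, v2[m]])) { ok <- FALSE; break }
        }
        if (ok) cand <- rbind(cand, c(a, b))
      }
    }
    if (is.null(cand)) return(invisible())
    ## branch on the lowest-numbered frontier atom of g1: map it to each
    ## compatible partner, or exclude it from the common subgraph
    a0 <- min(cand[, 1])
    for (r in which(cand[, 1] == a0)) {
      b <- cand[r, 2]
      u1 <- used1; u2 <- used2
      u1[a0] <- TRUE; u2[b] <- TRUE
      extend(c(v1, a0), c(v2, b), u1, u2)
    }
    u1 <- used1; u1[a0] <- TRUE
    extend(v1, v2, u1, used2)
  }
  ## seed pairs, deterministic order
  for (a in seq_len(n1)) {
    for (b in seq_len(n2)) {
      if (g1$elements[a] != g2$elements[b]) next
      used1 <- rep(FALSE, n1); used2 <- rep(FALSE, n2)
      used1[a] <- TRUE; used2[b] <- TRUE
      extend(a, b, used1, used2)
    }
  }
  best
}

## first embedding of the (small) core graph into a molecule graph, induced
## semantics; returns core-order vector of g vertices or NULL
embed_core <- function(core, g, match_order = TRUE) {
  nc <- length(core$elements)
  order_ok <- function(o1, o2) if (match_order) o1 == o2 else (o1 > 0) == (o2 > 0)
  ## explore core vertices in a connectivity-respecting order
  explore <- integer(0)
  remaining <- seq_len(nc)
  explore <- 1L
  remaining <- setdiff(remaining, 1L)
  while (length(remaining)) {
    nxt <- remaining[vapply(remaining, function(r) any(core$adj[r, explore] > 0), logical(1))]
    nxt <- if (length(nxt)) nxt[1] else remaining[1]
    explore <- c(explore, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  assign_vec <- rep(NA_integer_, nc)
  used <- rep(FALSE, length(g$elements))
  search <- function(pos) {
    if (pos > nc) return(TRUE)
    c_v <- explore[pos]
    for (b in seq_along(g$elements)) {
      if (used[b] || g$elements[b] != core$elements[c_v]) next
      ok <- TRUE
      for (q in seq_len(pos - 1L)) {
        c_u <- explore[q]
        if (!order_ok(core$adj[c_v, c_u], g$adj[b, assign_vec[c_u]])) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[c_v] <<- b
      used[b] <<- TRUE
      if (search(pos + 1L)) return(TRUE)
      used[b] <<- FALSE
      assign_vec[c_v] <<- NA_integer_
    }
    FALSE
  }
  if (search(1L)) assign_vec else NULL
}

#' Find the maximum common substructure of a molecule set
#'
#' Backtracking search for the largest connected substructure (strict
#' element and bond-order matching by default) shared by every molecule,
#' folded pairwise: the core of the first two molecules is intersected with
#' each further molecule in turn.
#'
#' @param set a `comsia_molset` with at least 2 molecules.
#' @param match_order logical; require equal bond orders (default) or mere
#'   connectivity.
#' @return an object of class `comsia_mcs`: `smarts` (a SMARTS rendering of
#'   the core), `size`, `core` (internal graph) and `matches` (named list:
#'   per molecule, the atom indices the core maps onto, in core order).
#' @export
find_mcs <- function(set, match_order = TRUE) {
  if (length(set) < 2) abort("MCS requires at least 2 molecules")
  graphs <- lapply(set$molecules, mol_graph)
  core <- graphs[[1]]
  for (k in 2:length(graphs)) {
    m <- mccs_pair(core, graphs[[k]], match_order = match_order)
    if (m$size < 3) {
      abort("alignment core too small: no common substructure of >= 3 atoms")
    }
    core <- subgraph_of(core, sort(m$v1))
  }
  matches <- lapply(graphs, function(g) {
    emb <- embed_core(core, g, match_order = match_order)
    if (is.null(emb)) abort("internal error: core failed to match a set member")
    g$atom_index[emb]
  })
  names(matches) <- names(set)
  structure(
    list(
      smarts = core_to_smarts(core),
      size = length(core$elements),
      core = core,
      matches = matches
    ),
    class = "comsia_mcs"
  )
}

#' @export
print.comsia_mcs <- function(x, ...) {
  cat(sprintf("<comsia_mcs> %d-atom core: %s\n", x$size, x$smarts))
  invisible(x)
}

## SMARTS rendering of the core graph (DFS with ring-closure digits)
core_to_smarts <- function(core) {
  n <- length(core$elements)
  atomic_num <- ATOMIC_NUMBERS[core$elements]
  bond_sym <- function(o) switch(as.character(o), `1` = "", `2` = "=", `3` = "#", `4` = ":", "~")
  visited <- rep(FALSE, n)
  ring_bonds <- list()
  ring_digit <- 0L
  closure_at <- vector("list", n)
  ## first pass: find back edges via DFS
  parent <- rep(NA_integer_, n)
  dfs_order <- integer(0)
  stack <- 1L
  visited[1] <- TRUE
  walk <- function(v) {
    dfs_order <<- c(dfs_order, v)
    for (w in which(core$adj[v, ] > 0)) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        parent[w] <<- v
        walk(w)
      } else if (!identical(parent[v], w) && v < w) {
        ## back edge: assign a ring-closure digit to both ends
        ring_digit <<- ring_digit + 1L
        closure_at[[v]] <<- c(closure_at[[v]], setNames(ring_digit, bond_sym(core$adj[v, w])))
        closure_at[[w]] <<- c(closure_at[[w]], setNames(ring_digit, ""))
      }
    }
  }
  walk(1L)
  emit <- function(v, bond_in) {
    s <- paste0(bond_in, sprintf("[#%d]", atomic_num[v]))
    for (i in seq_along(closure_at[[v]])) {
      s <- paste0(s, names(closure_at[[v]])[i], closure_at[[v]][i])
    }
    kids <- which(parent == v)
    kids <- kids[order(match(kids, dfs_order))]
    for (i in seq_along(kids)) {
      sub <- emit(kids[i], bond_sym(core$adj[v, kids[i]]))
      s <- if (i < length(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
    }
    s
  }
  emit(1L, "")
}

## ---------------------------------------------------------------------------

## Kabsch: optimal rotation + translation mapping moving -> target
kabsch_transform <- function(moving, target) {
  cm <- colMeans(moving)
  ct <- colMeans(target)
  A <- sweep(moving, 2, cm)
  B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, center_moving = cm, center_target = ct)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_moving) %*% t(tr$R), 2, tr$center_target, "+")
}

#' Align a molecule set on its maximum common substructure
#'
#' The first molecule (or the named `template`) defines the common frame.
#' Molecules lacking 3D coordinates (SMILES input) are first built in 3D
#' with the deterministic OpenBabel structure generator, which
#' energy-minimizes each conformer; every molecule is then rigidly
#' superposed (Kabsch) so its MCS core atoms best fit the template's core
#' coordinates, and the residual core RMSD is reported. Deterministic for a
#' given input and seed.
#'
#' @param set a `comsia_molset`.
#' @param seed integer seed for any package-owned randomness (recorded in
#'   the result; the 3D builder itself is deterministic).
#' @param template optional molecule name to use as the template instead of
#'   the first molecule.
#' @param match_order see [find_mcs()].
#' @return an object of class `comsia_alignment`: `aligned` (molset),
#'   `template_name`, `core_rmsd` (named, Angstrom), `mcs_smarts`, `mcs`.
#' @export
align_set <- function(set, seed = 1L, template = NULL, match_order = TRUE) {
  set.seed(seed)
  ## embed molecules that still lack 3D coordinates
  for (i in seq_along(set$molecules)) {
    mol <- set$molecules[[i]]
    if (needs_embedding(mol)) {
      if (is.null(mol$smiles)) {
        abort(sprintf("molecule '%s' has no 3D coordinates and no SMILES to embed from", mol$name))
      }
      emb <- embed_smiles(mol$smiles, mol$name)
      emb$activity <- mol$activity
      set$molecules[[i]] <- emb
    }
  }
  template <- template %||% names(set)[1]
  t_idx <- match(template, names(set))
  if (is.na(t_idx)) abort(sprintf("template '%s' is not in the set", template))
  if (length(set) == 1L) {
    return(structure(
      list(
        aligned = set, template_name = template,
        core_rmsd = setNames(0, template), mcs_smarts = NA_character_,
        mcs = NULL, seed = seed
      ),
      class = "comsia_alignment"
    ))
  }
  mcs <- find_mcs(set, match_order = match_order)
  t_core <- coords_matrix(set[[t_idx]])[mcs$matches[[t_idx]], , drop = FALSE]
  rmsd <- setNames(numeric(length(set)), names(set))
  for (i in seq_along(set$molecules)) {
    mol <- set$molecules[[i]]
    xyz <- coords_matrix(mol)
    core_xyz <- xyz[mcs$matches[[i]], , drop = FALSE]
    if (i != t_idx) {
      tr <- kabsch_transform(core_xyz, t_core)
      xyz <- apply_transform(xyz, tr)
      core_xyz <- xyz[mcs$matches[[i]], , drop = FALSE]
      set$molecules[[i]] <- set_coords(mol, xyz)
    }
    rmsd[i] <- sqrt(mean(rowSums((core_xyz - t_core)^2)))
  }
  structure(
    list(
      aligned = set, template_name = template, core_rmsd = rmsd,
      mcs_smarts = mcs$smarts, mcs = mcs, seed = seed
    ),
    class = "comsia_alignment"
  )
}

#' @export
print.comsia_alignment <- function(x, ...) {
  cat(sprintf(
    "<comsia_alignment> %d molecules on template '%s' (core: %s)\n  core RMSD: %s A\n",
    length(x$aligned), x$template_name, x$mcs_smarts %||% "<none>",
    paste(sprintf("%.3f", x$core_rmsd), collapse = ", ")
  ))
  invisible(x)
}

#' Per-molecule core RMSD as a tibble
#' @param x a `comsia_alignment`.
#' @param ... unused.
#' @return tibble with `molecule`, `core_rmsd`.
#' @export
tidy.comsia_alignment <- function(x, ...) {
  tibble::tibble(molecule = names(x$core_rmsd), core_rmsd = unname(x$core_rmsd))
}
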