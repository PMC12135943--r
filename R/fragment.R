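#' Fragment a molecule around a rotatable bond
#'
#' Carves out the chemical environment of a target bond so that its torsion
#' profile can be scanned on a much smaller system. The fragment contains the
#' two axis atoms and every heavy atom within `shells` bond-graph shells of
#' either axis atom; ring systems, multiple-bond partners (keeping carbonyls,
#' imines and conjugated units intact) and charged neighbours of any included
#' atom are completed iteratively. Heavy bonds cut at the fragment boundary are
#' capped with hydrogens.
#'
#' The scheme is a transparent shell-based fragmenter: it is documented,
#' deterministic and testable, and by construction preserves the target torsion
#' quadruple under `parent_map`.
#'
#' @param mol parent `mol_graph`.
#' @param bond one row of a [detect_rotatable_bonds()] result (or any list with
#'   fields `i`, `j`, `a`, `b`, `label`).
#' @param shells integer number of bond shells around the axis (>= 1,
#'   default 2).
#' @return an object of class `mol_fragment`: a list with `graph` (the fragment
#'   `mol_graph`), `parent_map` (fragment atom index -> parent atom index, `NA`
#'   for cap hydrogens), `target_torsion` (the `(a, i, j, b)` quadruple
#'   re-indexed into the fragment), `cap_atoms` and `bond_label`.
#' @export
fragment_around_bond <- function(mol, bond, shells = 2L) {
  if (!inherits(mol, "mol_graph")) abort_input("'mol' must be a mol_graph")
  shells <- as.integer(shells)
  if (is.na(shells) || shells < 1L) abort_input("'shells' must be >= 1")
  bd <- as.list(bond)
  quad <- as.integer(c(bd$a, bd$i, bd$j, bd$b))
  if (anyNA(quad)) abort_logic("bond must carry fields a, i, j, b")
  n <- n_atoms(mol)
  if (any(quad < 1L | quad > n)) abort_logic("bond does not belong to molecule")
  if (!length(bond_index(mol, bd$i, bd$j))) {
    abort_logic("bond (", bd$i, ",", bd$j, ") not present in molecule '",
                mol$name, "'")
  }

  g <- as_igraph(mol, heavy_only = TRUE)
  hv <- heavy_atoms(mol)
  d <- igraph::distances(g, v = c(bd$i, bd$j))
  keep <- rep(FALSE, n)
  keep[hv] <- apply(d[, hv, drop = FALSE], 2, min) <= shells
  keep[quad] <- TRUE

  # ring systems: connected components of the subgraph of ring bonds
  rb <- mol$bonds[mol$bonds$in_ring, , drop = FALSE]
  ring_comp <- rep(NA_integer_, n)
  if (nrow(rb)) {
    rg <- edge_graph(n, rb$i, rb$j)
    comp <- igraph::components(rg)$membership
    in_ring_atom <- seq_len(n) %in% unique(c(rb$i, rb$j))
    ring_comp[in_ring_atom] <- comp[in_ring_atom]
  }

  repeat {
    before <- sum(keep)
    # complete ring systems touched by the fragment
    touched <- unique(stats::na.omit(ring_comp[keep]))
    if (length(touched)) keep[which(ring_comp %in% touched)] <- TRUE
    # complete multiple bonds and charged neighbours
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (keep[i] == keep[j]) next
      multi <- mol$bonds$order[k] > 1L
      charged <- mol$atoms$charge[i] != 0L || mol$atoms$charge[j] != 0L
      if (multi || charged) keep[c(i, j)] <- TRUE
    }
    if (sum(keep) == before) break
  }
  # explicit hydrogens riding on kept heavy atoms come along
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (keep[i] && mol$atoms$element[j] == "H") keep[j] <- TRUE
    if (keep[j] && mol$atoms$element[i] == "H") keep[i] <- TRUE
  }

  kept <- which(keep)
  new_idx <- match(seq_len(n), kept)
  atoms <- mol$atoms[kept, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- mol$bonds[keep[mol$bonds$i] & keep[mol$bonds$j], , drop = FALSE]
  bonds <- data.frame(i = new_idx[bsel$i], j = new_idx[bsel$j],
                      order = bsel$order)
  parent_map <- kept
  coords <- if (!is.null(mol$coords)) mol$coords[kept, , drop = FALSE] else NULL

  # hydrogen caps on cut heavy-heavy bonds
  cut <- mol$bonds[xor(keep[mol$bonds$i], keep[mol$bonds$j]), , drop = FALSE]
  cap_atoms <- integer(0)
  for (k in seq_len(nrow(cut))) {
    inside <- if (keep[cut$i[k]]) cut$i[k] else cut$j[k]
    outside <- if (keep[cut$i[k]]) cut$j[k] else cut$i[k]
    if (mol$atoms$element[outside] == "H") next
    atoms <- rbind(atoms, data.frame(element = "H", charge = 0L))
    idx <- nrow(atoms)
    bonds <- rbind(bonds, data.frame(i = new_idx[inside], j = idx, order = 1L))
    parent_map <- c(parent_map, NA_integer_)
    cap_atoms <- c(cap_atoms, idx)
    if (!is.null(coords)) {
      # place the cap along the cut bond direction at a standard X-H length
      v <- mol$coords[outside, ] - mol$coords[inside, ]
      v <- v / sqrt(sum(v^2))
      coords <- rbind(coords, mol$coords[inside, ] + 1.09 * v)
    }
  }

  graph <- mol_graph(atoms, bonds, coords = coords,
                     name = paste0(mol$name, ":", bd$label %||% "frag"))
  structure(list(graph = graph,
                 parent_map = parent_map,
                 target_torsion = new_idx[quad],
                 cap_atoms = cap_atoms,
                 bond_label = bd$label %||% NA_character_),
            class = "mol_fragment")
}

#' @export
print.mol_fragment <- function(x, ...) {
  cat(sprintf("<mol_fragment> %s: %d atoms (%d caps), torsion (%s)%s\n",
              x$graph$name, n_atoms(x$graph), length(x$cap_atoms),
              paste(x$target_torsion, collapse = ","),
              if (is.null(x$graph$coords)) "" else ", 3D"))
  invisible(x)
}

#' Generate 3D coordinates for a fragment
#'
#' Embeds the fragment with the ETKDG distance-geometry conformer generator
#' followed by an MMFF94 cleanup (driven through the system python's RDKit;
#' an OpenBabel fallback covers installations without it). Implicit hydrogens
#' are made explicit during embedding and appended to the fragment graph; the
#' heavy-atom order and the cap hydrogens of the input are preserved, so
#' `parent_map` and `target_torsion` remain valid. Embedding is deterministic
#' for a fixed `seed`: repeated calls reproduce identical coordinates. Retry
#' attempts advance the seed.
#'
#' The embedded geometry is validated: no two atoms closer than 0.7 Angstrom
#' and all bonded distances within 0.6-2.0 Angstrom (failures trigger bounded
#' retries, then an error condition of class `atroposcan_embed_error` that
#' pipeline drivers catch per fragment).
#'
#' @param fragment a `mol_fragment` (or a plain `mol_graph`).
#' @param seed integer seed.
#' @param max_attempts bounded retry count.
#' @return the fragment with `graph$coords` populated.
#' @export
embed_3d <- function(fragment, seed = 1L, max_attempts = 3L) {
  plain <- inherits(fragment, "mol_graph")
  frag <- if (plain) {
    structure(list(graph = fragment,
                   parent_map = seq_len(n_atoms(fragment)),
                   target_torsion = NULL, cap_atoms = integer(0),
                   bond_label = NA_character_),
              class = "mol_fragment")
  } else fragment
  n_in <- n_atoms(frag$graph)
  sdf_in <- write_sdf(frag$graph)
  last_err <- NULL
  for (attempt in seq_len(max_attempts)) {
    res <- tryCatch({
      out <- gen3d_sdf(sdf_in, seed = seed + attempt - 1L)
      m <- sdf_text_to_mol(out, name = frag$graph$name)
      check_embedding(m, n_in, frag$graph)
      m
    }, error = function(e) e)
    if (!inherits(res, "error")) {
      frag$graph <- res
      frag$parent_map <- c(frag$parent_map,
                           rep(NA_integer_, n_atoms(res) - n_in))
      return(if (plain) frag$graph else frag)
    }
    last_err <- res
  }
  stop(errorCondition(
    paste0("3D embedding failed for fragment '", frag$graph$name, "' after ",
           max_attempts, " attempts: ", conditionMessage(last_err)),
    class = c("atroposcan_embed_error", "atroposcan_error")))
}

check_embedding <- function(m, n_in, graph_in) {
  if (is.null(m$coords)) abort_input("no 3D coordinates generated")
  if (n_atoms(m) < n_in) abort_input("embedding lost atoms")
  if (!identical(m$atoms$element[seq_len(n_in)],
                 graph_in$atoms$element[seq_len(n_in)])) {
    abort_input("embedding permuted atoms")
  }
  dmin <- min(stats::dist(m$coords))
  if (dmin < 0.7) abort_input(sprintf("atoms too close (%.2f A)", dmin))
  dl <- bond_lengths(m)
  if (any(dl < 0.6 | dl > 2.0)) {
    abort_input("bonded distance outside 0.6-2.0 A")
  }
  invisible(TRUE)
}

bond_lengths <- function(mol) {
  if (!nrow(mol$bonds)) return(numeric(0))
  d <- mol$coords[mol$bonds$i, , drop = FALSE] -
    mol$coords[mol$bonds$j, , drop = FALSE]
  sqrt(rowSums(d^2))
}
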