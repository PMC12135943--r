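#' Detect non-terminal rotatable bonds
#'
#' Finds every acyclic single bond whose two axis atoms are heavy atoms with at
#' least two heavy neighbours each. Amide (peptide) C-N bonds are deliberately
#' *included*: their partial double-bond character is precisely what makes them
#' candidate atropisomer axes in flexible beyond-rule-of-5 molecules. The two
#' conjugation-locked bonds of ester and carbamate units -- the carbonyl-to-
#' ester-oxygen bond `(O=)C-O` and the carbamate nitrogen-to-carbonyl bond
#' `N-C(=O)O` -- are excluded, as in the strict rotatable-bond conventions; the
#' ester `O-`alkyl bond remains rotatable.
#'
#' Each detected bond carries a measured torsion quadruple `(a, i, j, b)`. The
#' flanking atoms `a` and `b` are the heavy neighbour of highest atomic number
#' (ties broken by lowest atom index) on each side of the axis.
#'
#' @param mol a `mol_graph` (a valid, connected, sanitized molecule).
#' @return data.frame of class `rotatable_bonds` with columns `label`, `i`,
#'   `j`, `a`, `b`, ordered by `(min(i,j), max(i,j))`; zero rows when the
#'   molecule has no rotatable bond.
#' @examples
#' \donttest{
#' detect_rotatable_bonds(read_smiles("CCCC", "butane"))   # one bond, C2-C3
#' }
#' @export
detect_rotatable_bonds <- function(mol) {
  if (!inherits(mol, "mol_graph")) abort_input("'mol' must be a mol_graph")
  b <- mol$bonds
  rows <- list()
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      if (b$order[k] != 1L || b$in_ring[k]) next
      i <- b$i[k]; j <- b$j[k]
      if (mol$atoms$element[i] == "H" || mol$atoms$element[j] == "H") next
      nb_i <- heavy_neighbours(mol, i)
      nb_j <- heavy_neighbours(mol, j)
      if (length(nb_i) < 2L || length(nb_j) < 2L) next
      if (is_ester_single_bond(mol, i, j) || is_ester_single_bond(mol, j, i)) next
      if (is_carbamate_nc_bond(mol, i, j) || is_carbamate_nc_bond(mol, j, i)) next
      a <- pick_flank(mol, setdiff(nb_i, j))
      bb <- pick_flank(mol, setdiff(nb_j, i))
      rows[[length(rows) + 1L]] <- data.frame(i = i, j = j, a = a, b = bb)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), a = integer(), b = integer())
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(label = if (nrow(out))
    paste0(mol$name, "-", seq_len(nrow(out))) else character(0), out)
  class(out) <- c("rotatable_bonds", "data.frame")
  attr(out, "molecule") <- mol$name
  out
}

# (O=)C-O single bond of an ester, carbamate or anhydride: `c_idx` is a carbon
# that also bears a double-bonded oxygen, `o_idx` the single-bonded oxygen.
is_ester_single_bond <- function(mol, c_idx, o_idx) {
  if (mol$atoms$element[c_idx] != "C" || mol$atoms$element[o_idx] != "O") {
    return(FALSE)
  }
  has_carbonyl_oxygen(mol, c_idx, exclude = o_idx)
}

# N-C(=O)O carbamate/urethane nitrogen-to-carbonyl bond. Plain amides
# (carbonyl carbon without a single-bonded, non-terminal oxygen) are kept.
is_carbamate_nc_bond <- function(mol, n_idx, c_idx) {
  if (mol$atoms$element[n_idx] != "N" || mol$atoms$element[c_idx] != "C") {
    return(FALSE)
  }
  if (!has_carbonyl_oxygen(mol, c_idx)) return(FALSE)
  for (nb in heavy_neighbours(mol, c_idx)) {
    if (nb == n_idx || mol$atoms$element[nb] != "O") next
    bo <- mol$bonds$order[bond_index(mol, c_idx, nb)]
    if (bo == 1L && length(heavy_neighbours(mol, nb)) >= 2L) return(TRUE)
  }
  FALSE
}

has_carbonyl_oxygen <- function(mol, c_idx, exclude = integer(0)) {
  for (nb in heavy_neighbours(mol, c_idx)) {
    if (nb %in% exclude || mol$atoms$element[nb] != "O") next
    if (mol$bonds$order[bond_index(mol, c_idx, nb)] == 2L) return(TRUE)
  }
  FALSE
}

# Flanking-atom rule: highest atomic number, then lowest atom index.
pick_flank <- function(mol, candidates) {
  z <- atomic_number(mol$atoms$element[candidates])
  candidates[order(-z, candidates)][1]
}
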