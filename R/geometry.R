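#' Measure a dihedral angle
#'
#' Standard signed dihedral for the quadruple `(a, i, j, b)`: looking down the
#' `i -> j` axis, the angle from the `a-i-j` plane to the `i-j-b` plane,
#' reported in degrees in `(-180, 180]`.
#'
#' @param coords numeric `n x 3` coordinate matrix (Angstrom).
#' @param quad integer vector `(a, i, j, b)` of 1-based atom indices.
#' @return dihedral angle in degrees.
#' @export
measure_dihedral <- function(coords, quad) {
  p <- coords[quad, , drop = FALSE]
  b0 <- p[2, ] - p[1, ]
  b1 <- p[3, ] - p[2, ]
  b2 <- p[4, ] - p[3, ]
  n1 <- cross3(b0, b1)
  n2 <- cross3(b1, b2)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    abort_input("collinear torsion atoms: dihedral undefined")
  }
  b1u <- b1 / sqrt(sum(b1^2))
  m1 <- cross3(n1, b1u)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Set a dihedral angle
#'
#' Rigidly rotates the `j`-side of the axis bond `(i, j)` about the bond axis
#' until the measured dihedral of `quad = (a, i, j, b)` equals `target_deg`.
#' Only atoms on the rotated side move; all bond lengths are preserved exactly
#' (rigid rotation). The axis bond must be acyclic -- removing it must split
#' the molecule in two.
#'
#' @param fragment a `mol_fragment` (or `mol_graph`) with coordinates.
#' @param quad torsion quadruple `(a, i, j, b)`; defaults to the fragment's
#'   target torsion.
#' @param target_deg desired dihedral in degrees.
#' @return the input object with rotated coordinates.
#' @export
set_dihedral <- function(fragment, target_deg, quad = NULL) {
  plain <- inherits(fragment, "mol_graph")
  g <- if (plain) fragment else fragment$graph
  if (is.null(g$coords)) abort_input("fragment has no coordinates; embed first")
  quad <- quad %||% (if (!plain) fragment$target_torsion else NULL)
  if (is.null(quad)) abort_input("no torsion quadruple supplied")
  i <- quad[2]; j <- quad[3]
  current <- measure_dihedral(g$coords, quad)
  delta <- wrap_angle(target_deg - current)
  if (abs(delta) > 1e-12) {
    moving <- j_side_atoms(g, i, j)
    axis <- g$coords[j, ] - g$coords[i, ]
    axis <- axis / sqrt(sum(axis^2))
    rot <- rotation_matrix(axis, delta * pi / 180)
    shifted <- sweep(g$coords[moving, , drop = FALSE], 2, g$coords[i, ])
    g$coords[moving, ] <- sweep(shifted %*% t(rot), 2, g$coords[i, ], "+")
    # fix the sign convention empirically: if the dihedral moved the wrong
    # way, rotate back twice as far
    got <- measure_dihedral(g$coords, quad)
    if (abs(wrap_angle(got - target_deg)) > 1e-6) {
      rot2 <- rotation_matrix(axis, -2 * delta * pi / 180)
      shifted <- sweep(g$coords[moving, , drop = FALSE], 2, g$coords[i, ])
      g$coords[moving, ] <- sweep(shifted %*% t(rot2), 2, g$coords[i, ], "+")
    }
  }
  if (plain) g else { fragment$graph <- g; fragment }
}

# Atoms on the j side once bond (i, j) is removed; errors if (i, j) is cyclic.
j_side_atoms <- function(mol, i, j) {
  b <- mol$bonds
  keep <- !(pmin(b$i, b$j) == min(i, j) & pmax(b$i, b$j) == max(i, j))
  g <- edge_graph(n_atoms(mol), b$i[keep], b$j[keep])
  comp <- igraph::components(g)$membership
  if (comp[i] == comp[j]) {
    abort_input("axis bond lies in a ring; cannot rotate")
  }
  which(comp == comp[j])
}

# Rodrigues rotation matrix about unit axis u by angle theta (radians).
rotation_matrix <- function(u, theta) {
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}
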