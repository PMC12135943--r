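#' Energy backends
#'
#' A backend supplies the potential energy of a fragment geometry and a
#' restrained local optimizer. Backends are deliberately pluggable: the scan
#' engine only relies on the contract that `evaluate()` is deterministic for
#' identical geometry and that `optimize()` never returns a higher restrained
#' energy than its input.
#'
#' Built-in backends:
#' \describe{
#'   \item{`backend_cosine(multiplicity, barrier, sign)`}{analytic cosine
#'     potential `V(theta) = (B/2) (1 + sign * cos(m * theta))` in kcal/mol,
#'     a function of the target dihedral only. `backend_id`s `"cosine2"`
#'     (`(B/2)(1 - cos 2 theta)`, maxima at 90/270 deg) and `"cosine3"`
#'     (`(B/2)(1 + cos 3 theta)`, three-fold) follow this template. Used for
#'     engine validation against closed forms.}
#'   \item{`backend_steric()`}{a light steric molecular-mechanics surrogate:
#'     harmonic bond terms referenced to the embedded geometry plus a purely
#'     repulsive `r^-12` non-bonded term between atom pairs three or more
#'     bonds apart. Qualitative by design -- it reproduces the shape features
#'     of clash-driven torsion profiles (e.g. ortho-substituted biphenyls),
#'     not literature energetics.}
#'   \item{`backend_qm_stub()`}{interface stub reserved for an external
#'     quantum-chemistry engine; `evaluate()` raises a configuration error.}
#' }
#'
#' @param id backend identifier string.
#' @param evaluate function `(fragment) -> energy` (kcal/mol).
#' @param dihedral_only logical; `TRUE` when the energy depends on the target
#'   dihedral alone, enabling the fast 1-D restrained optimizer.
#' @param optimize optional custom optimizer; defaults to the generic
#'   restrained minimiser.
#' @return an object of class `energy_backend`.
#' @export
energy_backend <- function(id, evaluate, dihedral_only = FALSE,
                           optimize = NULL) {
  structure(list(id = id, evaluate = evaluate,
                 dihedral_only = isTRUE(dihedral_only),
                 optimize = optimize, units = "kcal/mol"),
            class = "energy_backend")
}

#' @export
print.energy_backend <- function(x, ...) {
  cat(sprintf("<energy_backend> %s (%s)%s\n", x$id, x$units,
              if (x$dihedral_only) ", dihedral-only" else ""))
  invisible(x)
}

#' @rdname energy_backend
#' @param multiplicity integer periodicity of the cosine potential.
#' @param barrier barrier height B in kcal/mol.
#' @param sign +1 or -1 (sign of the cosine term).
#' @export
backend_cosine <- function(multiplicity = 3, barrier = 3, sign = +1) {
  force(multiplicity); force(barrier); force(sign)
  energy_backend(
    id = paste0("cosine", multiplicity),
    evaluate = function(fragment) {
      th <- measure_dihedral(fragment$graph$coords,
                             fragment$target_torsion) * pi / 180
      (barrier / 2) * (1 + sign * cos(multiplicity * th))
    },
    dihedral_only = TRUE
  )
}

#' @rdname energy_backend
#' @export
backend_steric <- function() {
  # reference (spring rest) distances are frozen at the first geometry seen
  # for a fragment, i.e. its embedded conformer
  cache <- new.env(parent = emptyenv())
  b <- energy_backend(
    id = "steric",
    evaluate = function(fragment) steric_energy(fragment, cache),
    dihedral_only = FALSE
  )
  b$gradient <- function(fragment) steric_gradient(fragment, cache)
  b
}

#' @rdname energy_backend
#' @export
backend_qm_stub <- function() {
  energy_backend(
    id = "stub-qm",
    evaluate = function(fragment) {
      stop(errorCondition(
        paste0("'stub-qm' is an interface stub: attach an external ",
               "quantum-chemistry engine to use it"),
        class = c("atroposcan_config_error", "atroposcan_error")))
    },
    dihedral_only = FALSE
  )
}

#' Resolve a backend from its identifier
#'
#' Accepts `"cosine2"`, `"cosine3"`, `"steric"`, `"stub-qm"` or an
#' `energy_backend` object (returned unchanged).
#'
#' @param id backend id or object.
#' @param barrier barrier height forwarded to cosine backends.
#' @return an `energy_backend`.
#' @export
get_backend <- function(id, barrier = 3) {
  if (inherits(id, "energy_backend")) return(id)
  switch(id,
    cosine2 = backend_cosine(2, barrier, sign = -1),
    cosine3 = backend_cosine(3, barrier, sign = +1),
    steric = backend_steric(),
    `stub-qm` = backend_qm_stub(),
    stop(errorCondition(paste0("unknown backend id '", id, "'"),
         class = c("atroposcan_config_error", "atroposcan_error")))
  )
}

# approximate van der Waals radii (Angstrom) for the repulsive term
.VDW <- c(H = 1.1, C = 1.7, N = 1.55, O = 1.52, F = 1.47, S = 1.8,
          Cl = 1.75, Br = 1.85, I = 1.98, P = 1.8, B = 1.92, Si = 2.1)

steric_energy <- function(fragment, cache = NULL) {
  g <- fragment$graph
  xyz <- g$coords
  info <- steric_terms(fragment, cache)
  d <- xyz[info$bond_i, , drop = FALSE] - xyz[info$bond_j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  e_bond <- sum(info$k_spring * (r - info$r0)^2)
  e_rep <- 0
  if (nrow(info$pairs)) {
    d <- xyz[info$pairs$i, , drop = FALSE] - xyz[info$pairs$j, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    e_rep <- sum(0.1 * (info$pairs$sig / r)^12)
  }
  e_bond + e_rep
}

# analytic Cartesian gradient of the steric energy (kcal/mol/Angstrom)
steric_gradient <- function(fragment, cache = NULL) {
  xyz <- fragment$graph$coords
  n <- nrow(xyz)
  info <- steric_terms(fragment, cache)
  grad <- matrix(0, n, 3)
  accumulate <- function(grad, i, j, coef, d) {
    contrib <- d * coef
    add <- rowsum(rbind(contrib, -contrib), group = c(i, j))
    idx <- as.integer(rownames(add))
    grad[idx, ] <- grad[idx, ] + add
    grad
  }
  d <- xyz[info$bond_i, , drop = FALSE] - xyz[info$bond_j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  grad <- accumulate(grad, info$bond_i, info$bond_j,
                     2 * info$k_spring * (r - info$r0) / r, d)
  if (nrow(info$pairs)) {
    d <- xyz[info$pairs$i, , drop = FALSE] - xyz[info$pairs$j, , drop = FALSE]
    r2 <- rowSums(d^2)
    grad <- accumulate(grad, info$pairs$i, info$pairs$j,
                       -1.2 * info$pairs$sig^12 / r2^7, d)
  }
  grad
}

# Per-fragment term lists. Local geometry is held by harmonic springs on the
# 1-2 (bond) and 1-3 (angle-equivalent) distances referenced to the embedded
# geometry; pairs three or more bonds apart interact through the repulsive
# term only, which leaves torsions as the soft degrees of freedom.
steric_terms <- function(fragment, cache = NULL) {
  g <- fragment$graph
  key <- paste0(g$name, ":", n_atoms(g), ":", nrow(g$bonds))
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  gg <- as_igraph(g)
  sep <- igraph::distances(gg)
  xyz <- g$coords
  p13 <- which(upper.tri(sep) & sep == 2, arr.ind = TRUE)
  si <- c(g$bonds$i, p13[, 1])
  sj <- c(g$bonds$j, p13[, 2])
  d <- xyz[si, , drop = FALSE] - xyz[sj, , drop = FALSE]
  pairs <- which(upper.tri(sep) & sep >= 3, arr.ind = TRUE)
  rv <- .VDW[g$atoms$element]
  info <- list(
    bond_i = si, bond_j = sj,
    k_spring = c(rep(300, nrow(g$bonds)), rep(100, nrow(p13))),
    r0 = sqrt(rowSums(d^2)),
    pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                       # contact distance = sum of vdW radii, slightly
                       # softened so equilibrium structures sit near zero
                       sig = 0.9 * (rv[pairs[, 1]] + rv[pairs[, 2]]))
  )
  if (!is.null(cache)) cache[[key]] <- info
  info
}

#' Restrained optimization of a fragment geometry
#'
#' Minimises `E(x) + k_dihedral * (theta(x) - theta0)^2` where the harmonic
#' dihedral restraint constant is quoted in kJ/mol (per rad^2) as in the scan
#' settings and converted internally to kcal/mol. For dihedral-only backends
#' the problem reduces exactly to a 1-D minimisation over the target dihedral;
#' otherwise all Cartesian coordinates are relaxed with BFGS. The result never
#' has a higher restrained energy than the input (the input geometry is
#' returned if the optimizer fails to improve it).
#'
#' @param backend an `energy_backend`.
#' @param fragment embedded `mol_fragment`.
#' @param theta0_deg restraint target angle (degrees).
#' @param k_kjmol restraint force constant, kJ/mol units as configured.
#' @param maxit iteration budget for the Cartesian optimizer.
#' @return list with `fragment` (optimized) and `energy` (unrestrained
#'   backend energy, kcal/mol).
#' @export
optimize_restrained <- function(backend, fragment, theta0_deg, k_kjmol,
                                maxit = 80L) {
  if (!is.null(backend$optimize)) {
    return(backend$optimize(fragment, theta0_deg, k_kjmol))
  }
  k_kcal <- kj_to_kcal(k_kjmol)
  quad <- fragment$target_torsion
  penalty <- function(frag) {
    dth <- wrap_angle(measure_dihedral(frag$graph$coords, quad) -
                        theta0_deg) * pi / 180
    k_kcal * dth^2
  }
  obj_in <- backend$evaluate(fragment) + penalty(fragment)

  if (backend$dihedral_only) {
    f <- function(th) {
      fr <- set_dihedral(fragment, th)
      backend$evaluate(fr) + k_kcal * (wrap_angle(th - theta0_deg) * pi / 180)^2
    }
    # with k ~ 1e4+ kcal/mol/rad^2 the restrained optimum sits within a
    # fraction of a degree of theta0; a bracketed 1-D search suffices
    opt <- stats::optimize(f, interval = theta0_deg + c(-3, 3), tol = 1e-10)
    if (opt$objective <= obj_in + 1e-12) {
      out <- set_dihedral(fragment, opt$minimum)
      return(list(fragment = out, energy = backend$evaluate(out)))
    }
    return(list(fragment = fragment, energy = backend$evaluate(fragment)))
  }

  x0 <- as.vector(fragment$graph$coords)
  n <- nrow(fragment$graph$coords)
  fn <- function(x) {
    fr <- fragment
    fr$graph$coords <- matrix(x, ncol = 3)
    backend$evaluate(fr) + penalty(fr)
  }
  gr <- NULL
  if (!is.null(backend$gradient)) {
    # analytic backend gradient; the restraint only involves the four torsion
    # atoms, so its gradient is finite-differenced on those 12 coordinates
    gr <- function(x) {
      fr <- fragment
      fr$graph$coords <- matrix(x, ncol = 3)
      g <- backend$gradient(fr)
      h <- 1e-6
      for (at in quad) {
        for (ax in 1:3) {
          fr$graph$coords[at, ax] <- fr$graph$coords[at, ax] + h
          up <- penalty(fr)
          fr$graph$coords[at, ax] <- fr$graph$coords[at, ax] - 2 * h
          dn <- penalty(fr)
          fr$graph$coords[at, ax] <- fr$graph$coords[at, ax] + h
          g[at, ax] <- g[at, ax] + (up - dn) / (2 * h)
        }
      }
      as.vector(g)
    }
  }
  res <- tryCatch(
    stats::optim(x0, fn, gr = gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(res) && res$value <= obj_in + 1e-12) {
    fragment$graph$coords <- matrix(res$par, ncol = 3)
  }
  list(fragment = fragment, energy = backend$evaluate(fragment))
}
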