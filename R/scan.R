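#' Scan settings
#'
#' Bundles the torsion-scan configuration: a uniform angular grid
#' (`step_deg * n_points` must equal 360; defaults 10 degrees x 36 points),
#' the two restraint force constants of the staged optimization (a cheap
#' pre-optimization with `k = 1e5` kJ/mol and a refined optimization with
#' `k = 1e6` kJ/mol, interpreted as harmonic dihedral restraints per rad^2),
#' the backend id and a seed.
#'
#' @param step_deg angular increment in degrees.
#' @param n_points number of grid points.
#' @param restraint_k_stage1,restraint_k_stage2 force constants (kJ/mol).
#' @param backend_id backend identifier (see [get_backend()]).
#' @param seed integer seed (forwarded to embedding).
#' @param continue_from_previous start each grid point from the previous
#'   point's optimized geometry (torsion-drive style) rather than from the
#'   seed conformer.
#' @return object of class `scan_settings`.
#' @export
scan_settings <- function(step_deg = 10, n_points = 360 / step_deg,
                          restraint_k_stage1 = 1e5,
                          restraint_k_stage2 = 1e6,
                          backend_id = "cosine3", seed = 1L,
                          continue_from_previous = TRUE) {
  if (abs(step_deg * n_points - 360) > 1e-9) {
    abort_input("step_deg * n_points must equal 360 (got ",
                step_deg, " x ", n_points, ")")
  }
  if (restraint_k_stage1 <= 0 || restraint_k_stage2 <= 0) {
    abort_input("restraint force constants must be positive")
  }
  structure(list(step_deg = step_deg, n_points = as.integer(n_points),
                 restraint_k_stage1 = restraint_k_stage1,
                 restraint_k_stage2 = restraint_k_stage2,
                 backend_id = backend_id, seed = as.integer(seed),
                 continue_from_previous = isTRUE(continue_from_previous)),
            class = "scan_settings")
}

#' Relative energies of a profile
#'
#' Subtracts the minimum finite energy from every point, so the profile
#' minimum is exactly zero and pairwise differences are preserved.
#'
#' @param energies numeric vector with at least one finite entry.
#' @return numeric vector of relative energies (`min == 0`).
#' @export
relative_energies <- function(energies) {
  fin <- is.finite(energies)
  if (!any(fin)) {
    stop(errorCondition("no finite energies in profile",
         class = c("atroposcan_data_error", "atroposcan_error")))
  }
  energies - min(energies[fin])
}

#' Drive a restrained torsion scan
#'
#' Rotates the fragment's target torsion over the angular grid. At each grid
#' point the dihedral is set rigidly, then relaxed in two stages of restrained
#' optimization (stage 1 with `restraint_k_stage1`, stage 2 with
#' `restraint_k_stage2`), and the backend energy of the refined geometry is
#' recorded. A point fails when the optimized dihedral drifts more than 0.5
#' degrees from its target or the backend errors; up to two failed points are
#' interpolated linearly on the periodic grid, more mark the whole scan as
#' failed.
#'
#' @param fragment embedded `mol_fragment`.
#' @param settings a [scan_settings()] object.
#' @param backend an `energy_backend` (defaults to the settings' backend id).
#' @return object of class `torsion_profile`: angles (degrees, `[0, 360)`),
#'   raw energies, relative energies (kcal/mol, minimum exactly 0), backend
#'   id, settings, failed point indices, and `failed` flag.
#' @export
scan_torsion <- function(fragment, settings = scan_settings(),
                         backend = get_backend(settings$backend_id)) {
  if (!inherits(fragment, "mol_fragment")) {
    abort_input("'fragment' must be a mol_fragment")
  }
  if (is.null(fragment$graph$coords)) {
    abort_input("fragment not embedded; call embed_3d() first")
  }
  angles <- settings$step_deg * (seq_len(settings$n_points) - 1)
  energies <- rep(NA_real_, settings$n_points)
  failed <- integer(0)
  current <- fragment
  for (p in seq_along(angles)) {
    start <- if (settings$continue_from_previous) current else fragment
    res <- tryCatch({
      fr <- set_dihedral(start, angles[p])
      s1 <- optimize_restrained(backend, fr, angles[p],
                                settings$restraint_k_stage1)
      s2 <- optimize_restrained(backend, s1$fragment, angles[p],
                                settings$restraint_k_stage2)
      got <- measure_dihedral(s2$fragment$graph$coords,
                              s2$fragment$target_torsion)
      if (abs(wrap_angle(got - angles[p])) > 0.5) {
        abort_input(sprintf("dihedral drifted to %.2f (target %.1f)",
                            got, angles[p]))
      }
      # snap the residual sub-degree restraint offset back onto the grid
      # (frozen-dihedral limit of the stage-2 restraint), then record the
      # backend energy of the grid geometry
      fr2 <- set_dihedral(s2$fragment, angles[p])
      list(fragment = fr2, energy = backend$evaluate(fr2))
    }, atroposcan_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, p)
      msg_log("scan point ", angles[p], " deg failed for '",
              fragment$graph$name, "': ", conditionMessage(res),
              level = "WARN")
    } else {
      energies[p] <- res$energy
      current <- res$fragment
    }
  }
  scan_failed <- length(failed) > 2L
  if (!scan_failed && length(failed)) {
    energies <- interpolate_periodic(energies)
  }
  rel <- if (scan_failed) rep(NA_real_, length(energies)) else
    relative_energies(energies)
  structure(list(bond = attr(fragment, "bond") %||% fragment$bond_label,
                 bond_label = fragment$bond_label,
                 angles_deg = angles,
                 energies = energies,
                 relative_energies = rel,
                 backend_id = backend$id,
                 settings = settings,
                 failed_points = failed,
                 failed = scan_failed),
            class = "torsion_profile")
}

#' @export
print.torsion_profile <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("<torsion_profile> %s [%s]: FAILED (%d bad points)\n",
                x$bond_label %||% "?", x$backend_id, length(x$failed_points)))
  } else {
    cat(sprintf(
      "<torsion_profile> %s [%s]: %d points, max rel energy %.2f kcal/mol\n",
      x$bond_label %||% "?", x$backend_id, length(x$angles_deg),
      max(x$relative_energies)))
  }
  invisible(x)
}

# Linear interpolation over NA entries of a periodic vector.
interpolate_periodic <- function(e) {
  n <- length(e)
  e0 <- e
  for (p in which(is.na(e0))) {
    lo <- p; hi <- p
    while (is.na(e0[(lo - 2) %% n + 1])) lo <- lo - 1
    while (is.na(e0[hi %% n + 1])) hi <- hi + 1
    prev <- (lo - 2) %% n + 1
    nxt <- hi %% n + 1
    gap <- (hi + 1) - (lo - 1)
    w <- (p - (lo - 1)) / gap
    e[p] <- (1 - w) * e0[prev] + w * e0[nxt]
  }
  e
}

#' Construct a torsion profile directly from values
#'
#' Utility for analysis and testing: wraps a vector of energies on a uniform
#' periodic grid as a `torsion_profile` without running a scan.
#'
#' @param relative numeric energies (kcal/mol); re-referenced so the minimum
#'   is exactly zero.
#' @param bond_label label.
#' @param backend_id provenance tag.
#' @return a `torsion_profile`.
#' @export
as_torsion_profile <- function(relative, bond_label = "profile",
                               backend_id = "direct") {
  n <- length(relative)
  if (n < 4L) abort_input("a profile needs at least 4 grid points")
  structure(list(bond = bond_label, bond_label = bond_label,
                 angles_deg = 360 / n * (seq_len(n) - 1),
                 energies = relative,
                 relative_energies = relative_energies(relative),
                 backend_id = backend_id,
                 settings = scan_settings(step_deg = 360 / n, n_points = n,
                                          backend_id = backend_id),
                 failed_points = integer(0), failed = FALSE),
            class = "torsion_profile")
}

#' Export torsion profiles
#'
#' `profiles_to_json()` writes the canonical machine-readable output (per
#' molecule, per bond: angles, relative energies in kcal/mol, backend id and
#' settings); `profiles_to_csv()` writes the long-format mirror with columns
#' `molecule, bond_label, angle_deg, rel_energy_kcal_mol`.
#'
#' @param profiles named list of `torsion_profile`s (names = bond labels).
#' @param molecule molecule name.
#' @param path output file.
#' @return the path, invisibly.
#' @export
profiles_to_json <- function(profiles, molecule, path) {
  payload <- list()
  payload[[molecule]] <- lapply(profiles, function(p) {
    list(angles_deg = p$angles_deg,
         relative_energies_kcal_mol = p$relative_energies,
         backend_id = p$backend_id,
         failed = p$failed,
         settings = unclass(p$settings))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname profiles_to_json
#' @export
profiles_to_csv <- function(profiles, molecule, path) {
  rows <- do.call(rbind, lapply(names(profiles), function(lab) {
    p <- profiles[[lab]]
    data.frame(molecule = molecule, bond_label = lab,
               angle_deg = p$angles_deg,
               rel_energy_kcal_mol = p$relative_energies)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
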