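embedded_butane <- function() {
  bu <- fixture_mol("butane")
  embed_3d(fragment_around_bond(bu, detect_rotatable_bonds(bu)[1, ],
                                shells = 2), seed = 1)
}

test_that("set_dihedral reaches its target and is a rigid motion", {
  fr <- embedded_butane()
  for (tgt in c(180, 60, -60, 0, 123.4, -171.2)) {
    fr2 <- set_dihedral(fr, tgt)
    expect_equal(measure_dihedral(fr2$graph$coords, fr2$target_torsion),
                 atroposcan:::wrap_angle(tgt), tolerance = 1e-6)
    # bond lengths unchanged
    expect_equal(atroposcan:::bond_lengths(fr2$graph),
                 atroposcan:::bond_lengths(fr$graph), tolerance = 1e-9)
  }
  # setting the current angle is the identity
  th <- measure_dihedral(fr$graph$coords, fr$target_torsion)
  expect_equal(set_dihedral(fr, th)$graph$coords, fr$graph$coords,
               tolerance = 1e-9)
})

test_that("only the far side of the axis moves", {
  fr <- embedded_butane()
  quad <- fr$target_torsion
  i <- quad[2]; j <- quad[3]
  static <- atroposcan:::j_side_atoms(fr$graph, j, i)  # the i side
  fr2 <- set_dihedral(fr, measure_dihedral(fr$graph$coords, quad) + 40)
  expect_equal(fr2$graph$coords[static, ], fr$graph$coords[static, ],
               tolerance = 1e-12)
  moved <- setdiff(seq_len(nrow(fr$graph$coords)), c(static, i, j))
  expect_gt(max(abs(fr2$graph$coords[moved, ] - fr$graph$coords[moved, ])), 0.1)
})

test_that("composed rotations match the explicit rotation-matrix oracle", {
  fr <- embedded_butane()
  quad <- fr$target_torsion
  th0 <- measure_dihedral(fr$graph$coords, quad)
  # compose set(th1) then set(th2) and compare with set(th2) directly
  a <- set_dihedral(set_dihedral(fr, 35), -120)
  b <- set_dihedral(fr, -120)
  expect_equal(a$graph$coords, b$graph$coords, tolerance = 1e-6)
  # oracle: rotating the j side by delta about the bond axis changes the
  # dihedral by exactly delta (sign fixed by the package convention)
  i <- quad[2]; j <- quad[3]
  moving <- atroposcan:::j_side_atoms(fr$graph, i, j)
  u <- fr$graph$coords[j, ] - fr$graph$coords[i, ]
  u <- u / sqrt(sum(u^2))
  for (delta in c(25, -70) * pi / 180) {
    pts <- fr$graph$coords
    pts[moving, ] <- oracle_rotate(pts[moving, , drop = FALSE],
                                   fr$graph$coords[i, ], u, delta)
    got <- measure_dihedral(pts, quad)
    expect_equal(abs(atroposcan:::wrap_angle(got - th0)),
                 abs(delta) * 180 / pi, tolerance = 1e-6)
  }
})

test_that("relative energies subtract the minimum and preserve differences", {
  expect_equal(relative_energies(c(5, 7, 5)), c(0, 2, 0))
  expect_equal(relative_energies(-3.2), 0)
  set.seed(1)
  e <- rnorm(36, 10, 4)
  r <- relative_energies(e)
  expect_equal(min(r), 0)
  expect_equal(diff(r), diff(e))
  expect_error(relative_energies(c(NaN, NA)),
               class = "atroposcan_data_error")
})

test_that("scans on analytic cosine backends equal the closed form everywhere", {
  fr <- embedded_butane()
  grids <- list(
    list(backend = get_backend("cosine2", barrier = 20),
         closed = function(th) 10 * (1 - cos(2 * th))),
    list(backend = get_backend("cosine3", barrier = 3),
         closed = function(th) 1.5 * (1 + cos(3 * th)))
  )
  for (g in grids) {
    prof <- scan_torsion(fr, scan_settings(backend_id = g$backend$id),
                         backend = g$backend)
    expect_false(prof$failed)
    expect_equal(length(prof$angles_deg), 36L)
    expect_equal(diff(prof$angles_deg), rep(10, 35))
    th <- prof$angles_deg * pi / 180
    closed <- g$closed(th)
    expect_equal(prof$relative_energies, closed - min(closed),
                 tolerance = 1e-6)
    expect_equal(min(prof$relative_energies), 0)
  }
  # two-fold: maxima ~20 at 90/270, minima 0 at 0/180
  prof <- scan_torsion(fr, scan_settings(backend_id = "cosine2"),
                       backend = get_backend("cosine2", barrier = 20))
  expect_equal(prof$relative_energies[prof$angles_deg %in% c(90, 270)],
               c(20, 20), tolerance = 1e-6)
  expect_equal(prof$relative_energies[prof$angles_deg %in% c(0, 180)],
               c(0, 0), tolerance = 1e-9)
})

test_that("a zero-barrier backend yields a flat profile", {
  fr <- embedded_butane()
  prof <- scan_torsion(fr, scan_settings(backend_id = "cosine2"),
                       backend = get_backend("cosine2", barrier = 0))
  expect_equal(prof$relative_energies, rep(0, 36))
})

test_that("profiles are invariant to the starting conformer's dihedral", {
  fr <- embedded_butane()
  bk <- get_backend("cosine3", barrier = 5)
  p1 <- scan_torsion(set_dihedral(fr, 17), scan_settings(), bk)
  p2 <- scan_torsion(set_dihedral(fr, -111), scan_settings(), bk)
  expect_equal(p1$relative_energies, p2$relative_energies, tolerance = 1e-6)
})

test_that("restrained optimization never increases the restrained energy", {
  fr <- embedded_butane()
  set.seed(5)
  for (bk in list(get_backend("cosine3", barrier = 8), get_backend("steric"))) {
    for (th in c(0, 45, 150)) {
      f0 <- set_dihedral(fr, th)
      e0 <- bk$evaluate(f0)
      res <- optimize_restrained(bk, f0, th, 1e5)
      got <- measure_dihedral(res$fragment$graph$coords,
                              res$fragment$target_torsion)
      expect_lte(res$energy, e0 + 1e-9)
      expect_lt(abs(atroposcan:::wrap_angle(got - th)), 0.5)
    }
  }
})

test_that("energy unit conversions round-trip exactly", {
  x <- c(1e-3, 1, 41.84, 1e5)
  expect_equal(kcal_to_kj(kj_to_kcal(x)), x, tolerance = 1e-12)
  expect_equal(kj_to_kcal(4.184), 1)
})

test_that("failed points are interpolated up to two, then the scan fails", {
  fr <- embedded_butane()
  flaky <- function(bad_angles) {
    calls <- new.env(); calls$n <- 0
    energy_backend("flaky", function(fragment) {
      th <- round(measure_dihedral(fragment$graph$coords,
                                   fragment$target_torsion)) %% 360
      if (th %in% bad_angles) stop("backend blew up")
      1.5 * (1 + cos(3 * th * pi / 180))
    }, dihedral_only = TRUE)
  }
  p <- scan_torsion(fr, scan_settings(backend_id = "flaky"), flaky(c(40, 200)))
  expect_false(p$failed)
  expect_setequal(p$failed_points, c(5L, 21L))
  expect_true(all(is.finite(p$relative_energies)))
  # interpolation is linear between the surviving neighbours
  closed <- function(th) 1.5 * (1 + cos(3 * th * pi / 180))
  expect_equal(p$energies[5], (closed(30) + closed(50)) / 2, tolerance = 1e-6)

  p2 <- scan_torsion(fr, scan_settings(backend_id = "flaky"),
                     flaky(c(40, 200, 300)))
  expect_true(p2$failed)
})

test_that("the QM backend stub reports itself as unimplemented plumbing", {
  fr <- embedded_butane()
  expect_error(backend_qm_stub()$evaluate(fr),
               class = "atroposcan_config_error")
  p <- scan_torsion(fr, scan_settings(backend_id = "stub-qm"),
                    backend_qm_stub())
  expect_true(p$failed)
})
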