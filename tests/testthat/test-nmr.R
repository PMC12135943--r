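test_that("delta-nu converts shift separations to Hz", {
  expect_equal(as.numeric(delta_nu_from_shifts(4.46, 4.76, 400.13)),
               120.039, tolerance = 1e-9)
  expect_equal(as.numeric(delta_nu_from_shifts(4.53, 4.69, 400.13)),
               0.16 * 400.13, tolerance = 1e-9)
  z <- delta_nu_from_shifts(5.0, 5.0, 400.13)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "coalesced"))
  expect_error(delta_nu_from_shifts(1, 2, -1),
               class = "atroposcan_input_error")
})

test_that("the modified Eyring equation reproduces the six printed barriers", {
  for (r in seq_len(nrow(PAPER_BARRIERS))) {
    dnu <- delta_nu_from_shifts(PAPER_BARRIERS$shift_a[r],
                                PAPER_BARRIERS$shift_b[r], PAPER_FREQ_MHZ)
    dg <- eyring_barrier(PAPER_BARRIERS$T_K[r], dnu)
    expect_equal(round(dg, 1), PAPER_BARRIERS$dG_printed[r],
                 info = sprintf("%s @ %g K", PAPER_BARRIERS$pair[r],
                                PAPER_BARRIERS$T_K[r]))
  }
})

test_that("the log term vanishes when T equals delta-nu numerically", {
  cst <- physical_constants()
  expect_equal(eyring_barrier(300, 300, units = "J"),
               cst$eyring_const * cst$R * 300, tolerance = 1e-12)
  expect_equal(eyring_barrier(300, 300),
               cst$eyring_const * cst$R * 300 / 4184, tolerance = 1e-12)
})

test_that("kcal and J outputs are consistent and inputs validated", {
  expect_equal(eyring_barrier(393, 120, units = "J"),
               eyring_barrier(393, 120) * 4184, tolerance = 1e-9)
  expect_error(eyring_barrier(-1, 120), class = "atroposcan_input_error")
  expect_error(eyring_barrier(393, 0), class = "atroposcan_input_error")
})

test_that("the barrier is monotone in T and delta-nu over a 50x50 grid", {
  Ts <- seq(250, 500, length.out = 50)
  dnus <- seq(5, 500, length.out = 50)
  G <- outer(Ts, dnus, eyring_barrier)
  # increasing in T for every fixed delta-nu
  expect_true(all(apply(G, 2, diff) > 0))
  # decreasing in delta-nu for every fixed T
  expect_true(all(apply(G, 1, diff) < 0))
})

test_that("classification is stable under +-1 Hz away from class boundaries", {
  set.seed(9)
  Ts <- runif(200, 300, 470)
  dnus <- runif(200, 20, 300)
  for (k in seq_along(Ts)) {
    dg0 <- eyring_barrier(Ts[k], dnus[k])
    near_boundary <- min(abs(dg0 - c(10, 20, 30))) < 0.05
    if (near_boundary) next
    cls <- classify_barrier(c(dg0,
                              eyring_barrier(Ts[k], dnus[k] + 1),
                              eyring_barrier(Ts[k], max(dnus[k] - 1, 1))))
    expect_equal(length(unique(cls)), 1L)
  }
})

test_that("coalescence temperature is recovered from a linear separation trend", {
  # separation = 500 - 1.24 T  ->  root at T = 403.2258...
  Tg <- seq(303, 393, by = 10)
  sep <- 500 - 1.24 * Tg
  s <- vt_series(data.frame(temperature_K = Tg,
                            shift_a_ppm = 4.6 - sep / (2 * 400.13),
                            shift_b_ppm = 4.6 + sep / (2 * 400.13)),
                 400.13, "line")
  est <- estimate_coalescence_temperature(s)
  expect_equal(est$T_coal, 500 / 1.24, tolerance = 1e-6)
  expect_equal(est$method, "extrapolated")
  expect_lt(est$se, 1e-6)
})

test_that("an in-range coalescence returns the bracketing temperature", {
  Tg <- c(303, 313, 323, 333)
  sep <- c(30, 15, 0, 0)
  s <- vt_series(data.frame(temperature_K = Tg,
                            shift_a_ppm = 4.6 - sep / (2 * 400.13),
                            shift_b_ppm = 4.6 + sep / (2 * 400.13)),
                 400.13, "obs")
  est <- estimate_coalescence_temperature(s)
  expect_equal(est$T_coal, 323)
  expect_equal(est$method, "observed")
  expect_equal(est$se, 0)
})

test_that("a flat separation trend warns and reports unbounded uncertainty", {
  Tg <- seq(303, 343, by = 10)
  s <- vt_series(data.frame(temperature_K = Tg,
                            shift_a_ppm = 4.5, shift_b_ppm = 4.8),
                 400.13, "const")
  expect_warning(est <- estimate_coalescence_temperature(s),
                 "does not decrease")
  expect_true(is.infinite(est$se))
})

test_that("racemization half-life behaves like an Eyring rate", {
  cst <- physical_constants()
  # direct evaluation oracle at the Class 1 boundary barrier
  dg <- 20; T <- 310.15
  k <- (cst$k_B * T / cst$h) * exp(-dg * 4184 / (cst$R * T))
  expect_equal(racemization_halflife(20, 310.15), log(2) / k,
               tolerance = 1e-12)
  # the 20 kcal/mol boundary barrier sits within a factor ~10 of the 60 s
  # half-life boundary of Class 1
  expect_gt(racemization_halflife(20, 310.15), 6)
  expect_lt(racemization_halflife(20, 310.15), 600)
  # monotone in dG, linear in the statistical factor
  expect_gt(racemization_halflife(40, 310.15),
            racemization_halflife(20, 310.15))
  expect_equal(racemization_halflife(20, 310.15, statistical_factor = 2),
               racemization_halflife(20, 310.15) / 2, tolerance = 1e-12)
})

test_that("barrier reports reproduce the tool-compound analyses", {
  # ACBI1: coalescence not reached; candidate temperatures bracket the barrier
  rep1 <- barrier_report(fixture_vt_pair("acbi1_pair1"),
                         T_coal = 453.15,
                         candidates_K = c(393.15, 423.15, 453.15))
  expect_equal(round(rep1$dG_kcal, 1), 22.4)
  expect_equal(rep1$assigned_class, "2")
  expect_true(rep1$estimated)
  expect_equal(round(rep1$candidates$dG_kcal, 1), c(19.4, 20.9, 22.4))
  rep2 <- barrier_report(fixture_vt_pair("acbi1_pair1"), T_coal = 423.15)
  expect_equal(round(rep2$dG_kcal, 1), 20.9)
  # BI201335 pair 1: coalescence observed at 393.15 K -> Class 1
  rep3 <- barrier_report(fixture_vt_pair("bi201335_pair1"), T_coal = 393.15)
  expect_equal(round(rep3$dG_kcal, 1), 18.9)
  expect_equal(rep3$assigned_class, "1")
  # BI201335 pair 2 at the estimated 403.15 K coalescence
  rep4 <- barrier_report(fixture_vt_pair("bi201335_pair2"), T_coal = 403.15)
  expect_equal(round(rep4$dG_kcal, 1), 19.3)
  expect_equal(rep4$assigned_class, "1")
})

test_that("stored barrier estimates are self-consistent to 1e-9", {
  rep1 <- barrier_report(fixture_vt_pair("acbi1_pair1"), T_coal = 453.15)
  expect_equal(rep1$dG_kcal, eyring_barrier(rep1$T_coal, rep1$delta_nu_Hz),
               tolerance = 1e-9)
})

test_that("a fully coalesced series yields an upper-bound-only report", {
  s <- vt_series(data.frame(temperature_K = c(303, 313, 323),
                            shift_a_ppm = 4.6, shift_b_ppm = 4.6),
                 400.13, "merged")
  rep <- barrier_report(s)
  expect_true(rep$upper_bound_only)
  expect_true(is.na(rep$dG_kcal))
})

test_that("VT-NMR CSV reading validates its rows", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(temperature_K = c(303, 313),
                       shift_a_ppm = c(4.5, 4.55),
                       shift_b_ppm = c(4.8, 4.7)), tf, row.names = FALSE)
  s <- read_vt_csv(tf, 400.13)
  expect_s3_class(s, "vt_nmr_series")
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("temperature_K,shift_a_ppm,shift_b_ppm",
               "303,4.5,4.8", "313,oops,4.7"), tf2)
  err <- tryCatch(read_vt_csv(tf2, 400.13), error = function(e) e)
  expect_s3_class(err, "atroposcan_data_error")
  expect_match(conditionMessage(err), "row 2")
})
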