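grid36 <- function(f) f(2 * pi * (0:35) / 36)

test_that("symmetric threefold profile has three equal minima and barriers", {
  v <- grid36(function(th) 1.5 * (1 + cos(3 * th)))
  f <- extract_features(as_torsion_profile(v))
  expect_equal(f$n_clear_minima, 3L)
  expect_equal(nrow(f$maxima), 3L)
  expect_equal(f$delta_delta_V_min, 0)
  expect_equal(f$max_V_max, 3)
  expect_equal(f$min_V_max, 3)
  expect_false(f$of_interest)
})

test_that("constructed two-basin profile reports the defining features", {
  # periodic profile with minima at 0 and 1.5, maxima at 10 and 12,
  # built from piecewise cosine ramps
  v <- numeric(36)
  v[1:10] <- 0 + (10 - 0) * (1 - cos(pi * (0:9) / 9)) / 2       # rise 0 -> 10
  v[10:19] <- 10 - (10 - 1.5) * (1 - cos(pi * (0:9) / 9)) / 2   # fall -> 1.5
  v[19:28] <- 1.5 + (12 - 1.5) * (1 - cos(pi * (0:9) / 9)) / 2  # rise -> 12
  v[28:36] <- 12 - (12 - 0) * (1 - cos(pi * (0:8) / 8)) / 2     # fall -> ~0
  f <- extract_features(as_torsion_profile(v))
  expect_equal(f$n_clear_minima, 2L)
  expect_equal(f$delta_delta_V_min, 1.5)
  expect_equal(f$max_V_max, 12)
  expect_equal(f$min_V_max, 10)
  expect_false(f$of_interest)  # barrier 12 sits below the 13 kcal/mol screen
})

test_that("feature extraction matches the sublevel-persistence oracle", {
  set.seed(2024)
  for (rep in 1:100) {
    v <- random_profile()
    f <- extract_features(as_torsion_profile(v), prominence_kcal = 1)
    o <- oracle_features(v, prominence = 1)
    expect_equal(f$n_clear_minima, o$n_minima, info = paste("profile", rep))
    expect_equal(nrow(f$maxima), length(o$maxima))
    expect_equal(f$delta_delta_V_min, o$ddVmin, tolerance = 1e-12)
    expect_equal(f$max_V_max, o$maxVmax, tolerance = 1e-12)
    expect_equal(f$min_V_max, o$minVmax, tolerance = 1e-12)
    # alternation and ordering invariants
    expect_gte(f$max_V_max, f$min_V_max)
    expect_gte(f$min_V_max, 0)
    expect_gte(f$delta_delta_V_min, 0)
  }
})

test_that("features are invariant to cyclic rotation and constant shifts", {
  set.seed(7)
  v <- random_profile()
  f0 <- extract_features(as_torsion_profile(v))
  for (shift in c(5, 18, 31)) {
    vs <- c(v[-seq_len(shift)], v[seq_len(shift)])
    fs <- extract_features(as_torsion_profile(vs))
    expect_equal(fs$n_clear_minima, f0$n_clear_minima)
    expect_equal(fs$max_V_max, f0$max_V_max, tolerance = 1e-12)
    expect_equal(fs$min_V_max, f0$min_V_max, tolerance = 1e-12)
    expect_equal(fs$delta_delta_V_min, f0$delta_delta_V_min,
                 tolerance = 1e-12)
  }
  fc <- extract_features(as_torsion_profile(v + 11.3))
  expect_equal(fc$max_V_max, f0$max_V_max, tolerance = 1e-12)
})

test_that("flat profiles yield one minimum, no maxima, and no flag", {
  f <- extract_features(as_torsion_profile(rep(2.5, 36)))
  expect_equal(f$n_clear_minima, 1L)
  expect_equal(nrow(f$maxima), 0L)
  expect_equal(f$max_V_max, 0)
  expect_false(f$of_interest)
})

test_that("adjacent-minimum barrier reference bounds the global reference", {
  set.seed(11)
  for (rep in 1:20) {
    v <- random_profile()
    fg <- extract_features(as_torsion_profile(v), barrier_reference = "global")
    fa <- extract_features(as_torsion_profile(v),
                           barrier_reference = "adjacent")
    expect_lte(fa$max_V_max, fg$max_V_max + 1e-12)
    expect_lte(fa$min_V_max, fg$min_V_max + 1e-12)
  }
})

test_that("the of-interest screen needs both the barrier and the minima", {
  scheme <- classification_scheme()
  expect_true(flag_of_interest(list(max_V_max = 16.67, n_clear_minima = 2),
                               scheme))
  expect_false(flag_of_interest(list(max_V_max = 12, n_clear_minima = 3),
                                scheme))
  expect_false(flag_of_interest(list(max_V_max = 25, n_clear_minima = 1),
                                scheme))
  expect_false(flag_of_interest(list(max_V_max = 13, n_clear_minima = 2),
                                scheme))  # strictly greater than 13
})

test_that("LaPlante classification follows the half-open band convention", {
  expect_equal(classify_barrier(23.0), "2")
  expect_equal(classify_barrier(18.9), "1")
  expect_equal(classify_barrier(30.0), "3")
  expect_equal(classify_barrier(c(0, 9.99, 10, 19.99, 20, 29.99, 30, 50)),
               c("none", "none", "1", "1", "2", "2", "3", "3"))
  expect_error(classify_barrier(-1), class = "atroposcan_input_error")
  # monotone: higher barrier never yields a lower class
  set.seed(3)
  dg <- sort(runif(100, 0, 40))
  cls <- match(classify_barrier(dg), c("none", "1", "2", "3"))
  expect_false(is.unsorted(cls))
})

test_that("features_table mirrors the per-bond report layout", {
  v3 <- grid36(function(th) 1.5 * (1 + cos(3 * th)))
  v2 <- grid36(function(th) 8 * (1 - cos(2 * th)))
  tab <- features_table(list(`m-1` = as_torsion_profile(v3),
                             `m-2` = as_torsion_profile(v2)), "m")
  expect_equal(names(tab),
               c("molecule", "bond_label", "delta_delta_V_min", "max_V_max",
                 "min_V_max", "n_minima", "of_interest", "class"))
  expect_equal(tab$n_minima, c(3L, 2L))
  expect_equal(tab$max_V_max, c(3, 16), tolerance = 1e-9)
  expect_equal(tab$of_interest, c(FALSE, TRUE))
})
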