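#' Physical constants
#'
#' CODATA-fixed constants used by the kinetics module, plus the dimensionless
#' coalescence constant 22.96 of the modified Eyring equation
#' `dG = R * T_coal * (22.96 + ln(T_coal / delta_nu))` (J/mol).
#'
#' @return named list: `R` (8.314462618 J/mol/K), `k_B` (1.380649e-23 J/K),
#'   `h` (6.62607015e-34 J s), `eyring_const` (22.96), `J_per_kcal` (4184).
#' @export
physical_constants <- function() {
  list(R = 8.314462618, k_B = 1.380649e-23, h = 6.62607015e-34,
       eyring_const = 22.96, J_per_kcal = 4184)
}

#' Variable-temperature NMR series
#'
#' One rotameric signal pair followed over temperature: rows of
#' `(temperature K, shift A ppm, shift B ppm)` plus the spectrometer proton
#' frequency in MHz. Temperatures must be strictly increasing, shifts finite.
#'
#' @param points data.frame with columns `temperature_K`, `shift_a_ppm`,
#'   `shift_b_ppm`.
#' @param spectrometer_MHz proton resonance frequency (e.g. 400.13).
#' @param pair_label label for the signal pair.
#' @return object of class `vt_nmr_series`.
#' @export
vt_series <- function(points, spectrometer_MHz, pair_label = "pair") {
  points <- as.data.frame(points)
  need <- c("temperature_K", "shift_a_ppm", "shift_b_ppm")
  if (!all(need %in% names(points))) {
    abort_input("series needs columns ", paste(need, collapse = ", "))
  }
  if (!is.numeric(spectrometer_MHz) || spectrometer_MHz <= 0) {
    abort_input("'spectrometer_MHz' must be positive")
  }
  if (nrow(points) < 1L) abort_input("series has no rows")
  if (is.unsorted(points$temperature_K, strictly = TRUE)) {
    abort_input("temperatures must be strictly increasing")
  }
  if (!all(is.finite(as.matrix(points[need])))) {
    abort_input("non-finite values in series")
  }
  structure(list(points = points[need],
                 spectrometer_MHz = spectrometer_MHz,
                 pair_label = pair_label),
            class = "vt_nmr_series")
}

#' @export
print.vt_nmr_series <- function(x, ...) {
  cat(sprintf("<vt_nmr_series> %s: %d temperatures (%g-%g K) @ %.2f MHz\n",
              x$pair_label, nrow(x$points), min(x$points$temperature_K),
              max(x$points$temperature_K), x$spectrometer_MHz))
  invisible(x)
}

#' Read a VT-NMR series from CSV
#'
#' Expects a header `temperature_K, shift_a_ppm, shift_b_ppm`.
#'
#' @param path CSV file path.
#' @param spectrometer_MHz proton frequency in MHz.
#' @param pair_label label (defaults to the file name).
#' @return a [vt_series()].
#' @export
read_vt_csv <- function(path, spectrometer_MHz,
                        pair_label = sub("\\.csv$", "", basename(path))) {
  if (!file.exists(path)) abort_input("VT-NMR file not found: ", path)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) abort_input("malformed CSV '", path,
                                                 "': ", conditionMessage(e)))
  need <- c("temperature_K", "shift_a_ppm", "shift_b_ppm")
  if (!all(need %in% names(df))) {
    abort_input("'", path, "' must have header ", paste(need, collapse = ", "))
  }
  df[need] <- lapply(df[need], function(x)
    suppressWarnings(as.numeric(as.character(x))))
  bad <- which(!apply(sapply(df[need], is.finite), 1, all))
  if (length(bad)) {
    stop(errorCondition(
      paste0("non-numeric or missing value in '", path, "', data row ",
             bad[1]),
      class = c("atroposcan_data_error", "atroposcan_error")))
  }
  vt_series(df, spectrometer_MHz, pair_label)
}

#' Larmor frequency difference from chemical shifts
#'
#' `delta_nu = |shift_A - shift_B| * spectrometer_MHz` -- a ppm difference
#' times a frequency in MHz is directly a frequency difference in Hz.
#' A zero difference means the signals have coalesced; the result carries a
#' `coalesced` attribute in that case (a barrier cannot be computed from it).
#'
#' @param shift_a_ppm,shift_b_ppm chemical shifts (ppm).
#' @param spectrometer_MHz proton frequency (MHz), > 0.
#' @return delta-nu in Hz (vectorised), with attribute `coalesced`.
#' @examples
#' delta_nu_from_shifts(4.46, 4.76, 400.13)   # 120.039 Hz
#' @export
delta_nu_from_shifts <- function(shift_a_ppm, shift_b_ppm, spectrometer_MHz) {
  if (!is.numeric(spectrometer_MHz) || any(spectrometer_MHz <= 0)) {
    abort_input("'spectrometer_MHz' must be positive")
  }
  dnu <- abs(shift_a_ppm - shift_b_ppm) * spectrometer_MHz
  attr(dnu, "coalesced") <- dnu == 0
  dnu
}

#' Rotational barrier from coalescence (modified Eyring equation)
#'
#' `dG = R * T_coal * (22.96 + ln(T_coal / delta_nu))` in J/mol, converted to
#' kcal/mol (divide by 4184). Summaries print barriers rounded to 0.1
#' kcal/mol; full precision is retained in the returned value.
#'
#' @param T_coal coalescence temperature in K, > 0.
#' @param delta_nu_Hz Larmor frequency difference in Hz, > 0.
#' @param units `"kcal"` (default) or `"J"` (per mol).
#' @return barrier(s) as numeric, in the requested unit. Vectorised over both
#'   arguments.
#' @examples
#' eyring_barrier(393.15, delta_nu_from_shifts(4.46, 4.76, 400.13))  # ~18.9
#' @export
eyring_barrier <- function(T_coal, delta_nu_Hz, units = c("kcal", "J")) {
  units <- match.arg(units)
  if (any(!is.finite(T_coal)) || any(T_coal <= 0)) {
    abort_input("'T_coal' must be positive and finite")
  }
  if (any(!is.finite(delta_nu_Hz)) || any(delta_nu_Hz <= 0)) {
    abort_input("'delta_nu_Hz' must be positive and finite ",
                "(coalesced signals carry no barrier information)")
  }
  cst <- physical_constants()
  T_coal <- as.vector(T_coal)
  delta_nu_Hz <- as.vector(delta_nu_Hz)
  J <- cst$R * T_coal * (cst$eyring_const + log(T_coal / delta_nu_Hz))
  if (units == "J") J else J / cst$J_per_kcal
}

#' Estimate the coalescence temperature by extrapolation
#'
#' Fits the observed peak separation (Hz) against temperature with a linear
#' trend and extrapolates to zero separation. If the separation already
#' reaches (numerical) zero within the measured range, the first such
#' bracketing temperature is returned with zero uncertainty. A non-decreasing
#' trend triggers a warning and an unbounded-uncertainty estimate.
#'
#' @param series a [vt_series()] with at least 3 resolved temperature points.
#' @return list with `T_coal` (K), `se` (standard error of the extrapolated
#'   root, delta method), `method` (`"observed"` or `"extrapolated"`), and
#'   the underlying `fit` (or `NULL`).
#' @export
estimate_coalescence_temperature <- function(series) {
  stopifnot(inherits(series, "vt_nmr_series"))
  p <- series$points
  sep <- as.numeric(delta_nu_from_shifts(p$shift_a_ppm, p$shift_b_ppm,
                                         series$spectrometer_MHz))
  hit <- which(sep <= 1e-9)
  if (length(hit)) {
    return(list(T_coal = p$temperature_K[hit[1]], se = 0,
                method = "observed", fit = NULL))
  }
  if (nrow(p) < 3L) {
    abort_input("need >= 3 resolved temperature points to extrapolate")
  }
  fit <- stats::lm(sep ~ p$temperature_K)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] >= 0) {
    warning("peak separation does not decrease with temperature; ",
            "coalescence temperature is unbounded", call. = FALSE)
    return(list(T_coal = NA_real_, se = Inf, method = "extrapolated",
                fit = fit))
  }
  Tc <- unname(-b[1] / b[2])
  V <- stats::vcov(fit)
  # delta method for the root -b0/b1
  g <- c(-1 / b[2], b[1] / b[2]^2)
  se <- sqrt(drop(t(g) %*% V %*% g))
  list(T_coal = Tc, se = unname(se), method = "extrapolated", fit = fit)
}

#' Racemization half-life from a barrier
#'
#' Standard Eyring rate `k = (k_B T / h) exp(-dG / (R T))`, half-life
#' `t1/2 = ln(2) / (statistical_factor * k)`. The statistical factor defaults
#' to 1 (set 2 to count racemization as two-directional enantiomerization).
#'
#' @param dG_kcal barrier in kcal/mol, > 0.
#' @param T_K temperature in K (default 310.15, i.e. 37 C).
#' @param statistical_factor 1 or 2.
#' @return half-life in seconds (vectorised).
#' @export
racemization_halflife <- function(dG_kcal, T_K = 310.15,
                                  statistical_factor = 1) {
  if (any(dG_kcal <= 0) || any(T_K <= 0)) {
    abort_input("'dG_kcal' and 'T_K' must be positive")
  }
  cst <- physical_constants()
  k <- (cst$k_B * T_K / cst$h) *
    exp(-dG_kcal * cst$J_per_kcal / (cst$R * T_K))
  log(2) / (statistical_factor * k)
}

#' Full barrier report for a signal pair
#'
#' Combines the slow-exchange shift separation (taken at the lowest measured
#' temperature unless `delta_nu_Hz` is supplied), a coalescence temperature
#' (observed in-range, extrapolated, or user-supplied via `T_coal`), the
#' modified Eyring barrier, the racemization half-life at 37 C and the
#' LaPlante class into one estimate. When the coalescence temperature lies
#' above the measured range the barrier is labelled *estimated* and, if
#' `candidates_K` are given, the report tabulates the barrier at each
#' candidate coalescence temperature (mirroring how a barrier is bracketed
#' when the spectrometer cannot reach coalescence).
#'
#' @param series a [vt_series()].
#' @param T_coal optional user-supplied coalescence temperature (K).
#' @param candidates_K optional vector of candidate coalescence temperatures.
#' @param delta_nu_Hz optional direct Larmor separation (Hz).
#' @param statistical_factor forwarded to [racemization_halflife()].
#' @param scheme a [classification_scheme()].
#' @return object of class `barrier_estimate`: `dG_kcal`, `T_coal`,
#'   `delta_nu_Hz`, `halflife_s`, `assigned_class`, `estimated` (logical),
#'   `upper_bound_only` (logical), `candidates` (data.frame of
#'   `T_coal_K, dG_kcal, halflife_s, class`) and `pair_label`.
#' @export
barrier_report <- function(series, T_coal = NULL, candidates_K = NULL,
                           delta_nu_Hz = NULL, statistical_factor = 1,
                           scheme = classification_scheme()) {
  stopifnot(inherits(series, "vt_nmr_series"))
  p <- series$points
  sep <- as.numeric(delta_nu_from_shifts(p$shift_a_ppm, p$shift_b_ppm,
                                         series$spectrometer_MHz))
  dnu <- delta_nu_Hz %||% sep[1]
  if (dnu <= 0) {
    # coalesced already at the lowest temperature: only an upper bound exists
    out <- structure(list(dG_kcal = NA_real_, T_coal = NA_real_,
                          delta_nu_Hz = 0, halflife_s = NA_real_,
                          assigned_class = NA_character_, estimated = TRUE,
                          upper_bound_only = TRUE,
                          candidates = empty_candidates(),
                          pair_label = series$pair_label),
                     class = "barrier_estimate")
    return(out)
  }
  estimated <- FALSE
  if (is.null(T_coal)) {
    est <- tryCatch(estimate_coalescence_temperature(series),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(est) && is.finite(est$T_coal %||% NA_real_)) {
      T_coal <- est$T_coal
      estimated <- est$method != "observed" ||
        T_coal > max(p$temperature_K)
    }
  } else {
    estimated <- T_coal > max(p$temperature_K)
  }
  cand <- if (!is.null(candidates_K) && length(candidates_K)) {
    dg <- eyring_barrier(candidates_K, dnu)
    data.frame(T_coal_K = candidates_K, dG_kcal = dg,
               halflife_s = racemization_halflife(dg, scheme$reference_T,
                                                  statistical_factor),
               class = classify_barrier(dg, scheme))
  } else empty_candidates()
  if (is.null(T_coal) || !is.finite(T_coal)) {
    dG <- NA_real_; hl <- NA_real_; cls <- NA_character_
    estimated <- TRUE
  } else {
    dG <- eyring_barrier(T_coal, dnu)
    hl <- racemization_halflife(dG, scheme$reference_T, statistical_factor)
    cls <- classify_barrier(dG, scheme)
  }
  structure(list(dG_kcal = dG, T_coal = T_coal, delta_nu_Hz = dnu,
                 halflife_s = hl, assigned_class = cls,
                 estimated = estimated, upper_bound_only = FALSE,
                 candidates = cand, pair_label = series$pair_label),
            class = "barrier_estimate")
}

empty_candidates <- function() {
  data.frame(T_coal_K = numeric(0), dG_kcal = numeric(0),
             halflife_s = numeric(0), class = character(0))
}

#' @export
print.barrier_estimate <- function(x, ...) {
  if (x$upper_bound_only) {
    cat(sprintf(paste0("<barrier_estimate> %s: signals coalesced at all ",
                       "temperatures; only an upper bound on the barrier ",
                       "exists\n"), x$pair_label))
  } else if (is.finite(x$dG_kcal %||% NA_real_)) {
    cat(sprintf(
      "<barrier_estimate> %s: dG = %.1f kcal/mol%s (T_coal %.1f K, dnu %.2f Hz), t1/2(37C) = %.3g s, Class %s\n",
      x$pair_label, round(x$dG_kcal, 1),
      if (x$estimated) " [estimated]" else "",
      x$T_coal, x$delta_nu_Hz, x$halflife_s, x$assigned_class))
  } else {
    cat(sprintf("<barrier_estimate> %s: coalescence not reached; see candidate table\n",
                x$pair_label))
  }
  if (nrow(x$candidates)) {
    cat("  candidate coalescence temperatures:\n")
    for (r in seq_len(nrow(x$candidates))) {
      cat(sprintf("    T = %.1f K -> dG = %.1f kcal/mol (Class %s)\n",
                  x$candidates$T_coal_K[r], round(x$candidates$dG_kcal[r], 1),
                  x$candidates$class[r]))
    }
  }
  invisible(x)
}
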