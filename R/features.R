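#' Atropisomer classification scheme
#'
#' The LaPlante scheme ranks hindered single-bond rotations by their
#' racemization half-life at 37 C (310.15 K): Class 1 (`t1/2 < 60 s`,
#' `dG < 20 kcal/mol`, treated as achiral), Class 2 (`60 s < t1/2 < 4.5
#' years`, `20-30 kcal/mol`, the "lurking menace" of minutes-to-months
#' interconversion), Class 3 (`t1/2 > 4.5 years`, `> 30 kcal/mol`, isolable
#' atropisomers). Barriers below 10 kcal/mol are free rotations and receive no
#' class. Torsion profiles are flagged as *of interest* when their maximal
#' barrier exceeds 13 kcal/mol and they show at least 2 clear minima.
#'
#' @param class1_max_dG,class2_max_dG class boundaries in kcal/mol.
#' @param class_floor_dG barrier below which no class is assigned (kcal/mol).
#' @param class1_max_halflife,class2_max_halflife half-life boundaries in
#'   seconds (60 s; 4.5 years).
#' @param reference_T reference temperature in K (37 C).
#' @param interest_barrier_threshold screening barrier threshold (kcal/mol).
#' @param interest_min_minima minimum number of clear minima for the screen.
#' @return object of class `classification_scheme`.
#' @export
classification_scheme <- function(class1_max_dG = 20, class2_max_dG = 30,
                                  class_floor_dG = 10,
                                  class1_max_halflife = 60,
                                  class2_max_halflife = 4.5 * 365.25 * 86400,
                                  reference_T = 310.15,
                                  interest_barrier_threshold = 13,
                                  interest_min_minima = 2L) {
  if (!(class_floor_dG < class1_max_dG && class1_max_dG < class2_max_dG)) {
    abort_input("class thresholds must be strictly increasing")
  }
  structure(list(class1_max_dG = class1_max_dG, class2_max_dG = class2_max_dG,
                 class_floor_dG = class_floor_dG,
                 class1_max_halflife = class1_max_halflife,
                 class2_max_halflife = class2_max_halflife,
                 reference_T = reference_T,
                 interest_barrier_threshold = interest_barrier_threshold,
                 interest_min_minima = as.integer(interest_min_minima)),
            class = "classification_scheme")
}

#' Extract profile features
#'
#' Locates the local minima and maxima of a periodic torsion profile and
#' derives the summary features used to screen torsions of interest: the
#' spread of the minima energies `delta_delta_V_min` (largest minus smallest
#' minimum), the maximal barrier height `max_V_max` and the minimal barrier
#' height `min_V_max`.
#'
#' "Clear" extrema are enforced with a prominence filter: the pair of adjacent
#' extrema (one minimum, one maximum) with the smallest energy contrast is
#' merged into its neighbours whenever that contrast is below
#' `prominence_kcal`, repeatedly, until all surviving basins are separated by
#' at least the prominence. This is the persistence-cancellation rule on a
#' circular profile. A flat profile reports one minimum, no maxima and zero
#' features.
#'
#' Barrier heights are measured, by default, as the maximum's relative energy
#' above the *global* minimum of the profile (`barrier_reference = "global"`,
#' consistent with profiles being re-referenced to their minimum); set
#' `barrier_reference = "adjacent"` to measure each barrier above the higher
#' of its two flanking minima (the smaller escape barrier over that saddle).
#'
#' @param profile a `torsion_profile`.
#' @param prominence_kcal prominence threshold in kcal/mol (default 1).
#' @param barrier_reference `"global"` (default) or `"adjacent"`.
#' @param scheme a [classification_scheme()] for the of-interest flag.
#' @return object of class `profile_features`: data.frames `minima` and
#'   `maxima` (columns `angle_deg`, `energy`), scalars `delta_delta_V_min`,
#'   `max_V_max`, `min_V_max`, `n_clear_minima`, and logical `of_interest`.
#' @export
extract_features <- function(profile, prominence_kcal = 1,
                             barrier_reference = c("global", "adjacent"),
                             scheme = classification_scheme()) {
  barrier_reference <- match.arg(barrier_reference)
  if (prominence_kcal < 0) abort_input("'prominence_kcal' must be >= 0")
  if (isTRUE(profile$failed)) abort_input("cannot analyse a failed scan")
  v <- profile$relative_energies
  ang <- profile$angles_deg
  ext <- periodic_extrema(v)
  ext <- prune_extrema(v, ext, prominence_kcal)

  if (!length(ext$max)) {
    # flat (or single-basin-after-pruning degenerate) profile
    minima <- data.frame(angle_deg = ang[which.min(v)], energy = min(v))
    feats <- list(minima = minima,
                  maxima = data.frame(angle_deg = numeric(0),
                                      energy = numeric(0)),
                  delta_delta_V_min = 0, max_V_max = 0, min_V_max = 0,
                  n_clear_minima = 1L, of_interest = FALSE)
    return(structure(c(feats, list(prominence_kcal = prominence_kcal,
                                   barrier_reference = barrier_reference)),
                     class = "profile_features"))
  }

  minima <- data.frame(angle_deg = ang[ext$min], energy = v[ext$min])
  maxima <- data.frame(angle_deg = ang[ext$max], energy = v[ext$max])
  barriers <- if (barrier_reference == "global") {
    maxima$energy          # profile is referenced to its global minimum
  } else {
    vapply(ext$max, function(mx) {
      fl <- flanking_minima(ext, mx, length(v))
      v[mx] - max(v[fl])
    }, numeric(1))
  }
  feats <- list(
    minima = minima, maxima = maxima,
    delta_delta_V_min = max(minima$energy) - min(minima$energy),
    max_V_max = max(barriers),
    min_V_max = min(barriers),
    n_clear_minima = nrow(minima))
  feats$of_interest <- flag_of_interest(feats, scheme)
  structure(c(feats, list(prominence_kcal = prominence_kcal,
                          barrier_reference = barrier_reference)),
            class = "profile_features")
}

#' @export
print.profile_features <- function(x, ...) {
  cat(sprintf(paste0("<profile_features> %d clear minima | ddV_min %.2f | ",
                     "max(V_max) %.2f | min(V_max) %.2f kcal/mol | %s\n"),
              x$n_clear_minima, x$delta_delta_V_min, x$max_V_max, x$min_V_max,
              if (x$of_interest) "OF INTEREST" else "not flagged"))
  invisible(x)
}

# Local extrema of a periodic sequence, plateau-safe: collapse runs of equal
# neighbours, then detect sign changes of the circular differences. Returns
# index vectors (representative = first index of a plateau run).
periodic_extrema <- function(v) {
  n <- length(v)
  runs <- integer(0)   # first index of each run of equal consecutive values
  k <- 1L
  while (k <= n) {
    runs <- c(runs, k)
    while (k < n && v[k + 1] == v[k]) k <- k + 1L
    k <- k + 1L
  }
  # merge a wrap-around run (last == first)
  if (length(runs) > 1L && v[runs[length(runs)]] == v[1L]) {
    runs <- runs[-length(runs)]
  }
  m <- length(runs)
  if (m < 2L) return(list(min = integer(0), max = integer(0)))
  mins <- integer(0); maxs <- integer(0)
  for (r in seq_len(m)) {
    prev <- v[runs[(r - 2) %% m + 1]]
    nxt <- v[runs[r %% m + 1]]
    cur <- v[runs[r]]
    if (cur < prev && cur < nxt) mins <- c(mins, runs[r])
    if (cur > prev && cur > nxt) maxs <- c(maxs, runs[r])
  }
  list(min = mins, max = maxs)
}

# Persistence cancellation: repeatedly remove the adjacent (min, max) pair of
# smallest contrast while that contrast is below the prominence threshold.
prune_extrema <- function(v, ext, prominence) {
  repeat {
    if (!length(ext$max)) break
    idx <- sort(c(ext$min, ext$max))
    m <- length(idx)
    contrasts <- vapply(seq_len(m), function(r) {
      abs(v[idx[r]] - v[idx[r %% m + 1]])
    }, numeric(1))
    r <- which.min(contrasts)
    if (contrasts[r] >= prominence) break
    if (length(ext$min) <= 1L) {
      # single shallow basin: drop the sub-prominence maximum, keep the
      # global minimum (profile is effectively featureless)
      ext$max <- integer(0)
      break
    }
    drop_pair <- c(idx[r], idx[r %% m + 1])
    ext$min <- setdiff(ext$min, drop_pair)
    ext$max <- setdiff(ext$max, drop_pair)
  }
  if (!length(ext$max)) ext$min <- integer(0)
  ext
}

flanking_minima <- function(ext, mx, n) {
  idx <- sort(c(ext$min, ext$max))
  pos <- match(mx, idx)
  m <- length(idx)
  c(idx[(pos - 2) %% m + 1], idx[pos %% m + 1])
}

#' Screening rule for torsions of interest
#'
#' A torsion is flagged when its maximal barrier height exceeds the screening
#' threshold (13 kcal/mol) *and* the profile shows at least the required
#' number of clear minima (2).
#'
#' @param features a `profile_features` object (or list with `max_V_max`,
#'   `n_clear_minima`).
#' @param scheme a [classification_scheme()].
#' @return logical.
#' @export
flag_of_interest <- function(features, scheme = classification_scheme()) {
  isTRUE(features$max_V_max > scheme$interest_barrier_threshold &&
           features$n_clear_minima >= scheme$interest_min_minima)
}

#' LaPlante class from a rotational barrier
#'
#' Assigns the atropisomer class for a barrier `dG` (kcal/mol): `"none"`
#' below 10, Class 1 in `[10, 20)`, Class 2 in `[20, 30)`, Class 3 at and
#' above 30 (half-open intervals, lower bound inclusive). Vectorised.
#'
#' @param dG_kcal numeric barrier(s), kcal/mol, finite and non-negative.
#' @param scheme a [classification_scheme()].
#' @return character vector in `c("none", "1", "2", "3")`.
#' @export
classify_barrier <- function(dG_kcal, scheme = classification_scheme()) {
  if (any(!is.finite(dG_kcal)) || any(dG_kcal < 0)) {
    abort_input("barriers must be finite and non-negative")
  }
  ifelse(dG_kcal < scheme$class_floor_dG, "none",
         ifelse(dG_kcal < scheme$class1_max_dG, "1",
                ifelse(dG_kcal < scheme$class2_max_dG, "2", "3")))
}

#' Tabulate profile features per bond
#'
#' Builds the per-molecule report table (one row per scanned bond) with the
#' screening features, flag and class columns, and optionally writes CSV/JSON.
#'
#' @param profiles named list of `torsion_profile`s.
#' @param molecule molecule name.
#' @param prominence_kcal forwarded to [extract_features()].
#' @param scheme a [classification_scheme()].
#' @param csv,json optional output paths.
#' @return data.frame with columns `molecule`, `bond_label`,
#'   `delta_delta_V_min`, `max_V_max`, `min_V_max`, `n_minima`,
#'   `of_interest`, `class`.
#' @export
features_table <- function(profiles, molecule, prominence_kcal = 1,
                           scheme = classification_scheme(),
                           csv = NULL, json = NULL) {
  rows <- lapply(names(profiles), function(lab) {
    p <- profiles[[lab]]
    if (isTRUE(p$failed)) {
      return(data.frame(molecule = molecule, bond_label = lab,
                        delta_delta_V_min = NA_real_, max_V_max = NA_real_,
                        min_V_max = NA_real_, n_minima = NA_integer_,
                        of_interest = NA, class = NA_character_))
    }
    f <- extract_features(p, prominence_kcal, scheme = scheme)
    data.frame(molecule = molecule, bond_label = lab,
               delta_delta_V_min = f$delta_delta_V_min,
               max_V_max = f$max_V_max, min_V_max = f$min_V_max,
               n_minima = f$n_clear_minima, of_interest = f$of_interest,
               class = classify_barrier(max(f$max_V_max, 0), scheme))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(tab, json, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)
  tab
}
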