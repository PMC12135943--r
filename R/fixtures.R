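#' Embedded fixtures
#'
#' Download-free test inputs shipped with the package: curated structures of
#' the two beyond-rule-of-5 tool compounds, a set of toy molecules for engine
#' validation, and the variable-temperature NMR signal pairs of the tool
#' compounds with their experimental settings.
#'
#' The tool-compound structures are transcribed from their published 2D
#' structure drawings:
#' \describe{
#'   \item{`acbi1`}{ACBI1, a VHL-recruiting SMARCA2/4 PROTAC degrader:
#'     phenol-pyridazine-piperazine bromodomain ligand, short bis-amide
#'     glycol-diether linker, and the VH032-class VHL ligand
#'     (tert-leucine / 4-hydroxyproline / (S)-1-(4-(4-methylthiazol-5-yl)-
#'     phenyl)ethylamine).}
#'   \item{`bi201335`}{BI201335 (faldaprevir), a linear tripeptide HCV NS3
#'     protease inhibitor: 8-bromo-7-methoxy-2-(2-acylamino-thiazol-4-yl)-
#'     quinolin-4-yl ether on 4-hydroxyproline, cyclopentyl-carbamate-capped
#'     tert-leucine, and a C-terminal 1-carboxy-2-vinylcyclopropyl amide.
#'     The transcription is verified by its empirical formula
#'     C40H49BrN6O9S.}
#' }
#' Toy molecules: `ethane`, `butane`, `biphenyl`, and the ortho-substituted
#' biphenyl series `biphenyl_2_methyl`, `biphenyl_2_2p_dimethyl`,
#' `biphenyl_2_6_2p_6p_tetramethyl` (increasing steric hindrance about the
#' inter-ring axis). `water` is included for geometry checks.
#'
#' @name fixtures
NULL

.FIXTURE_SMILES <- c(
  acbi1 = paste0(
    "Oc1ccc(-c2ccc(N3CCN(C(=O)COCCOCC(=O)N[C@H](C(C)(C)C)C(=O)N4C[C@H](O)",
    "C[C@H]4C(=O)N[C@@H](C)c4ccc(-c5scnc5C)cc4)CC3)nn2)cc1"),
  bi201335 = paste0(
    "CC(C)C(=O)Nc1nc(cs1)-c1cc(O[C@@H]2C[C@H](N(C2)C(=O)[C@@H](NC(=O)",
    "OC3CCCC3)C(C)(C)C)C(=O)N[C@]4(C[C@@H]4C=C)C(=O)O)c5ccc(OC)c(Br)c5n1"),
  ethane = "CC",
  butane = "CCCC",
  biphenyl = "c1ccccc1-c1ccccc1",
  biphenyl_2_methyl = "Cc1ccccc1-c1ccccc1",
  biphenyl_2_2p_dimethyl = "Cc1ccccc1-c1ccccc1C",
  biphenyl_2_6_2p_6p_tetramethyl = "Cc1cccc(C)c1-c1c(C)cccc1C",
  water = "O"
)

# Printed slow-exchange (303 K) chemical shifts of the rotameric signal
# pairs, with the proton frequency of the spectrometer (400.13 MHz) and the
# experimental VT range 303-393 K in 10 K steps. Temperatures were set in
# Celsius on the VT unit, so absolute temperatures carry the +0.15 K offset
# (30 C = 303.15 K, ..., 120 C = 393.15 K).
.FIXTURE_VT <- list(
  acbi1_pair1 = list(shift_a = 4.53, shift_b = 4.69,
                     candidates_K = c(393.15, 423.15, 453.15)),
  acbi1_pair2 = list(shift_a = 4.46, shift_b = 4.60,
                     candidates_K = c(393.15, 423.15, 453.15)),
  bi201335_pair1 = list(shift_a = 4.46, shift_b = 4.76,
                        T_coal = 393.15, candidates_K = numeric(0)),
  bi201335_pair2 = list(shift_a = 4.62, shift_b = 4.95,
                        candidates_K = c(393.15, 403.15))
)

.FIXTURE_FREQ_MHZ <- 400.13
.FIXTURE_T_LOW <- 303.15

#' @rdname fixtures
#' @return `fixture_names()`: list with the molecule and VT-NMR fixture names.
#' @export
fixture_names <- function() {
  list(molecules = names(.FIXTURE_SMILES), vt_pairs = names(.FIXTURE_VT))
}

#' @rdname fixtures
#' @param name fixture name.
#' @return `fixture_smiles()`: the curated SMILES string.
#' @export
fixture_smiles <- function(name) {
  if (!name %in% names(.FIXTURE_SMILES)) {
    abort_input("unknown molecule fixture '", name, "'; see fixture_names()")
  }
  unname(.FIXTURE_SMILES[name])
}

#' @rdname fixtures
#' @return `fixture_mol()`: the fixture as a `mol_graph`.
#' @export
fixture_mol <- function(name) {
  read_smiles(fixture_smiles(name), name = name)
}

#' @rdname fixtures
#' @return `fixture_vt_pair()`: a [vt_series()] holding the printed
#'   slow-exchange shifts of the named signal pair (single 303.15 K row) at
#'   400.13 MHz, with attributes `candidates_K` (candidate coalescence
#'   temperatures) and, where coalescence was observed in range, `T_coal`.
#' @export
fixture_vt_pair <- function(name) {
  if (!name %in% names(.FIXTURE_VT)) {
    abort_input("unknown VT-NMR fixture '", name, "'; see fixture_names()")
  }
  fx <- .FIXTURE_VT[[name]]
  s <- vt_series(data.frame(temperature_K = .FIXTURE_T_LOW,
                            shift_a_ppm = fx$shift_a,
                            shift_b_ppm = fx$shift_b),
                 spectrometer_MHz = .FIXTURE_FREQ_MHZ, pair_label = name)
  attr(s, "candidates_K") <- fx$candidates_K
  attr(s, "T_coal") <- fx$T_coal
  s
}

#' Generate a synthetic VT-NMR series
#'
#' Emulates the raw input of a coalescence analysis: a rotameric signal pair
#' whose separation (in Hz) decays linearly from `delta_nu_at_303K` at the
#' first temperature to zero at `T_coal_true`, optionally with Gaussian noise
#' on the separation, sampled on a 10 K grid. Shifts are placed symmetrically
#' about a 4.6 ppm centre. Linear decay is an idealisation -- real separations
#' curve near coalescence -- but it matches the linear-extrapolation
#' estimator's assumption, making exact parameter-recovery tests possible.
#'
#' @param T_coal_true true coalescence temperature (K).
#' @param delta_nu_at_303K separation at the series start (Hz), > 0.
#' @param n_points number of temperatures (>= 3).
#' @param noise_sd_Hz standard deviation of the separation noise (Hz), >= 0.
#' @param seed integer seed (RNG state of the caller is preserved).
#' @param T_start first temperature (K).
#' @param T_step temperature increment (K).
#' @param spectrometer_MHz proton frequency (MHz).
#' @return a [vt_series()].
#' @export
synth_vt_series <- function(T_coal_true, delta_nu_at_303K, n_points = 10L,
                            noise_sd_Hz = 0, seed = 1L,
                            T_start = 303.15, T_step = 10,
                            spectrometer_MHz = 400.13) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 3L) {
    abort_input("'n_points' must be >= 3 (two points cannot witness a trend)")
  }
  if (delta_nu_at_303K <= 0) abort_input("'delta_nu_at_303K' must be > 0")
  if (noise_sd_Hz < 0) abort_input("'noise_sd_Hz' must be >= 0")
  Tg <- T_start + T_step * (seq_len(n_points) - 1)
  sep <- delta_nu_at_303K * (T_coal_true - Tg) / (T_coal_true - T_start)
  if (noise_sd_Hz > 0) {
    sep <- sep + with_seed(seed, stats::rnorm(n_points, 0, noise_sd_Hz))
  }
  sep <- pmax(sep, 0)
  half <- sep / (2 * spectrometer_MHz)
  vt_series(data.frame(temperature_K = Tg,
                       shift_a_ppm = 4.6 - half,
                       shift_b_ppm = 4.6 + half),
            spectrometer_MHz = spectrometer_MHz,
            pair_label = sprintf("synthetic_Tc%.0f", T_coal_true))
}

#' Export fixtures to files
#'
#' Writes molecule fixtures as SDF and VT-NMR pairs as CSV into a directory.
#'
#' @param dir output directory (created if missing).
#' @return invisible vector of written paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(.FIXTURE_SMILES)) {
    p <- file.path(dir, paste0(nm, ".sdf"))
    write_sdf(fixture_mol(nm), p)
    paths <- c(paths, p)
  }
  for (nm in names(.FIXTURE_VT)) {
    s <- fixture_vt_pair(nm)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(s$points, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
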