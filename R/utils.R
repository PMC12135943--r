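# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(..., class = "atroposcan_input_error") {
  stop(errorCondition(paste0(...), class = c(class, "atroposcan_error")))
}

abort_logic <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("atroposcan_logic_error", "atroposcan_error")))
}

#' @keywords internal
msg_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("atroposcan.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

# Wrap an angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

KJ_PER_KCAL <- 4.184
J_PER_KCAL <- 4184

#' Convert energies between kJ/mol and kcal/mol
#'
#' The torsion engine stores energies in kcal/mol; restraint force constants
#' are quoted in kJ/mol. These helpers are exact inverses of each other
#' (thermochemical calorie, 1 kcal = 4.184 kJ).
#'
#' @param x numeric vector of energies.
#' @return numeric vector in the target unit.
#' @export
kj_to_kcal <- function(x) x / KJ_PER_KCAL

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * KJ_PER_KCAL

# Atomic numbers for the elements this package expects to meet.
.ATOMIC_NUMBER <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

atomic_number <- function(element) {
  z <- .ATOMIC_NUMBER[element]
  if (anyNA(z)) {
    abort_input("unknown element symbol(s): ",
                paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}
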