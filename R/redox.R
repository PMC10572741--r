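# Nernst pH adjustment of midpoint potentials and mediator feasibility
# against the indigo reduction threshold (~ -600 mV at alkaline pH).

#' Physical constants used by the Nernst adjustment
#'
#' Gas constant R = 8.315 J K^-1 mol^-1, Faraday constant F = 96486
#' J mol^-1 V^-1, default temperature 298 K (25 degrees C).
#'
#' @format A list with elements `R`, `F_const`, `T_default`.
#' @export
redox_constants <- list(R = 8.315, F_const = 96486, T_default = 298)

#' Construct a redox couple
#'
#' A half-reaction with a known midpoint potential at some reference pH, and
#' the proton (`m`) and electron (`n`) stoichiometry of its reduction, which
#' set the slope of the pH dependence.
#'
#' @param name Couple label.
#' @param e_ref_mV Midpoint potential at `pH_ref`, in mV vs SHE.
#' @param pH_ref Reference pH of `e_ref_mV`.
#' @param m Number of protons transferred (>= 0).
#' @param n Number of electrons transferred (>= 1).
#' @return A `redox_couple` list.
#' @export
redox_couple <- function(name, e_ref_mV, pH_ref, m, n) {
  if (!is.finite(e_ref_mV)) stop_input("redox_couple: e_ref_mV must be finite")
  if (n < 1) stop_invariant("redox_couple: n must be >= 1")
  if (m < 0) stop_invariant("redox_couple: m must be >= 0")
  structure(list(name = name, e_ref_mV = e_ref_mV, pH_ref = pH_ref,
                 m = m, n = n),
            class = "redox_couple")
}

#' Nernst slope in mV per pH unit
#'
#' Computes `2.303 * R * T / F * 1000`, the per-pH-unit shift of a midpoint
#' potential for a couple with one proton per electron (m/n = 1). At 298 K
#' this is approximately 59 mV.
#'
#' @param T_K Absolute temperature in kelvin.
#' @return Slope in mV per pH unit.
#' @export
#' @examples
#' nernst_slope_mV(298)  # ~59.1
nernst_slope_mV <- function(T_K = redox_constants$T_default) {
  if (any(T_K <= 0)) stop_input("nernst_slope_mV: temperature must be > 0 K")
  2.303 * redox_constants$R * T_K / redox_constants$F_const * 1000
}

#' Adjust a midpoint potential to a target pH
#'
#' Applies the Nernst pH correction
#' `E_pH2 = E_pH1 - 2.303 m R T / (n F) * (pH2 - pH1)`, in mV.
#'
#' @param couple A [redox_couple()].
#' @param pH_target Target pH.
#' @param T_K Absolute temperature in kelvin.
#' @return Adjusted midpoint potential in mV vs SHE (vectorized over
#'   `pH_target`).
#' @export
adjust_midpoint <- function(couple, pH_target,
                            T_K = redox_constants$T_default) {
  if (couple$n == 0) stop_invariant("adjust_midpoint: n must be >= 1")
  couple$e_ref_mV -
    nernst_slope_mV(T_K) * (couple$m / couple$n) * (pH_target - couple$pH_ref)
}

#' Classify an electron mediator as feasible for indigo reduction
#'
#' Indigo reduction requires a mediator potential at or below the reduction
#' threshold (default -600 mV vs SHE). The boundary counts as feasible;
#' set `inclusive = FALSE` for a strict comparison.
#'
#' @param e_adjusted_mV Adjusted midpoint potential(s), mV vs SHE.
#' @param e_required_mV Required potential threshold (default -600 mV).
#' @param inclusive Whether equality with the threshold counts as feasible.
#' @return Logical vector of feasibility flags.
#' @export
classify_mediator <- function(e_adjusted_mV, e_required_mV = -600,
                              inclusive = TRUE) {
  if (any(!is.finite(e_adjusted_mV)) || !is.finite(e_required_mV)) {
    stop_input("classify_mediator: potentials must be finite")
  }
  if (inclusive) e_adjusted_mV <= e_required_mV else e_adjusted_mV < e_required_mV
}

#' Read a table of redox couples
#'
#' Tab-delimited with columns `name`, `e_ref_mV`, `pH_ref`, `m`, `n`. A
#' template listing candidate mediators (NADH, FMN, riboflavin, acetaldehyde,
#' anthraquinone) ships in `inst/extdata/reference_couples.tsv` with the
#' potential fields left for the user to fill from their preferred
#' compilation.
#'
#' @param path Path to the couples file.
#' @return Data frame of couples.
#' @export
read_redox_couples <- function(path) {
  check_file(path, "couples")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "e_ref_mV", "pH_ref", "m", "n")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_format("couples '", path, "': missing required column '", miss[1], "'")
  }
  if (any(df$n < 1)) stop_format("couples '", path, "': n must be >= 1")
  df
}

#' Adjust and classify a table of mediator couples
#'
#' @param couples Data frame from [read_redox_couples()].
#' @param pH_target Target pH.
#' @param T_K Temperature in kelvin.
#' @param e_required_mV Feasibility threshold in mV.
#' @param inclusive Boundary convention for [classify_mediator()].
#' @return The input data frame with `e_adjusted_mV` and `feasible` columns.
#' @export
mediator_table <- function(couples, pH_target,
                           T_K = redox_constants$T_default,
                           e_required_mV = -600, inclusive = TRUE) {
  couples$e_adjusted_mV <- vapply(seq_len(nrow(couples)), function(i) {
    cp <- redox_couple(couples$name[i], couples$e_ref_mV[i],
                       couples$pH_ref[i], couples$m[i], couples$n[i])
    adjust_midpoint(cp, pH_target, T_K)
  }, numeric(1))
  couples$feasible <- classify_mediator(couples$e_adjusted_mV,
                                        e_required_mV, inclusive)
  couples
}
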