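# Chloride ions liberated per formula unit on full dissociation. Non-chloride
# components common in ACSF/pipette recipes are listed explicitly at 0 so a
# typo in a salt name still errors rather than silently contributing nothing.
CHLORIDE_STOICHIOMETRY <- c(
  NaCl = 1, KCl = 1, CsCl = 1, LiCl = 1, NH4Cl = 1, TEACl = 1, CholineCl = 1,
  MgCl2 = 2, CaCl2 = 2, BaCl2 = 2, CoCl2 = 2, ZnCl2 = 2,
  glucose = 0, sucrose = 0, NaHCO3 = 0, NaH2PO4 = 0, KH2PO4 = 0,
  MgSO4 = 0, EGTA = 0, HEPES = 0, ATP = 0, GTP = 0,
  CsMeSO4 = 0, Kgluconate = 0, phosphocreatine = 0
)

#' Construct a recording/pipette solution recipe
#'
#' @param name Solution name.
#' @param salts Named numeric vector or list mapping salt formula to
#'   concentration in mM; names must appear in the chloride stoichiometry
#'   dictionary (`NaCl`, `KCl`, `CsCl` contribute 1 Cl- per unit, `MgCl2`,
#'   `CaCl2` contribute 2, buffers/sugars/nucleotides contribute 0).
#' @param temperature_C Recording temperature in Celsius (default 29, the
#'   midpoint of a 28-30 degree recording bath).
#' @return A `solution_recipe` list.
#' @export
solution_recipe <- function(name, salts, temperature_C = 29) {
  salts <- unlist(salts)
  if (is.null(names(salts)) || any(names(salts) == "")) {
    stop("`salts` must be a named mapping of salt formula to mM")
  }
  if (any(salts < 0)) stop("salt concentrations must be non-negative")
  unknown <- setdiff(names(salts), names(CHLORIDE_STOICHIOMETRY))
  if (length(unknown)) {
    stop("unknown salt(s) with no chloride stoichiometry: ",
         paste(unknown, collapse = ", "))
  }
  assert_scalar_num(temperature_C, "temperature_C", 0, 50, strict_lower = TRUE)
  structure(list(name = as.character(name), salts = salts,
                 temperature_C = temperature_C),
            class = "solution_recipe")
}

#' Free chloride concentration of a solution
#'
#' Sums concentration times chloride stoichiometry over all fully
#' dissociating chloride salts; buffers, sugars and nucleotides contribute
#' zero. The standard recording ACSF (125 NaCl, 2.5 KCl, 1 MgCl2, 2 CaCl2
#' plus chloride-free components) yields 133.5 mM.
#'
#' @param recipe A [solution_recipe()].
#' @return Free chloride concentration in mM.
#' @export
free_chloride <- function(recipe) {
  stopifnot(inherits(recipe, "solution_recipe"))
  sum(recipe$salts * CHLORIDE_STOICHIOMETRY[names(recipe$salts)])
}

GAS_CONSTANT <- 8.31446    # J mol^-1 K^-1
FARADAY <- 96485.3         # C mol^-1

#' Nernst equilibrium potential for chloride
#'
#' For a monovalent anion (z = -1):
#' `E = (R T / F) * ln(Cl_in / Cl_out) * 1000` mV. Equal concentrations give
#' 0 mV; an inwardly directed gradient (Cl_in < Cl_out) gives a negative
#' reversal potential.
#'
#' @param cl_in_mM,cl_out_mM Intracellular and extracellular chloride (mM),
#'   both positive.
#' @param temperature_C Temperature in Celsius (default 29).
#' @return Equilibrium potential in mV.
#' @export
nernst_potential <- function(cl_in_mM, cl_out_mM, temperature_C = 29) {
  if (any(cl_in_mM <= 0) || any(cl_out_mM <= 0)) {
    stop("chloride concentrations must be positive")
  }
  assert_scalar_num(temperature_C, "temperature_C", 0, 50, strict_lower = TRUE)
  t_k <- temperature_C + 273.15
  (GAS_CONSTANT * t_k / FARADAY) * log(cl_in_mM / cl_out_mM) * 1000
}

#' Intracellular chloride from a GABA-A reversal potential
#'
#' Inverts the Nernst equation for chloride (z = -1):
#' `Cl_in = Cl_out * exp(E_rev_mV / 1000 * F / (R T))`. With the 133.5 mM
#' chloride of standard recording ACSF at 29 C, measured reversal potentials
#' of -25.0, -20.7 and -61.3 mV correspond to intracellular chloride of
#' about 51, 60 and 13 mM respectively.
#'
#' @param e_rev_mV Reversal potential in mV.
#' @param cl_out_mM Extracellular chloride (mM), positive.
#' @param temperature_C Temperature in Celsius (default 29).
#' @return Intracellular chloride concentration in mM.
#' @export
nernst_concentration <- function(e_rev_mV, cl_out_mM, temperature_C = 29) {
  if (any(cl_out_mM <= 0)) stop("cl_out_mM must be positive")
  assert_scalar_num(temperature_C, "temperature_C", 0, 50, strict_lower = TRUE)
  t_k <- temperature_C + 273.15
  cl_out_mM * exp(e_rev_mV / 1000 * FARADAY / (GAS_CONSTANT * t_k))
}
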