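#' Reversal potential from a current-voltage series
#'
#' Ordinary least-squares regression of response amplitude on holding
#' potential; the reversal potential (E_GABA, the membrane voltage at which
#' net current through the channel is zero) is the x-intercept `-b/m`.
#'
#' @param iv Data.frame with columns `holding_mV` and `amplitude_pA`, at
#'   least two distinct voltages.
#' @param slope_tol Minimum absolute slope (pA/mV) below which the reversal
#'   potential is undefined.
#' @return List with `e_rev_mV`, `slope_nS` (pA/mV = nS), `intercept_pA` and
#'   `r_squared`.
#' @export
reversal_from_iv <- function(iv, slope_tol = 1e-9) {
  if (!all(c("holding_mV", "amplitude_pA") %in% names(iv))) {
    stop("`iv` needs columns holding_mV and amplitude_pA")
  }
  if (length(unique(iv$holding_mV)) < 2) {
    stop("at least two distinct holding potentials are required")
  }
  fit <- stats::lm(amplitude_pA ~ holding_mV, data = iv)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || abs(m) < slope_tol) {
    stop("undefined reversal potential: I-V slope is (near) zero",
         call. = FALSE)
  }
  ss_tot <- sum((iv$amplitude_pA - mean(iv$amplitude_pA))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else NA_real_
  list(e_rev_mV = -b / m, slope_nS = m, intercept_pA = b, r_squared = r2)
}

#' Intracellular chloride from per-cell current-voltage series
#'
#' For each cell, regresses the I-V relation to get its reversal potential
#' and converts it to intracellular chloride with the Nernst equation, using
#' the free chloride of the bath solution as the extracellular concentration.
#' Reversal potentials and chloride values are computed per cell and then
#' averaged (mean and s.e.m.), not pooled into one regression.
#'
#' @param iv_list A single I-V data.frame or a list of them (one per cell).
#' @param recipe [solution_recipe()] of the extracellular (bath) solution.
#' @param temperature_C Temperature in Celsius; defaults to the recipe's.
#' @param e_rev_offset_mV Optional additive correction applied to each
#'   fitted reversal potential (e.g. a junction-potential correction);
#'   default 0.
#' @return List with `per_cell` (data.frame of `e_rev_mV`, `cl_in_mM`),
#'   `cl_out_mM`, `mean_cl_in_mM`, `sem_cl_in_mM`, `mean_e_rev_mV`,
#'   `sem_e_rev_mV`.
#' @export
estimate_chloride_per_cell <- function(iv_list, recipe,
                                       temperature_C = NULL,
                                       e_rev_offset_mV = 0) {
  stopifnot(inherits(recipe, "solution_recipe"))
  if (is.data.frame(iv_list)) iv_list <- list(iv_list)
  if (is.null(temperature_C)) temperature_C <- recipe$temperature_C
  cl_out <- free_chloride(recipe)
  e_rev <- vapply(iv_list, function(iv) reversal_from_iv(iv)$e_rev_mV,
                  numeric(1)) + e_rev_offset_mV
  cl_in <- nernst_concentration(e_rev, cl_out, temperature_C)
  per_cell <- data.frame(cell = seq_along(e_rev), e_rev_mV = e_rev,
                         cl_in_mM = cl_in)
  list(
    per_cell = per_cell,
    cl_out_mM = cl_out,
    mean_e_rev_mV = mean(e_rev),
    sem_e_rev_mV = if (length(e_rev) > 1) standard_error(e_rev) else NA_real_,
    mean_cl_in_mM = mean(cl_in),
    sem_cl_in_mM = if (length(cl_in) > 1) standard_error(cl_in) else NA_real_
  )
}

#' Responder fractions across xenograft models
#'
#' @param counts Data.frame with columns `model`, `responders`, `cells`.
#' @return List with `per_model` (the input plus a `fraction` column) and
#'   `pooled` (sum of responders over sum of cells).
#' @export
responder_fraction <- function(counts) {
  need <- c("model", "responders", "cells")
  if (!all(need %in% names(counts))) {
    stop("`counts` needs columns model, responders, cells")
  }
  if (any(counts$responders < 0) || any(counts$cells <= 0) ||
      any(counts$responders > counts$cells)) {
    stop("responders must satisfy 0 <= responders <= cells, cells > 0")
  }
  counts$fraction <- counts$responders / counts$cells
  list(per_model = counts,
       pooled = sum(counts$responders) / sum(counts$cells))
}
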