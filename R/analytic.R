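#' Closed-form AUC after a single oral dose
#'
#' Because the model is linear and time-invariant, total exposure has a closed
#' form. The fraction of the oral dose reaching the tegafur central
#' compartment is `ka / (ka + ka_met)`; the rest is first-pass converted to
#' the 5-FU precursor. All 5-FU ever formed is the first-pass fraction plus
#' the `f_met` share of centrally cleared tegafur, so
#'
#' \deqn{AUC_{Teg} = \frac{k_a}{k_a + k_{a,Met}} \cdot \frac{D}{CL_{Teg}},
#' \quad
#' AUC_{5FU} = \left(\frac{k_{a,Met}}{k_a + k_{a,Met}} +
#'   \frac{k_a}{k_a + k_{a,Met}} f_{Met}\right) \frac{D}{CL_{5FU}}.}
#'
#' These serve as exact oracles for the numerical solvers and for NCA
#' extrapolation.
#'
#' @param params A [structural_params()] object.
#' @param dose Single oral dose (mg/kg tegafur).
#' @return A named list with `tegafur` and `fu` total AUC in ng·h/mL.
#' @export
#' @examples
#' analytic_auc(reference_params("control"), dose = 5)
analytic_auc <- function(params, dose) {
  p <- validate_structural_params(params)
  ktot <- p$ka + p$ka_met
  if (ktot <= 0) stop("ka + ka_met must be positive", call. = FALSE)
  f_abs <- p$ka / ktot
  f_first_pass <- p$ka_met / ktot
  f_to_5fu <- f_first_pass + f_abs * p$f_met
  list(
    tegafur = 1000 * f_abs * dose / p$cl_teg,
    fu = 1000 * f_to_5fu * dose / p$cl_5fu
  )
}

#' Fraction of the dose ever converted to 5-FU
#'
#' @inheritParams analytic_auc
#' @return Dimensionless fraction `(ka_met + ka * f_met) / (ka + ka_met)`.
#' @export
fraction_converted <- function(params) {
  p <- validate_structural_params(params)
  (p$ka_met + p$ka * p$f_met) / (p$ka + p$ka_met)
}

#' Terminal slope of a concentration-time profile
#'
#' Returns the first-order rate constant governing the terminal log-linear
#' decline of an analyte: the smallest-magnitude eigenvalue of the linear
#' subsystem feeding that analyte. For oral dosing the absorption states are
#' included, so that when gut emptying (`ka + ka_met`) or the slow tegafur
#' disposition phase is the slowest rate in the chain, both tegafur and 5-FU
#' inherit it — the flip-flop regime in which the terminal phase of 5-FU
#' reflects its formation, not its (much faster) elimination.
#'
#' @param params A [structural_params()] object.
#' @param analyte `"tegafur"` or `"fu"`.
#' @param route `"oral"` (default) or `"iv"`; `"iv"` is only meaningful for
#'   5-FU and uses the two-compartment disposition subsystem alone.
#' @return Terminal rate constant (1/h, positive). Halve `log(2)` by it for
#'   the terminal half-life.
#' @export
#' @examples
#' lam <- terminal_slope(reference_params("control"), "fu", route = "iv")
#' log(2) / lam * 60  # terminal half-life in minutes
terminal_slope <- function(params, analyte = c("tegafur", "fu"),
                           route = c("oral", "iv")) {
  analyte <- match.arg(analyte)
  route <- match.arg(route)
  A <- pk_rate_matrix(params)
  idx <- if (route == "iv") {
    if (analyte != "fu") {
      stop("intravenous dosing is only modelled for 5-FU", call. = FALSE)
    }
    5:6
  } else if (analyte == "tegafur") {
    1:3
  } else {
    1:6
  }
  sub <- A[idx, idx, drop = FALSE]
  # unit dose into the input state; central compartment of the analyte
  x0 <- numeric(length(idx))
  x0[1L] <- 1  # gut depot for oral, 5-FU central for IV
  row <- if (route == "iv") 1L else if (analyte == "tegafur") 2L else 5L
  es <- .eigen_system(sub)
  if (is.null(es)) {
    # defective eigenbasis: log-linear regression on the simulated tail
    tail_t <- seq(150, 250, by = 2)
    prof <- simulate_profile(params, dose_event(0, 1, "oral_teg"), tail_t,
                             method = "ode")
    y <- if (analyte == "tegafur") prof$tegafur else prof$fu
    return(-unname(stats::coef(stats::lm(log(y) ~ tail_t))[2]))
  }
  # keep only modes that actually contribute to the analyte's profile:
  # a disconnected state (e.g. the peripheral compartment as cld -> 0) adds a
  # near-zero eigenvalue with vanishing residue
  resid_coef <- es$V[row, ] * as.vector(es$Vinv %*% x0)
  keep <- abs(resid_coef) > 1e-7 * max(abs(resid_coef))
  min(abs(es$values[keep]))
}
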