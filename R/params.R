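#' Structural pharmacokinetic parameters for the tegafur/5-FU model
#'
#' Constructs the 12 apparent (per-bioavailability) parameters of the six-state
#' linear model: first-order tegafur absorption (`ka`), first-order formation of
#' the 5-FU precursor from the gut and first-pass route (`ka_met`), conversion
#' of precursor to 5-FU (`k_conv`), two-compartment disposition of tegafur
#' (`cl_teg`, `cld_teg`, `v1_teg`, `v2_teg`) and of 5-FU (`cl_5fu`, `cld_5fu`,
#' `v1_5fu`, `v2_5fu`), and the fraction `f_met` of centrally cleared tegafur
#' that is routed to the 5-FU precursor.
#'
#' Internal units are mg/kg for amounts, L/kg for volumes, L/h/kg for
#' clearances and 1/h for rate constants; concentrations are converted to
#' ng/mL only at the output boundary (1 mg/L = 1000 ng/mL).
#'
#' @param ka First-order absorption rate constant of tegafur (1/h).
#' @param ka_met First-order formation rate of the 5-FU precursor from the gut
#'   compartment (1/h).
#' @param k_conv First-order conversion rate of precursor to 5-FU (1/h).
#' @param cl_teg,cld_teg Apparent systemic and distribution clearance of
#'   tegafur (L/h/kg).
#' @param f_met Fraction of centrally eliminated tegafur routed to the 5-FU
#'   precursor (dimensionless, in `[0, 1]`).
#' @param cl_5fu,cld_5fu Apparent systemic and distribution clearance of 5-FU
#'   (L/h/kg).
#' @param v1_teg,v2_teg,v1_5fu,v2_5fu Apparent central and peripheral volumes
#'   of distribution (L/kg).
#'
#' @return An object of class `structural_params` (a named list).
#' @seealso [reference_params()] for published rat estimates,
#'   [simulate_profile()], [analytic_auc()], [terminal_slope()].
#' @export
#' @examples
#' p <- reference_params("control")
#' p$ka
structural_params <- function(ka, ka_met, k_conv, cl_teg, cld_teg, f_met,
                              cl_5fu, cld_5fu, v1_teg, v2_teg, v1_5fu, v2_5fu) {
  p <- list(
    ka = ka, ka_met = ka_met, k_conv = k_conv,
    cl_teg = cl_teg, cld_teg = cld_teg, f_met = f_met,
    cl_5fu = cl_5fu, cld_5fu = cld_5fu,
    v1_teg = v1_teg, v2_teg = v2_teg, v1_5fu = v1_5fu, v2_5fu = v2_5fu
  )
  validate_structural_params(p)
  structure(p, class = "structural_params")
}

#' @rdname structural_params
#' @param p A list of parameter values to validate.
#' @export
validate_structural_params <- function(p) {
  expected <- c("ka", "ka_met", "k_conv", "cl_teg", "cld_teg", "f_met",
                "cl_5fu", "cld_5fu", "v1_teg", "v2_teg", "v1_5fu", "v2_5fu")
  missing <- setdiff(expected, names(p))
  if (length(missing) > 0) {
    stop("missing structural parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(p[expected])
  if (any(!is.finite(vals))) {
    stop("structural parameters must be finite, got non-finite: ",
         paste(expected[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  pos <- setdiff(expected, "f_met")
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad) > 0) {
    stop("structural parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$f_met < 0 || p$f_met > 1) {
    stop("f_met must lie in [0, 1], got ", p$f_met, call. = FALSE)
  }
  invisible(p)
}

#' Published population parameter estimates for the rat S-1 study
#'
#' Typical-value parameter sets estimated from the rat study that motivates
#' this package: a control group (vehicle-pretreated) and a group pretreated
#' with repeated doses of the herbal medicine Sipjeondaebo-tang (SDT). The
#' pretreatment effect is carried by slower `ka` and `ka_met` and a higher
#' `cl_5fu`; all other parameters are shared.
#'
#' @param group `"control"` or `"sdt"` (repeated-dose SDT pretreatment).
#' @return A [structural_params()] object.
#' @export
#' @examples
#' analytic_auc(reference_params("control"), dose = 5)
reference_params <- function(group = c("control", "sdt")) {
  group <- match.arg(group)
  p <- structural_params(
    ka = 0.296, ka_met = 0.122, k_conv = 2.88,
    cl_teg = 0.0813, cld_teg = 0.184, f_met = 0.342,
    cl_5fu = 3.52, cld_5fu = 1.87,
    v1_teg = 0.0464, v2_teg = 0.137,
    v1_5fu = 0.623, v2_5fu = 0.294
  )
  if (group == "sdt") {
    p$ka <- 0.197
    p$ka_met <- 0.0595
    p$cl_5fu <- 5.93
  }
  p
}

#' Published between-subject variability of the population estimates
#'
#' Variances (log scale, S-ADAPT convention) reported alongside the population
#' means returned by [reference_params()]. For parameters estimated separately
#' per group the control-group value is used.
#'
#' @return A named numeric vector of log-scale variances, one per structural
#'   parameter.
#' @export
reference_bsv <- function() {
  c(ka = 0.0101, ka_met = 0.308, k_conv = 0.747,
    cl_teg = 0.00221, cld_teg = 0.105, f_met = 0.0162,
    cl_5fu = 0.163, cld_5fu = 0.168,
    v1_teg = 0.729, v2_teg = 0.0141,
    v1_5fu = 0.291, v2_5fu = 0.184)
}

#' Dose events
#'
#' A dose event places drug into the model at a given time: oral S-1 doses
#' (expressed as mg/kg tegafur) enter the gut compartment, intravenous 5-FU
#' doses enter the 5-FU central compartment.
#'
#' @param time Dosing time (h, non-negative).
#' @param amount Dose amount (mg/kg, non-negative).
#' @param route `"oral_teg"` or `"iv_5fu"`.
#' @return A tibble with columns `time`, `amount`, `route`; multiple events
#'   may be bound together with [rbind()] / [dplyr::bind_rows()].
#' @export
#' @examples
#' dose_event(0, 5, "oral_teg")
dose_event <- function(time = 0, amount = 5, route = c("oral_teg", "iv_5fu")) {
  route <- match.arg(route)
  if (!is.finite(time) || time < 0) stop("dose time must be >= 0", call. = FALSE)
  if (!is.finite(amount) || amount < 0) stop("dose amount must be >= 0", call. = FALSE)
  tibble::tibble(time = time, amount = amount, route = route)
}

# internal: parameter vector <-> list transforms used by the estimator
.param_names <- c("ka", "ka_met", "k_conv", "cl_teg", "cld_teg", "f_met",
                  "cl_5fu", "cld_5fu", "v1_teg", "v2_teg", "v1_5fu", "v2_5fu")

# log scale for positive parameters, logit for f_met
.to_unconstrained <- function(p) {
  v <- vapply(.param_names, function(nm) {
    if (nm == "f_met") stats::qlogis(p[[nm]]) else log(p[[nm]])
  }, numeric(1))
  names(v) <- .param_names
  v
}

.from_unconstrained <- function(v) {
  p <- lapply(.param_names, function(nm) {
    if (nm == "f_met") stats::plogis(v[[nm]]) else exp(v[[nm]])
  })
  names(p) <- .param_names
  structure(p, class = "structural_params")
}
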