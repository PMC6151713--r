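#' Select the terminal elimination rate constant (lambda-z)
#'
#' Log-linear least squares on the terminal portion of a profile. Candidate
#' subsets are every contiguous run of the last k quantifiable post-Tmax
#' points (k = 3 up to all of them, the Cmax point itself excluded); the
#' subset maximizing the adjusted R-squared wins, with ties broken toward
#' more points. Subsets with a non-negative slope are not eligible.
#'
#' @param time,conc Numeric vectors of observation times (h, strictly
#'   increasing) and concentrations (ng/mL); only quantifiable points should
#'   be passed.
#' @return A list with `lambda_z` (1/h), `n_points`, `adj_r2` and
#'   `estimable`. When fewer than 3 usable points exist (or no declining
#'   subset), `estimable` is `FALSE` and the numeric fields are `NA` —
#'   flagged, not an error.
#' @export
#' @examples
#' t <- c(1, 2, 4, 8, 12)
#' select_lambda_z(t, 100 * exp(-0.3465 * t))$lambda_z
select_lambda_z <- function(time, conc) {
  stopifnot(length(time) == length(conc))
  keep <- is.finite(conc) & conc > 0
  time <- time[keep]; conc <- conc[keep]
  not_est <- list(lambda_z = NA_real_, n_points = NA_integer_,
                  adj_r2 = NA_real_, estimable = FALSE)
  if (length(time) < 3) return(not_est)
  i_max <- which.max(conc)
  time <- time[-seq_len(i_max)]
  conc <- conc[-seq_len(i_max)]
  m <- length(time)
  if (m < 3) return(not_est)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1):m
    fit <- stats::lm.fit(cbind(1, time[idx]), log(conc[idx]))
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0) next
    y <- log(conc[idx])
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    # strictly-greater comparison with k ascending breaks ties toward more points
    if (is.null(best) || adj >= best$adj_r2 - 1e-12) {
      best <- list(lambda_z = -slope, n_points = as.integer(k),
                   adj_r2 = adj, estimable = TRUE)
    }
  }
  if (is.null(best)) not_est else best
}

#' Noncompartmental analysis of one concentration-time profile
#'
#' Cmax and Tmax are read directly from the observations. AUC to the last
#' quantifiable observation (`auc_all`) uses the linear trapezoidal rule
#' (the log-down variant is available via `auc_method`), starting from a
#' zero concentration at time 0 for extravascular profiles. The terminal
#' rate constant comes from [select_lambda_z()];
#' `auc_inf = auc_all + Clast_observed / lambda_z`,
#' `cl_f = dose / auc_inf` (reported in mL/min/kg) and
#' `vz_f = dose / (lambda_z * auc_inf)` (L/kg).
#'
#' BLQ observations are excluded (not zeroed) after the first quantifiable
#' point; a leading predose BLQ is treated as a zero at time 0.
#'
#' @param time,conc Observation vectors (h, ng/mL), strictly increasing times.
#' @param dose Administered dose (mg/kg).
#' @param blq Optional 0/1 vector flagging below-LLOQ observations.
#' @param auc_method `"linear"` (default) or `"linear-log"` (linear up /
#'   log down).
#' @return A one-row tibble of class `nca_result`: `lambda_z`, `t_half`,
#'   `tmax`, `cmax`, `auc_all`, `auc_inf`, `cl_f` (mL/min/kg), `vz_f` (L/kg),
#'   `n_lambda`, `adj_r2`, `extrap_frac`, `estimable`. When lambda-z is not
#'   estimable the extrapolated quantities are `NA`.
#' @export
#' @examples
#' t <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
#' compute_nca(t, 100 * exp(-0.3 * t), dose = 5)
compute_nca <- function(time, conc, dose, blq = NULL,
                        auc_method = c("linear", "linear-log")) {
  auc_method <- match.arg(auc_method)
  stopifnot(length(time) == length(conc), dose >= 0)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("observation times must be strictly increasing", call. = FALSE)
  }
  if (is.null(blq)) blq <- as.integer(!(is.finite(conc) & conc > 0))
  quant <- blq == 0 & is.finite(conc)
  tq <- time[quant]; cq <- conc[quant]
  # anchor extravascular profiles at (0, 0) unless a quantifiable 0 h point exists
  if (length(tq) > 0 && tq[1] > 0) {
    tq <- c(0, tq); cq <- c(0, cq)
  }
  if (length(tq) < 2) {
    return(.nca_row(rep(NA_real_, 11), estimable = FALSE))
  }
  i_max <- which.max(cq)
  cmax <- cq[i_max]; tmax <- tq[i_max]
  auc_all <- .auc_trapezoid(tq, cq, auc_method)
  lz <- select_lambda_z(tq, cq)
  if (lz$estimable) {
    clast <- cq[length(cq)]
    auc_inf <- auc_all + clast / lz$lambda_z
    cl_f <- dose / (auc_inf / 1000) * 1000 / 60     # mg/kg over mg.h/L -> mL/min/kg
    vz_f <- dose / (lz$lambda_z * auc_inf / 1000)   # L/kg
    .nca_row(c(lz$lambda_z, log(2) / lz$lambda_z, tmax, cmax, auc_all,
               auc_inf, cl_f, vz_f, lz$n_points, lz$adj_r2,
               (auc_inf - auc_all) / auc_inf), estimable = TRUE)
  } else {
    .nca_row(c(NA_real_, NA_real_, tmax, cmax, auc_all, rep(NA_real_, 6)),
             estimable = FALSE)
  }
}

.nca_row <- function(v, estimable) {
  tibble::new_tibble(
    list(lambda_z = v[1], t_half = v[2], tmax = v[3], cmax = v[4],
         auc_all = v[5], auc_inf = v[6], cl_f = v[7], vz_f = v[8],
         n_lambda = as.integer(v[9]), adj_r2 = v[10], extrap_frac = v[11],
         estimable = estimable),
    class = "nca_result"
  )
}

.auc_trapezoid <- function(t, c, method = "linear") {
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linear-log") {
    down <- c2 < c1 & c2 > 0 & c1 > 0
    seg[down] <- dt[down] * (c1[down] - c2[down]) / log(c1[down] / c2[down])
  }
  sum(seg)
}

#' NCA for every subject and analyte in a study dataset
#'
#' Splits a [simulate_study()] / [read_dataset()] table into per-subject
#' profiles and applies [compute_nca()] to each. The dose is taken from the
#' subject's dose record (for gimeracil profiles generated alongside an oral
#' S-1 dose, supply `gimeracil_dose` since the gimeracil component differs
#' from the tegafur amount).
#'
#' @param dataset A `study_dataset` tibble.
#' @param gimeracil_dose Dose (mg/kg) used for `DVID = 3` records; defaults
#'   to 1.45, the gimeracil component of the rat S-1 dose.
#' @param auc_method Passed to [compute_nca()].
#' @return A tibble with one row per subject x analyte: `ID`, `GROUP`,
#'   `analyte`, and the [compute_nca()] columns.
#' @export
nca_dataset <- function(dataset, gimeracil_dose = 1.45,
                        auc_method = "linear") {
  obs <- dataset[dataset$EVID == 0, , drop = FALSE]
  dose_tbl <- dataset[dataset$EVID == 1, , drop = FALSE]
  keys <- unique(obs[, c("ID", "GROUP", "DVID")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- obs$ID == keys$ID[i] & obs$DVID == keys$DVID[i]
    sub <- obs[sel, , drop = FALSE]
    sub <- sub[order(sub$TIME), , drop = FALSE]
    dose <- if (keys$DVID[i] == 3L) {
      gimeracil_dose
    } else {
      sum(dose_tbl$AMT[dose_tbl$ID == keys$ID[i]], na.rm = TRUE)
    }
    res <- compute_nca(sub$TIME, sub$DV, dose = dose, blq = sub$BLQ,
                       auc_method = auc_method)
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(ID = keys$ID[i], GROUP = keys$GROUP[i],
                     analyte = .analyte_name(keys$DVID[i])),
      res
    )
  }
  dplyr::bind_rows(out)
}

#' Two-group comparison by unpaired t-test
#'
#' Two-sided pooled-variance (Student) unpaired t-test, the test used for the
#' study's group comparisons; `welch = TRUE` switches to the Welch variant.
#' Degenerate inputs with zero pooled variance return p = 1 when the means
#' are equal and p = 0 otherwise, flagged as `degenerate`.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param welch Use the Welch (unequal-variance) test instead.
#' @return A list: `statistic`, `p_value`, `significant` (at 0.05),
#'   `degenerate`.
#' @export
#' @examples
#' compare_groups(c(340, 300, 380, 360, 359), c(150, 120, 160, 140, 141))
compare_groups <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    return(list(statistic = NA_real_, p_value = p,
                significant = p < 0.05, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < 0.05, degenerate = FALSE)
}

#' Group summary table in the published layout
#'
#' Summarises per-subject NCA results as mean +/- SD per group with a
#' significance star on the pretreated group when the unpaired t-test against
#' control gives p < 0.05.
#'
#' @param nca_tbl Output of [nca_dataset()].
#' @param parameters Which NCA parameters to tabulate.
#' @return A tibble with `analyte`, `parameter`, per-group mean and sd,
#'   `p_value` and a formatted `label` column (`"mean ± sd *"`).
#' @export
nca_summary <- function(nca_tbl,
                        parameters = c("t_half", "tmax", "cmax", "auc_all",
                                       "auc_inf", "cl_f", "vz_f")) {
  long <- tidyr::pivot_longer(
    nca_tbl[, c("ID", "GROUP", "analyte", parameters)],
    cols = dplyr::all_of(parameters),
    names_to = "parameter", values_to = "value"
  )
  long <- long[is.finite(long$value), , drop = FALSE]
  grp <- dplyr::group_by(long, .data$analyte, .data$parameter)
  dplyr::summarise(
    grp,
    mean_control = mean(.data$value[.data$GROUP == 0]),
    sd_control = stats::sd(.data$value[.data$GROUP == 0]),
    mean_sdt = mean(.data$value[.data$GROUP == 1]),
    sd_sdt = stats::sd(.data$value[.data$GROUP == 1]),
    p_value = .safe_p(.data$value[.data$GROUP == 0],
                      .data$value[.data$GROUP == 1]),
    label = sprintf("%.1f ± %.1f vs %.1f ± %.1f%s",
                    .data$mean_control, .data$sd_control,
                    .data$mean_sdt, .data$sd_sdt,
                    ifelse(.data$p_value < 0.05, " *", "")),
    .groups = "drop"
  )
}

.safe_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  compare_groups(x, y)$p_value
}
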