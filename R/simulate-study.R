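#' Simulate a two-group single-dose rat study
#'
#' Generates a complete virtual study with the statistical structure the
#' population analysis assumes: per-subject parameters drawn with log-normal
#' between-subject variability and group effects, exact structural-model
#' profiles, combined additive + proportional residual error, and LLOQ
#' censoring flags. The result is a NONMEM-like long table (one dose row and
#' one row per observation) that round-trips through [write_dataset()] /
#' [read_dataset()].
#'
#' Observations below the analyte LLOQ keep their measured value but carry
#' `BLQ = 1`; the predose sample is recorded as 0 and flagged BLQ. The
#' generator is fully deterministic given `(pop, design, seed)`.
#'
#' @param pop A [population_model()].
#' @param design A [study_design()].
#' @param seed Integer seed; mandatory.
#' @param gimeracil Optionally a [gimeracil_model()]; if supplied, gimeracil
#'   observations (`DVID = 3`) are generated for the same subjects.
#' @return A tibble of class `study_dataset` with columns `ID`, `TIME`,
#'   `EVID`, `AMT`, `ROUTE`, `DVID`, `DV`, `BLQ`, `GROUP`. The true
#'   per-subject parameters are attached as attribute `"subject_params"`.
#' @export
#' @examples
#' ds <- simulate_study(default_population_model(), study_design(), seed = 1)
#' dplyr::count(ds, GROUP, EVID)
simulate_study <- function(pop, design, seed, gimeracil = NULL) {
  stopifnot(inherits(pop, "population_model"),
            inherits(design, "study_design"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (length(design$times) == 0) stop("design has no sampling times", call. = FALSE)
  set.seed(seed)
  n <- design$n_per_group
  ids <- seq_len(2L * n)
  groups <- rep(c(0L, 1L), each = n)
  rows <- vector("list", length(ids))
  subject_params <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p_i <- draw_subject(pop, groups[i])
    subject_params[[i]] <- p_i
    obs_times <- design$times[design$times > 0]
    pred <- .predict_oral(p_i, obs_times, design$dose)
    sub <- list(.dose_row(ids[i], 0, design$dose, "ORAL_TEG", groups[i]))
    for (analyte in c("tegafur", "fu")) {
      dvid <- .analyte_code(analyte)
      sub[[length(sub) + 1L]] <- .obs_rows(
        ids[i], groups[i], design$times, dvid,
        pred[[analyte]], pop$residual[[analyte]], design$lloq[[analyte]]
      )
    }
    if (!is.null(gimeracil)) {
      g_i <- .draw_gimeracil(gimeracil, groups[i])
      conc <- .bateman(obs_times, gimeracil$dose, g_i$ka, g_i$cl, g_i$v, g_i$frel)
      sub[[length(sub) + 1L]] <- .obs_rows(
        ids[i], groups[i], design$times, 3L,
        conc, gimeracil$residual, design$lloq[["gimeracil"]]
      )
    }
    rows[[i]] <- dplyr::bind_rows(sub)
  }
  out <- dplyr::bind_rows(rows)
  .as_study_dataset(out, seed = seed, subject_params = subject_params)
}

#' Simulate an auxiliary intravenous 5-FU arm
#'
#' A separate group of subjects receiving an IV bolus of 5-FU (default
#' 10 mg/kg), observed for 5-FU only. Used to inform 5-FU disposition when
#' co-fitted with the oral arms. 5-FU declines fast after an IV bolus, so the
#' default sampling grid is front-loaded.
#'
#' @param pop A [population_model()].
#' @param n Number of subjects.
#' @param dose IV dose (mg/kg).
#' @param times Sampling times (h).
#' @param seed Integer seed.
#' @param id_offset Added to subject IDs so the arm can be bound to an oral
#'   dataset without ID clashes.
#' @param lloq LLOQ for 5-FU (ng/mL).
#' @return A `study_dataset` tibble (GROUP = 0).
#' @export
simulate_iv_study <- function(pop, n = 5, dose = 10,
                              times = c(0.033, 0.083, 0.167, 0.25, 0.5,
                                        0.75, 1, 1.5, 2),
                              seed, id_offset = 1000L, lloq = 10) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  rows <- vector("list", n)
  subject_params <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- draw_subject(pop, 0)
    subject_params[[i]] <- p_i
    pred <- .predict_iv_5fu(p_i, times, dose)
    rows[[i]] <- dplyr::bind_rows(
      .dose_row(id_offset + i, 0, dose, "IV_5FU", 0L),
      .obs_rows(id_offset + i, 0L, times, 2L, pred,
                pop$residual[["fu"]], lloq, predose_zero = FALSE)
    )
  }
  out <- dplyr::bind_rows(rows)
  .as_study_dataset(out, seed = seed, subject_params = subject_params)
}

#' Simulate stand-alone gimeracil profiles
#'
#' Generates gimeracil-only observation records (`DVID = 3`) for a two-group
#' study under the one-compartment [gimeracil_model()]. Subjects receive the
#' gimeracil component of the S-1 dose.
#'
#' @param model A [gimeracil_model()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A `study_dataset` tibble.
#' @export
simulate_gimeracil <- function(model = gimeracil_model(), design = study_design(),
                               seed) {
  stopifnot(inherits(model, "gimeracil_model"), inherits(design, "study_design"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  n <- design$n_per_group
  ids <- seq_len(2L * n)
  groups <- rep(c(0L, 1L), each = n)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g_i <- .draw_gimeracil(model, groups[i])
    obs_times <- design$times[design$times > 0]
    conc <- .bateman(obs_times, model$dose, g_i$ka, g_i$cl, g_i$v, g_i$frel)
    rows[[i]] <- dplyr::bind_rows(
      .dose_row(ids[i], 0, model$dose, "ORAL_TEG", groups[i]),
      .obs_rows(ids[i], groups[i], design$times, 3L, conc,
                model$residual, design$lloq[["gimeracil"]])
    )
  }
  .as_study_dataset(dplyr::bind_rows(rows), seed = seed,
                    subject_params = NULL)
}

.draw_gimeracil <- function(model, group) {
  g <- list(ka = model$ka, cl = model$cl, v = model$v, frel = model$frel)
  if (group == 1 && length(model$group_mult) > 0) {
    for (nm in names(model$group_mult)) g[[nm]] <- g[[nm]] * model$group_mult[[nm]]
  }
  for (nm in names(model$bsv)) {
    g[[nm]] <- g[[nm]] * exp(stats::rnorm(1, 0, sqrt(model$bsv[[nm]])))
  }
  g
}

.analyte_code <- function(analyte) {
  c(tegafur = 1L, fu = 2L, gimeracil = 3L)[[analyte]]
}

.analyte_name <- function(dvid) {
  c("tegafur", "fu", "gimeracil")[dvid]
}

.dose_row <- function(id, time, amt, route, group) {
  tibble::tibble(ID = as.integer(id), TIME = time, EVID = 1L, AMT = amt,
                 ROUTE = route, DVID = NA_integer_, DV = NA_real_,
                 BLQ = NA_integer_, GROUP = as.integer(group))
}

# noisy observation rows for one analyte; the predose sample (time 0) is
# recorded as 0 and flagged BLQ, never given residual noise
.obs_rows <- function(id, group, times, dvid, pred, err, lloq,
                      predose_zero = TRUE) {
  obs_times <- times[times > 0]
  sd <- .residual_sd(err, pred)
  dv <- pmax(pred + stats::rnorm(length(pred), 0, sd), 0)
  blq <- as.integer(dv < lloq)
  if (predose_zero && any(times == 0)) {
    obs_times <- c(0, obs_times)
    dv <- c(0, dv)
    blq <- c(1L, blq)
  }
  tibble::tibble(ID = as.integer(id), TIME = obs_times, EVID = 0L,
                 AMT = NA_real_, ROUTE = NA_character_,
                 DVID = as.integer(dvid), DV = dv, BLQ = blq,
                 GROUP = as.integer(group))
}

.as_study_dataset <- function(x, seed = NULL, subject_params = NULL) {
  out <- tibble::as_tibble(x)
  class(out) <- c("study_dataset", class(out))
  attr(out, "seed") <- seed
  attr(out, "subject_params") <- subject_params
  out
}

#' Bind study datasets together
#'
#' @param ... `study_dataset` tibbles (e.g. an oral study and an IV arm).
#' @return A combined `study_dataset`; subject-parameter attributes are
#'   concatenated when all inputs carry them.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  sp <- lapply(parts, attr, "subject_params")
  sp <- if (any(vapply(sp, is.null, logical(1)))) NULL else do.call(c, sp)
  .as_study_dataset(dplyr::bind_rows(parts), subject_params = sp)
}
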