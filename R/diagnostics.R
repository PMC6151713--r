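#' Visual predictive check
#'
#' Simulates `n_sim` replicate studies under the model at the observed
#' design (same subjects, groups and nominal sampling times, new
#' between-subject and residual variability each replicate) and summarises
#' the simulated concentrations as the 10th, 25th, 50th, 75th and 90th
#' percentiles per nominal time point, analyte and group. Observations are
#' returned alongside for overlay; BLQ records are excluded from the
#' overlay. Time bins are the nominal sampling times (no adaptive binning)
#' and the bands are plain prediction intervals (a single dose level per arm
#' makes prediction correction unnecessary).
#'
#' @param object A [population_model()] or `pk_fit`.
#' @param dataset The observed `study_dataset`.
#' @param n_sim Number of replicate studies (>= 100).
#' @param seed Integer seed; identical inputs give identical bands.
#' @return A list of class `vpc_result`: `bands` (tibble with `analyte`,
#'   `GROUP`, `time`, `n_obs`, `p10` ... `p90`) and `observed` (the non-BLQ
#'   observations).
#' @export
vpc <- function(object, dataset, n_sim = 200, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)
  if (inherits(object, "pk_fit")) object <- as_population_model(object)
  stopifnot(inherits(object, "population_model"))
  subs <- .vpc_subjects(dataset)
  set.seed(seed)
  sims <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    reps <- matrix(NA_real_, n_sim, length(sub$time))
    for (r in seq_len(n_sim)) {
      p <- draw_subject(object, sub$group)
      reps[r, ] <- .vpc_predict(p, sub, object$residual)
    }
    sims[[i]] <- tibble::tibble(
      analyte = rep(sub$analyte, each = n_sim),
      GROUP = sub$group,
      time = rep(sub$time, each = n_sim),
      sim = as.vector(reps)
    )
  }
  simtab <- dplyr::bind_rows(sims)
  qs <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  bands <- dplyr::summarise(
    dplyr::group_by(simtab, .data$analyte, .data$GROUP, .data$time),
    n_obs = dplyr::n() / n_sim,
    p10 = stats::quantile(.data$sim, qs[1], names = FALSE),
    p25 = stats::quantile(.data$sim, qs[2], names = FALSE),
    p50 = stats::quantile(.data$sim, qs[3], names = FALSE),
    p75 = stats::quantile(.data$sim, qs[4], names = FALSE),
    p90 = stats::quantile(.data$sim, qs[5], names = FALSE),
    .groups = "drop"
  )
  obs <- dataset[dataset$EVID == 0 & dataset$BLQ == 0 & dataset$TIME > 0, ,
                 drop = FALSE]
  obs$analyte <- .analyte_name(obs$DVID)
  structure(
    list(bands = bands, observed = obs, percentiles = 100 * qs,
         n_sim = n_sim, seed = seed),
    class = "vpc_result"
  )
}

# observed design per subject: times per analyte (nominal, > 0), route, dose
.vpc_subjects <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & dataset$TIME > 0 &
                   dataset$DVID %in% c(1L, 2L), , drop = FALSE]
  doses <- dataset[dataset$EVID == 1, , drop = FALSE]
  ids <- sort(unique(obs$ID))
  lapply(ids, function(id) {
    o <- obs[obs$ID == id, , drop = FALSE]
    o <- o[order(o$DVID, o$TIME), , drop = FALSE]
    d <- doses[doses$ID == id, , drop = FALSE]
    list(id = id, group = d$GROUP[1], dose = d$AMT[1],
         route = tolower(d$ROUTE[1]),
         time = o$TIME, analyte = .analyte_name(o$DVID))
  })
}

# one replicate of a subject's observation vector (prediction + residual)
.vpc_predict <- function(p, sub, residual) {
  out <- numeric(length(sub$time))
  for (analyte in unique(sub$analyte)) {
    sel <- sub$analyte == analyte
    pred <- if (sub$route == "iv_5fu") {
      .predict_iv_5fu(p, sub$time[sel], sub$dose)
    } else {
      .predict_oral(p, sub$time[sel], sub$dose)[[analyte]]
    }
    sd <- .residual_sd(residual[[analyte]], pred)
    out[sel] <- pred + stats::rnorm(length(pred), 0, sd)
  }
  out
}

#' Normalized prediction distribution errors
#'
#' For each subject, `n_sim` replicate observation vectors are simulated
#' under the model; observed and simulated vectors are decorrelated with the
#' inverse Cholesky factor of the empirical simulation covariance, and each
#' decorrelated observation is mapped to a standard-normal deviate through
#' the rank of the observation within its simulated distribution. Under a
#' correct model the NPDE sample is standard normal. Rank ties are broken by
#' a deterministic uniform jitter of width `1/n_sim`; a singular empirical
#' covariance is ridge-regularized with a warning.
#'
#' @param object A [population_model()] or `pk_fit`.
#' @param dataset The observed `study_dataset`.
#' @param n_sim Number of simulated replicates per subject (>= 500).
#' @param seed Integer seed.
#' @return A list of class `npde_result`: `table` (tibble `ID`, `GROUP`,
#'   `analyte`, `time`, `npde`), `mean`, `var`, and a Shapiro-Wilk normality
#'   test (`normality_stat`, `normality_p`).
#' @export
npde <- function(object, dataset, n_sim = 500, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n_sim < 500) stop("n_sim must be at least 500", call. = FALSE)
  if (inherits(object, "pk_fit")) object <- as_population_model(object)
  stopifnot(inherits(object, "population_model"))
  obs_all <- dataset[dataset$EVID == 0 & dataset$TIME > 0 &
                       dataset$DVID %in% c(1L, 2L) & dataset$BLQ == 0, ,
                     drop = FALSE]
  doses <- dataset[dataset$EVID == 1, , drop = FALSE]
  set.seed(seed)
  ids <- sort(unique(obs_all$ID))
  rows <- vector("list", length(ids))
  for (ii in seq_along(ids)) {
    id <- ids[ii]
    o <- obs_all[obs_all$ID == id, , drop = FALSE]
    o <- o[order(o$DVID, o$TIME), , drop = FALSE]
    d <- doses[doses$ID == id, , drop = FALSE]
    sub <- list(id = id, group = d$GROUP[1], dose = d$AMT[1],
                route = tolower(d$ROUTE[1]),
                time = o$TIME, analyte = .analyte_name(o$DVID))
    n_i <- length(sub$time)
    sims <- matrix(NA_real_, n_sim, n_i)
    for (r in seq_len(n_sim)) {
      p <- draw_subject(object, sub$group)
      sims[r, ] <- .vpc_predict(p, sub, object$residual)
    }
    ybar <- colMeans(sims)
    S <- stats::cov(sims)
    L <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(L)) {
      warning("singular simulation covariance for subject ", id,
              "; ridge-regularized", call. = FALSE)
      ridge <- 1e-8 * mean(diag(S)) + 1e-12
      L <- chol(S + diag(ridge, n_i))
    }
    y_dec <- backsolve(L, o$DV - ybar, transpose = TRUE)
    sim_dec <- t(backsolve(L, t(sims) - ybar, transpose = TRUE))
    counts <- colSums(sim_dec < matrix(y_dec, n_sim, n_i, byrow = TRUE))
    pde <- counts / n_sim + stats::runif(n_i, 0, 1 / n_sim)
    pde <- pmin(pmax(pde, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    rows[[ii]] <- tibble::tibble(
      ID = id, GROUP = sub$group, analyte = sub$analyte, time = sub$time,
      npde = stats::qnorm(pde)
    )
  }
  tab <- dplyr::bind_rows(rows)
  sw <- stats::shapiro.test(
    if (nrow(tab) > 5000) sample(tab$npde, 5000) else tab$npde
  )
  structure(
    list(table = tab, mean = mean(tab$npde), var = stats::var(tab$npde),
         normality_stat = unname(sw$statistic),
         normality_p = sw$p.value, n_sim = n_sim, seed = seed),
    class = "npde_result"
  )
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations: mean %.3f, variance %.3f\n",
              nrow(x$table), x$mean, x$var))
  cat(sprintf("Shapiro-Wilk W = %.3f, p = %.3g\n",
              x$normality_stat, x$normality_p))
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Semi-log overlay of the simulated percentile bands and the observations,
#' faceted by analyte and group. Requires \pkg{ggplot2}.
#'
#' @param v A `vpc_result`.
#' @return A ggplot object.
#' @export
plot_vpc <- function(v) {
  stopifnot(inherits(v, "vpc_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  bands <- v$bands
  bands$arm <- ifelse(bands$GROUP == 0, "control", "pretreated")
  obs <- v$observed
  obs$arm <- ifelse(obs$GROUP == 0, "control", "pretreated")
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p25, ymax = .data$p75),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50), colour = "steelblue4") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(x = .data$TIME, y = .data$DV),
                        shape = 1, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(analyte ~ arm, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (ng/mL)")
}

#' Fraction of observations inside a VPC band
#'
#' @param v A `vpc_result`.
#' @param lower,upper Band columns to use (default the interquartile band).
#' @return The fraction of overlay observations lying inside the band at
#'   their nominal time.
#' @export
vpc_coverage <- function(v, lower = "p25", upper = "p75") {
  stopifnot(inherits(v, "vpc_result"))
  obs <- v$observed
  key <- paste(obs$analyte, obs$GROUP, obs$TIME)
  bkey <- paste(v$bands$analyte, v$bands$GROUP, v$bands$time)
  idx <- match(key, bkey)
  ok <- !is.na(idx)
  mean(obs$DV[ok] >= v$bands[[lower]][idx[ok]] &
         obs$DV[ok] <= v$bands[[upper]][idx[ok]])
}
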