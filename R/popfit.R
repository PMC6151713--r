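#' Settings for the population fit
#'
#' Configuration of the importance-sampling Monte Carlo parametric EM
#' estimator. Group effects are multiplicative factors on the typical values
#' (control group = reference), estimated on the log scale; between-subject
#' variability is log-normal (logit-normal for `f_met`) with a diagonal
#' covariance.
#'
#' @param group_params Parameters carrying a pretreatment group effect.
#' @param bsv_params Parameters carrying between-subject variability. The
#'   default covers the parameters that single-dose two-analyte profiles
#'   inform well; any subset of the 12 structural parameters is accepted.
#' @param init Optional list with elements `typical` (a
#'   [structural_params()]), `group_mult`, `omega2`, `residual` to override
#'   the NCA-informed starting values.
#' @param n_mc Importance samples per subject per iteration (>= 100).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative change in marginal log-likelihood below which the fit
#'   is declared converged when sustained over `tol_window` iterations.
#' @param tol_window Number of consecutive iterations over which `tol` must
#'   hold (absorbs Monte-Carlo noise).
#' @param seed Integer seed; importance-sample draws are seeded per subject
#'   from it, so subject order does not affect the fit.
#' @param blq BLQ policy: `"discard"` (M1, default) drops flagged records;
#'   `"censor"` (M3) keeps them as left-censored contributions, i.e. a BLQ
#'   record contributes the probability that the model prediction plus
#'   residual error falls below the analyte LLOQ — recommended when a group's
#'   profiles spend much of their time below the LLOQ, where discarding
#'   biases that group's clearance low; `"keep"` uses the recorded values.
#' @param lloq Named LLOQ vector (ng/mL) per analyte, used by the `"censor"`
#'   policy.
#' @param estimate_residual Estimate the per-analyte residual error models
#'   (shared across groups); if `FALSE` they stay at their initial values.
#' @param mc_inflate Variance inflation factor for the Laplace proposal.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(group_params = c("ka", "ka_met", "cl_5fu"),
                     bsv_params = c("ka", "ka_met", "k_conv", "cl_teg",
                                    "cl_5fu", "v1_teg", "v1_5fu"),
                     init = NULL,
                     n_mc = 300L,
                     max_iter = 50L,
                     tol = 1e-4,
                     tol_window = 10L,
                     seed = 1L,
                     blq = c("discard", "censor", "keep"),
                     lloq = c(tegafur = 50, fu = 10),
                     estimate_residual = TRUE,
                     mc_inflate = 1.2) {
  blq <- match.arg(blq)
  stopifnot(all(group_params %in% .param_names),
            all(bsv_params %in% .param_names))
  if (!all(group_params %in% bsv_params)) {
    stop("group-effect parameters must also carry BSV (the group effect is ",
         "updated from the conditional eta moments)", call. = FALSE)
  }
  if (n_mc < 100) stop("at least 100 importance samples are required", call. = FALSE)
  structure(
    list(group_params = group_params, bsv_params = bsv_params, init = init,
         n_mc = as.integer(n_mc), max_iter = as.integer(max_iter),
         tol = tol, tol_window = as.integer(tol_window),
         seed = as.integer(seed), blq = blq, lloq = lloq,
         estimate_residual = estimate_residual, mc_inflate = mc_inflate),
    class = "fit_spec"
  )
}

#' Individual log-likelihood under the combined residual error model
#'
#' Gaussian log-density of a subject's observations around the structural
#' model predictions, with per-observation standard deviation
#' `sqrt(add^2 + (prop * pred)^2)` from the analyte's residual model.
#'
#' @param params A [structural_params()] object (the subject's parameters).
#' @param obs A tibble with columns `time` (h), `analyte` (`"tegafur"` /
#'   `"fu"`) and `dv` (ng/mL); at least one row.
#' @param residual Named list of [residual_error()] models per analyte.
#' @param dose Dose amount (mg/kg).
#' @param route `"oral_teg"` or `"iv_5fu"`.
#' @return The log-likelihood (scalar).
#' @export
#' @examples
#' obs <- tibble::tibble(time = c(1, 2), analyte = "tegafur", dv = c(5000, 6000))
#' individual_loglik(reference_params("control"), obs,
#'                   list(tegafur = residual_error(25, 0.15)))
individual_loglik <- function(params, obs, residual, dose = 5,
                              route = c("oral_teg", "iv_5fu")) {
  route <- match.arg(route)
  validate_structural_params(params)
  stopifnot(nrow(obs) >= 1)
  ll <- 0
  for (analyte in unique(obs$analyte)) {
    sel <- obs$analyte == analyte
    t_a <- obs$time[sel]
    ord <- order(t_a)
    pred <- if (route == "iv_5fu") {
      if (analyte != "fu") stop("IV dosing provides only 5-FU observations",
                                call. = FALSE)
      .predict_iv_5fu(params, t_a[ord], dose)
    } else {
      .predict_oral(params, t_a[ord], dose)[[analyte]]
    }
    err <- residual[[analyte]]
    if (is.null(err)) stop("no residual model for analyte ", analyte, call. = FALSE)
    sd <- .residual_sd(err, pred)
    if (any(sd <= 0)) stop("residual SD must be positive", call. = FALSE)
    ll <- ll + sum(stats::dnorm(obs$dv[sel][ord], pred, sd, log = TRUE))
  }
  ll
}

# ---- internal fit machinery -------------------------------------------------

# per-subject bundle: id, group, route, dose, per-analyte obs times/values;
# with the censoring policy, BLQ records are kept with a cens flag and the
# analyte LLOQ as the left-censoring bound
.prep_subjects <- function(dataset, blq = "discard",
                           lloq = c(tegafur = 50, fu = 10),
                           keep_empty = FALSE) {
  obs <- dataset[dataset$EVID == 0 & dataset$DVID %in% c(1L, 2L), , drop = FALSE]
  if (blq == "discard") obs <- obs[obs$BLQ == 0, , drop = FALSE]
  obs <- obs[obs$TIME > 0, , drop = FALSE]
  doses <- dataset[dataset$EVID == 1, , drop = FALSE]
  ids <- sort(unique(dataset$ID))
  subs <- lapply(ids, function(id) {
    d <- doses[doses$ID == id, , drop = FALSE]
    if (nrow(d) == 0) stop("subject ", id, " has no dose record", call. = FALSE)
    o <- obs[obs$ID == id, , drop = FALSE]
    grab <- function(dvid, analyte) {
      sel <- o$DVID == dvid
      ord <- order(o$TIME[sel])
      cens <- if (blq == "censor") o$BLQ[sel][ord] == 1 else
        rep(FALSE, sum(sel))
      list(time = o$TIME[sel][ord], dv = o$DV[sel][ord],
           cens = cens, lloq = unname(lloq[analyte]))
    }
    list(id = id, group = d$GROUP[1], route = tolower(d$ROUTE[1]),
         dose = d$AMT[1], teg = grab(1L, "tegafur"), fu = grab(2L, "fu"),
         n_obs = nrow(o))
  })
  if (keep_empty) subs else
    subs[vapply(subs, function(s) s$n_obs > 0, logical(1))]
}

# subject predictions for a parameter set: list(teg =, fu =)
.subject_pred <- function(p, sub) {
  if (sub$route == "iv_5fu") {
    list(teg = numeric(0),
         fu = .predict_iv_5fu(p, sub$fu$time, sub$dose))
  } else {
    pr <- .predict_oral(p, c(sub$teg$time, sub$fu$time), sub$dose)
    nt <- length(sub$teg$time)
    list(teg = pr$tegafur[seq_len(nt)],
         fu = pr$fu[nt + seq_along(sub$fu$time)])
  }
}

.pred_loglik <- function(pred, sub, residual) {
  one <- function(p, o, err) {
    if (length(p) == 0) return(0)
    sd <- .residual_sd(err, p)
    ll <- sum(stats::dnorm(o$dv[!o$cens], p[!o$cens], sd[!o$cens], log = TRUE))
    if (any(o$cens)) {
      # left-censored (M3): probability of falling below the LLOQ
      ll <- ll + sum(stats::pnorm(o$lloq, p[o$cens], sd[o$cens],
                                  log.p = TRUE))
    }
    ll
  }
  ll <- one(pred$teg, sub$teg, residual$tegafur) +
    one(pred$fu, sub$fu, residual$fu)
  # overflowing parameter proposals during optimization get a finite penalty
  if (!is.finite(ll)) ll <- -1e10
  ll
}

# unconstrained subject parameter vector -> structural params, with eta added
# on the BSV subset
.subject_params <- function(theta_g, eta, bsv_params) {
  v <- theta_g
  v[bsv_params] <- v[bsv_params] + eta
  .from_unconstrained(v)
}

# E-step for one subject: Laplace mode, inflated-covariance importance
# sampling with fixed standard-normal draws Z (common random numbers)
.estep_subject <- function(sub, theta_g, omega2, residual, Z, inflate,
                           eta_start) {
  d <- length(omega2)
  bsv_params <- names(omega2)
  osd <- sqrt(pmax(omega2, 1e-10))
  nll <- function(eta) {
    p <- .subject_params(theta_g, eta, bsv_params)
    -(.pred_loglik(.subject_pred(p, sub), sub, residual) +
        sum(stats::dnorm(eta, 0, osd, log = TRUE)))
  }
  opt <- stats::optim(eta_start, nll, method = "BFGS",
                      control = list(reltol = 1e-7, maxit = 80))
  mode <- opt$par
  H <- try(stats::optimHess(mode, nll), silent = TRUE)
  Sigma <- NULL
  if (!inherits(H, "try-error")) {
    H <- (H + t(H)) / 2
    eh <- eigen(H, symmetric = TRUE)
    if (all(eh$values > 1e-8)) {
      Sigma <- inflate * (eh$vectors %*% (t(eh$vectors) / eh$values))
    }
  }
  if (is.null(Sigma)) Sigma <- diag(pmax(omega2, 1e-6), d) * inflate
  U <- chol(Sigma)
  n_mc <- nrow(Z)
  etas <- Z %*% U + matrix(mode, n_mc, d, byrow = TRUE)
  log_prop <- -0.5 * d * log(2 * pi) - sum(log(diag(U))) -
    0.5 * rowSums(Z^2)
  lw <- numeric(n_mc)
  pred_teg <- matrix(0, n_mc, length(sub$teg$time))
  pred_fu <- matrix(0, n_mc, length(sub$fu$time))
  for (k in seq_len(n_mc)) {
    p <- .subject_params(theta_g, etas[k, ], bsv_params)
    pr <- .subject_pred(p, sub)
    if (length(pr$teg)) pred_teg[k, ] <- pr$teg
    if (length(pr$fu)) pred_fu[k, ] <- pr$fu
    lw[k] <- .pred_loglik(pr, sub, residual) +
      sum(stats::dnorm(etas[k, ], 0, osd, log = TRUE)) - log_prop[k]
  }
  mx <- max(lw)
  ll_i <- mx + log(mean(exp(lw - mx)))
  w <- exp(lw - mx)
  w <- w / sum(w)
  list(mode = mode, ll = ll_i, w = w,
       m = colSums(w * etas),
       S2 = colSums(w * etas^2),
       pred_teg = pred_teg, pred_fu = pred_fu)
}

# NCA-informed starting values (control-group subjects only)
.nca_init <- function(dataset) {
  nca <- nca_dataset(dataset[dataset$GROUP == 0, , drop = FALSE])
  med <- function(analyte, what) {
    v <- nca[[what]][nca$analyte == analyte]
    stats::median(v[is.finite(v)])
  }
  auc_teg <- med("tegafur", "auc_inf")
  auc_fu <- med("fu", "auc_inf")
  lam <- med("tegafur", "lambda_z")
  vz <- med("tegafur", "vz_f")
  if (!is.finite(auc_teg) || !is.finite(lam)) {
    stop("NCA-informed initialization failed; supply init in fit_spec()",
         call. = FALSE)
  }
  dose <- dataset$AMT[dataset$EVID == 1][1]
  structural_params(
    ka = 1.5 * lam, ka_met = 0.5 * lam, k_conv = 2,
    cl_teg = dose / (auc_teg / 1000), cld_teg = 0.15,
    f_met = 0.3,
    cl_5fu = if (is.finite(auc_fu)) 0.5 * dose / (auc_fu / 1000) else 3,
    cld_5fu = 1.5,
    v1_teg = max(0.3 * vz, 1e-3, na.rm = TRUE), v2_teg = max(0.7 * vz, 1e-3),
    v1_5fu = 0.5, v2_5fu = 0.3
  )
}

#' Fit the population model by importance-sampling Monte Carlo parametric EM
#'
#' E-step: for each subject, the conditional mode of the random effects is
#' located (Laplace approximation), a multivariate-normal proposal with
#' inflated Laplace covariance is sampled, and self-normalized importance
#' weights yield conditional means and second moments of the random effects
#' plus a marginal log-likelihood estimate. M-step: typical values and group
#' effects are updated as weighted means on the unconstrained (log / logit)
#' scale, BSV variances as mean conditional second central moments, and the
#' residual error parameters by weighted likelihood maximization. Importance
#' draws are fixed per subject across iterations (common random numbers), so
#' the likelihood trace is monotone up to Monte-Carlo noise and the result
#' does not depend on subject order.
#'
#' @param dataset A `study_dataset` (oral two-group study, optionally with an
#'   IV 5-FU arm bound in via [bind_datasets()]).
#' @param spec A [fit_spec()].
#' @return An object of class `pk_fit`: `theta` / `group_mult` (typical
#'   values per group), `omega2`, `residual`, `ll_trace`, `converged`,
#'   per-subject conditional modes (`ebe_eta`), and the spec.
#' @export
mcpem_fit <- function(dataset, spec = fit_spec()) {
  stopifnot(inherits(spec, "fit_spec"))
  subs <- .prep_subjects(dataset, spec$blq, spec$lloq)
  if (length(subs) == 0) stop("no usable subjects in dataset", call. = FALSE)
  oral <- vapply(subs, function(s) s$route == "oral_teg", logical(1))
  if (any(oral)) {
    has_both <- any(vapply(subs[oral], function(s) length(s$teg$time) > 0,
                           logical(1))) &&
      any(vapply(subs[oral], function(s) length(s$fu$time) > 0, logical(1)))
    if (!has_both) {
      stop("oral arms must contain both tegafur and 5-FU observations",
           call. = FALSE)
    }
  }
  bsv <- spec$bsv_params
  d <- length(bsv)
  init <- spec$init
  typ0 <- if (!is.null(init$typical)) init$typical else .nca_init(dataset)
  theta <- .to_unconstrained(typ0)
  gamma <- stats::setNames(rep(0, length(spec$group_params)), spec$group_params)
  if (!is.null(init$group_mult)) {
    gamma[names(init$group_mult)] <- log(init$group_mult)
  }
  omega2 <- stats::setNames(rep(0.1, d), bsv)
  if (!is.null(init$omega2)) {
    common <- intersect(names(init$omega2), bsv)
    omega2[common] <- init$omega2[common]
  }
  residual <- if (!is.null(init$residual)) {
    init$residual
  } else {
    list(tegafur = residual_error(25, 0.2), fu = residual_error(5, 0.2))
  }

  # fixed standard-normal draws per subject (common random numbers; seeded by
  # subject id so the fit is invariant to subject order)
  Zs <- lapply(subs, function(s) {
    set.seed((spec$seed + 9973L * as.integer(s$id)) %% .Machine$integer.max)
    matrix(stats::rnorm(spec$n_mc * d), spec$n_mc, d)
  })
  modes <- lapply(subs, function(s) rep(0, d))
  groups <- vapply(subs, function(s) s$group, numeric(1))

  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(spec$max_iter)) {
    es <- vector("list", length(subs))
    for (i in seq_along(subs)) {
      theta_g <- theta
      if (groups[i] == 1) {
        theta_g[spec$group_params] <- theta_g[spec$group_params] + gamma
      }
      es[[i]] <- .estep_subject(subs[[i]], theta_g, omega2, residual,
                                Zs[[i]], spec$mc_inflate, modes[[i]])
      modes[[i]] <- es[[i]]$mode
    }
    ll <- sum(vapply(es, function(e) e$ll, numeric(1)))
    ll_trace <- c(ll_trace, ll)

    M <- do.call(rbind, lapply(es, function(e) e$m))
    S2 <- do.call(rbind, lapply(es, function(e) e$S2))
    # group-specific mean shifts on the unconstrained scale
    shift <- matrix(0, length(subs), d, dimnames = list(NULL, bsv))
    for (j in seq_len(d)) {
      nm <- bsv[j]
      if (nm %in% spec$group_params) {
        mu0 <- mean(M[groups == 0, j])
        mu1 <- if (any(groups == 1)) mean(M[groups == 1, j]) else mu0
        theta[nm] <- theta[nm] + mu0
        gamma[nm] <- gamma[nm] + (mu1 - mu0)
        shift[, j] <- ifelse(groups == 1, mu1, mu0)
      } else {
        mu <- mean(M[, j])
        theta[nm] <- theta[nm] + mu
        shift[, j] <- mu
      }
    }
    # group effects on parameters without BSV are not updated by eta moments;
    # restrict group_params to the BSV set (checked below)
    omega2 <- pmax(colMeans(S2 - 2 * M * shift + shift^2), 1e-8)
    names(omega2) <- bsv
    # recentre conditional modes for the next warm start
    for (i in seq_along(subs)) modes[[i]] <- modes[[i]] - shift[i, ]

    if (spec$estimate_residual) {
      residual <- .update_residual(es, subs, residual)
    }
    n_tr <- length(ll_trace)
    if (n_tr > spec$tol_window) {
      recent <- ll_trace[(n_tr - spec$tol_window):n_tr]
      rel <- abs(diff(recent)) / pmax(1, abs(recent[-1]))
      if (all(rel < spec$tol)) {
        converged <- TRUE
        break
      }
    }
  }

  typical <- .from_unconstrained(theta)
  structure(
    list(
      typical = typical,
      group_mult = stats::setNames(exp(gamma), spec$group_params),
      omega2 = omega2,
      residual = residual,
      ll_trace = ll_trace,
      converged = converged,
      ebe_eta = stats::setNames(modes, vapply(subs, function(s) s$id, numeric(1))),
      subjects = tibble::tibble(
        ID = vapply(subs, function(s) s$id, numeric(1)),
        GROUP = groups
      ),
      spec = spec
    ),
    class = "pk_fit"
  )
}

.update_residual <- function(es, subs, residual) {
  fit_one <- function(analyte) {
    obj <- function(lp) {
      add <- exp(lp[1]); prop <- exp(lp[2])
      tot <- 0
      for (i in seq_along(subs)) {
        o <- if (analyte == "tegafur") subs[[i]]$teg else subs[[i]]$fu
        if (length(o$dv) == 0) next
        P <- if (analyte == "tegafur") es[[i]]$pred_teg else es[[i]]$pred_fu
        sd <- sqrt(add^2 + (prop * P)^2)
        q <- !o$cens
        lls <- stats::dnorm(matrix(o$dv[q], nrow(P), sum(q), byrow = TRUE),
                            P[, q, drop = FALSE], sd[, q, drop = FALSE],
                            log = TRUE)
        tot <- tot + sum(es[[i]]$w * rowSums(lls))
        if (any(o$cens)) {
          lcs <- stats::pnorm(o$lloq, P[, o$cens, drop = FALSE],
                              sd[, o$cens, drop = FALSE], log.p = TRUE)
          tot <- tot + sum(es[[i]]$w * rowSums(lcs))
        }
      }
      -tot
    }
    cur <- residual[[analyte]]
    opt <- stats::optim(log(c(max(cur$add, 1e-3), max(cur$prop, 1e-3))), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-6, maxit = 200))
    residual_error(exp(opt$par[1]), exp(opt$par[2]))
  }
  list(tegafur = fit_one("tegafur"), fu = fit_one("fu"))
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Population PK fit (importance-sampling MC-PEM)\n")
  cat(sprintf("  iterations: %d, converged: %s, final logLik: %.2f\n",
              length(x$ll_trace), x$converged, utils::tail(x$ll_trace, 1)))
  print(coef(x))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  typ <- unlist(object$typical[.param_names])
  sdt <- typ
  gm <- object$group_mult
  sdt[names(gm)] <- sdt[names(gm)] * gm
  tibble::tibble(
    parameter = .param_names,
    control = unname(typ),
    sdt = unname(sdt),
    omega2 = unname(object$omega2[.param_names])
  )
}

#' Empirical Bayes (MAP) estimates of individual parameters
#'
#' Maximum a posteriori random effects per subject at fixed population
#' parameters, either from a fitted model or from a known
#' [population_model()] plus residual models. A subject with no quantifiable
#' observations sits at the population typical value (prior mode).
#'
#' @param dataset A `study_dataset`.
#' @param object A `pk_fit` or a [population_model()].
#' @param blq BLQ policy (see [fit_spec()]).
#' @param lloq LLOQ per analyte for the `"censor"` policy.
#' @return A tibble with one row per subject: `ID`, `GROUP`, the MAP
#'   structural parameters, and the `eta` vector as a list column.
#' @export
empirical_bayes <- function(dataset, object, blq = "discard",
                            lloq = c(tegafur = 50, fu = 10)) {
  cfg <- .pop_config(object)
  subs_all <- .prep_subjects(dataset, blq, lloq, keep_empty = TRUE)
  bsv <- names(cfg$omega2)
  osd <- sqrt(pmax(cfg$omega2, 1e-10))
  rows <- lapply(subs_all, function(sub) {
    theta_g <- cfg$theta
    if (sub$group == 1) {
      theta_g[names(cfg$gamma)] <- theta_g[names(cfg$gamma)] + cfg$gamma
    }
    if (sub$n_obs == 0) {
      eta <- stats::setNames(rep(0, length(bsv)), bsv)
    } else {
      nll <- function(eta) {
        p <- .subject_params(theta_g, eta, bsv)
        -(.pred_loglik(.subject_pred(p, sub), sub, cfg$residual) +
            sum(stats::dnorm(eta, 0, osd, log = TRUE)))
      }
      opt <- stats::optim(rep(0, length(bsv)), nll, method = "BFGS",
                          control = list(reltol = 1e-8, maxit = 200))
      eta <- stats::setNames(opt$par, bsv)
    }
    p <- .subject_params(theta_g, eta, bsv)
    out <- tibble::as_tibble(p[.param_names])
    out$ID <- sub$id
    out$GROUP <- sub$group
    out$eta <- list(eta)
    out
  })
  res <- dplyr::bind_rows(rows)
  res[, c("ID", "GROUP", .param_names, "eta")]
}

# common population configuration from a pk_fit or population_model
.pop_config <- function(object) {
  if (inherits(object, "pk_fit")) {
    list(theta = .to_unconstrained(object$typical),
         gamma = log(object$group_mult),
         omega2 = object$omega2,
         residual = object$residual)
  } else if (inherits(object, "population_model")) {
    list(theta = .to_unconstrained(object$typical),
         gamma = log(object$group_mult),
         omega2 = object$omega2,
         residual = object$residual)
  } else {
    stop("object must be a pk_fit or population_model", call. = FALSE)
  }
}

#' Convert a fit back to a population model
#'
#' @param fit A `pk_fit`.
#' @return A [population_model()] with the fitted typical values, group
#'   multipliers, BSV and residual models, usable by [simulate_study()],
#'   [vpc()] and [npde()].
#' @export
as_population_model <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  population_model(
    typical = fit$typical,
    group_mult = fit$group_mult,
    bsv = fit$omega2,
    bsv_scale = "variance",
    residual = fit$residual
  )
}
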