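err_unit <- list(tegafur = residual_error(1, 0), fu = residual_error(1, 0))

test_that("log-likelihood has its closed form at a perfect fit", {
  p <- reference_params("control")
  t_obs <- c(1, 2, 4)
  pred <- simulate_profile(p, dose_event(0, 5), t_obs)
  obs <- tibble::tibble(time = rep(t_obs, 2),
                        analyte = rep(c("tegafur", "fu"), each = 3),
                        dv = c(pred$tegafur, pred$fu))
  ll <- individual_loglik(p, obs, err_unit, dose = 5)
  expect_equal(ll, -6 * 0.5 * log(2 * pi), tolerance = 1e-8)
})

test_that("log-likelihood matches a direct density computation", {
  p <- reference_params("control")
  t_obs <- c(0.5, 2, 8)
  pred <- simulate_profile(p, dose_event(0, 5), t_obs)$tegafur
  dv <- c(4000, 7000, 2500)
  obs <- tibble::tibble(time = t_obs, analyte = "tegafur", dv = dv)
  err <- list(tegafur = residual_error(50, 0.1))
  manual <- sum(dnorm(dv, pred, sqrt(50^2 + (0.1 * pred)^2), log = TRUE))
  expect_equal(individual_loglik(p, obs, err, dose = 5), manual,
               tolerance = 1e-8)
})

test_that("true parameters dominate perturbed ones on noise-free data", {
  p <- reference_params("control")
  t_obs <- c(0.5, 1, 2, 4, 8, 12)
  pred <- simulate_profile(p, dose_event(0, 5), t_obs)
  obs <- tibble::tibble(time = rep(t_obs, 2),
                        analyte = rep(c("tegafur", "fu"), each = 6),
                        dv = c(pred$tegafur, pred$fu))
  err <- list(tegafur = residual_error(25, 0.15), fu = residual_error(5, 0.15))
  ll_true <- individual_loglik(p, obs, err, dose = 5)
  worse <- unclass(p)
  worse$cl_teg <- 2 * worse$cl_teg
  worse$ka <- 2 * worse$ka
  ll_worse <- individual_loglik(do.call(structural_params, worse), obs, err, 5)
  expect_gt(ll_true, ll_worse)
})

test_that("IV route likelihood uses the 5-FU disposition subsystem", {
  p <- reference_params("control")
  t_obs <- c(0.1, 0.25, 0.5)
  pred <- s1pk:::.predict_iv_5fu(p, t_obs, 10)
  obs <- tibble::tibble(time = t_obs, analyte = "fu", dv = pred)
  ll <- individual_loglik(p, obs, err_unit, dose = 10, route = "iv_5fu")
  expect_equal(ll, -3 * 0.5 * log(2 * pi), tolerance = 1e-8)
  expect_error(individual_loglik(p, tibble::tibble(time = 1,
                                                   analyte = "tegafur",
                                                   dv = 1),
                                 err_unit, 10, route = "iv_5fu"), "5-FU")
})

test_that("fit spec validates its contract", {
  expect_error(fit_spec(n_mc = 50), "100")
  expect_error(fit_spec(group_params = "cld_teg",
                        bsv_params = c("ka", "cl_5fu")), "BSV")
})

test_that("EM is a fixed point at the truth on degenerate data", {
  # no BSV, essentially no noise: with the residual fixed, the estimates
  # must stay at the generating values
  pop <- degenerate_pop(add = 0.05)
  ds <- simulate_study(pop, design_11pt(4), seed = 17)
  truth <- reference_params("control")
  spec <- fit_spec(
    group_params = "ka",
    bsv_params = c("ka", "cl_teg", "cl_5fu"),
    init = list(typical = truth, group_mult = c(ka = 0.5),
                omega2 = c(ka = 1e-4, cl_teg = 1e-4, cl_5fu = 1e-4),
                residual = list(tegafur = residual_error(1, 0.001),
                                fu = residual_error(1, 0.001))),
    n_mc = 100, max_iter = 3, estimate_residual = FALSE, seed = 3
  )
  fit <- mcpem_fit(ds, spec)
  expect_equal(fit$typical$ka, truth$ka, tolerance = 0.02)
  expect_equal(fit$typical$cl_teg, truth$cl_teg, tolerance = 0.02)
  expect_equal(fit$typical$cl_5fu, truth$cl_5fu, tolerance = 0.02)
  expect_equal(unname(fit$group_mult["ka"]), 0.5, tolerance = 0.03)
})

test_that("likelihood trace is non-decreasing up to Monte-Carlo noise", {
  pop <- population_model(
    reference_params("control"),
    group_mult = c(ka = 0.7, cl_5fu = 1.5),
    bsv = c(ka = 0.05, cl_teg = 0.05, cl_5fu = 0.05)
  )
  ds <- simulate_study(pop, design_11pt(4), seed = 23)
  spec <- fit_spec(group_params = c("ka", "cl_5fu"),
                   bsv_params = c("ka", "cl_teg", "cl_5fu"),
                   n_mc = 100, max_iter = 8, seed = 5)
  fit <- mcpem_fit(ds, spec)
  steps <- diff(fit$ll_trace)
  expect_true(all(steps > -0.5))   # small MC wiggle allowed, no real descent
  expect_gt(sum(steps), 0)
})

test_that("a null group effect is recovered as a ratio near one", {
  pop <- population_model(
    reference_params("control"),
    group_mult = c(ka = 1, cl_5fu = 1),
    bsv = c(ka = 0.02, cl_teg = 0.02, cl_5fu = 0.05, v1_teg = 0.1)
  )
  ds <- simulate_study(pop, study_design(n_per_group = 8), seed = 19)
  fit <- mcpem_fit(ds, fit_spec(
    group_params = c("ka", "cl_5fu"),
    bsv_params = c("ka", "cl_teg", "cl_5fu", "v1_teg"),
    n_mc = 100, max_iter = 10, seed = 3
  ))
  expect_lt(abs(log(fit$group_mult[["ka"]])), log(1.15))
  expect_lt(abs(log(fit$group_mult[["cl_5fu"]])), log(1.2))
})

test_that("subject order does not change the fit", {
  pop <- population_model(
    reference_params("control"),
    bsv = c(ka = 0.05, cl_teg = 0.05)
  )
  ds <- simulate_study(pop, design_11pt(3), seed = 29)
  perm <- ds[order(-ds$ID, ds$TIME, ds$DVID), ]
  spec <- fit_spec(group_params = character(0), bsv_params = c("ka", "cl_teg"),
                   n_mc = 100, max_iter = 4, seed = 11)
  f1 <- mcpem_fit(ds, spec)
  f2 <- mcpem_fit(perm, spec)
  expect_equal(unlist(f1$typical), unlist(f2$typical), tolerance = 1e-10)
  expect_equal(f1$omega2, f2$omega2, tolerance = 1e-10)
})

test_that("empirical Bayes returns the prior mode without observations", {
  pop <- default_population_model()
  ds <- simulate_study(pop, design_11pt(1), seed = 41)
  # strip one subject's quantifiable observations (flag all BLQ)
  ds$BLQ[ds$ID == 2 & ds$EVID == 0] <- 1L
  eb <- empirical_bayes(ds, pop)
  typical_sdt <- draw_subject(population_model(pop$typical,
                                               group_mult = pop$group_mult), 1)
  expect_equal(eb$ka[eb$ID == 2], typical_sdt$ka)
  expect_equal(unname(unlist(eb$eta[eb$ID == 2])),
               rep(0, length(pop$omega2)))
})

test_that("empirical Bayes recovers subjects from dense noise-free data", {
  pop <- population_model(
    reference_params("control"),
    bsv = c(cl_teg = 0.1, v1_teg = 0.1),
    residual = list(tegafur = residual_error(0.5, 0.001),
                    fu = residual_error(0.5, 0.001))
  )
  dense_design <- study_design(n_per_group = 3,
                               times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4,
                                         6, 8, 10, 12, 16, 20, 24))
  ds <- simulate_study(pop, dense_design, seed = 53)
  truth <- attr(ds, "subject_params")
  eb <- empirical_bayes(ds, pop)
  for (i in seq_len(3)) {
    expect_equal(eb$cl_teg[eb$ID == i], truth[[i]]$cl_teg, tolerance = 0.02)
    expect_equal(eb$v1_teg[eb$ID == i], truth[[i]]$v1_teg, tolerance = 0.02)
  }
})

test_that("shrinkage toward the typical value grows with residual noise", {
  pop_gen <- population_model(
    reference_params("control"),
    bsv = c(cl_teg = 0.1),
    residual = list(tegafur = residual_error(20, 0.1),
                    fu = residual_error(4, 0.1))
  )
  ds <- simulate_study(pop_gen, design_11pt(5), seed = 61)
  # inflate the additive SD only: a wider symmetric density shrinks the MAP
  # eta toward the prior mode (a proportional SD also skews the MAP through
  # its 1/sigma dependence on the prediction, so it is kept fixed)
  mean_abs_eta <- vapply(c(1, 10, 100), function(mult) {
    pop_eval <- population_model(
      reference_params("control"),
      bsv = c(cl_teg = 0.1),
      residual = list(tegafur = residual_error(20 * mult, 0.1),
                      fu = residual_error(4 * mult, 0.1))
    )
    eb <- empirical_bayes(ds, pop_eval)
    mean(abs(vapply(eb$eta, `[[`, numeric(1), "cl_teg")))
  }, numeric(1))
  expect_true(all(diff(mean_abs_eta) < 0))
})
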