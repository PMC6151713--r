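ctl <- reference_params("control")
sched <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 8, 12, 24)

test_that("parameter and input validation rejects bad values", {
  expect_error(structural_params(ka = -1, ka_met = 0.1, k_conv = 1,
                                 cl_teg = 0.1, cld_teg = 0.1, f_met = 0.3,
                                 cl_5fu = 1, cld_5fu = 1, v1_teg = 0.1,
                                 v2_teg = 0.1, v1_5fu = 0.1, v2_5fu = 0.1),
               "strictly positive")
  bad <- unclass(ctl); bad$f_met <- 1.2
  expect_error(validate_structural_params(bad), "f_met")
  bad2 <- unclass(ctl); bad2$ka <- NaN
  expect_error(validate_structural_params(bad2), "finite")
  expect_error(simulate_profile(ctl, dose_event(0, 5), c(2, 1)),
               "strictly increasing")
  expect_error(simulate_profile(ctl, dose_event(0, 5), c(-1, 1)), ">= 0")
})

test_that("zero dose gives identically zero concentrations", {
  prof <- simulate_profile(ctl, dose_event(0, 0), sched)
  expect_equal(prof$tegafur, rep(0, length(sched)))
  expect_equal(prof$fu, rep(0, length(sched)))
})

test_that("doubling the dose exactly doubles every concentration", {
  p1 <- simulate_profile(ctl, dose_event(0, 5), sched)
  p2 <- simulate_profile(ctl, dose_event(0, 10), sched)
  expect_equal(p2$tegafur, 2 * p1$tegafur, tolerance = 1e-12)
  expect_equal(p2$fu, 2 * p1$fu, tolerance = 1e-12)
})

test_that("matrix-exponential and adaptive-ODE solutions agree", {
  doses <- rbind(dose_event(0, 5, "oral_teg"), dose_event(2, 10, "iv_5fu"))
  a <- simulate_profile(ctl, doses, sched, method = "matexp")
  b <- simulate_profile(ctl, doses, sched, method = "ode")
  expect_lt(max(abs(a$tegafur - b$tegafur) / pmax(a$tegafur, 1)), 1e-6)
  expect_lt(max(abs(a$fu - b$fu) / pmax(a$fu, 1)), 1e-6)
})

test_that("mass is conserved to 1e-6 of the dose", {
  # track cumulative eliminations alongside the six states
  A <- pk_rate_matrix(ctl)
  deriv <- function(t, x, parms) {
    dx <- as.vector(A %*% x[1:6])
    el_teg <- (1 - ctl$f_met) * ctl$cl_teg * x[2] / ctl$v1_teg
    el_fu <- ctl$cl_5fu * x[5] / ctl$v1_5fu
    list(c(dx, el_teg, el_fu))
  }
  sol <- deSolve::lsoda(c(5, rep(0, 7)), times = c(0, 0.5, 2, 8, 24, 96),
                        deriv, rtol = 1e-10, atol = 1e-12)
  balance <- rowSums(sol[, -1])
  expect_lt(max(abs(balance - 5)) / 5, 1e-6)
})

test_that("total 5-FU ever formed matches the closed-form dose fraction", {
  dense <- seq(0, 400, by = 0.02)
  st <- s1pk:::.simulate_states(ctl, dose_event(0, 5), dense)
  formed <- trapz(dense, ctl$k_conv * st[4, ])
  expect_equal(formed, 5 * fraction_converted(ctl), tolerance = 1e-4)
  # closed form: (ka_met + ka * f_met) / (ka + ka_met) of the dose
  expect_equal(fraction_converted(ctl),
               (ctl$ka_met + ctl$ka * ctl$f_met) / (ctl$ka + ctl$ka_met))
})

test_that("analytic AUC agrees with dense-grid trapezoid to 0.5%", {
  # ten terminal half-lives (~20 h each phase); grid dense enough for trapz
  dense <- seq(0, 200, by = 0.01)
  prof <- simulate_profile(ctl, dose_event(0, 5), dense)
  a <- analytic_auc(ctl, 5)
  expect_lt(abs(trapz(dense, prof$tegafur) - a$tegafur) / a$tegafur, 0.005)
  expect_lt(abs(trapz(dense, prof$fu) - a$fu) / a$fu, 0.005)
})

test_that("tegafur AUC is structurally independent of 5-FU parameters", {
  base <- analytic_auc(ctl, 5)$tegafur
  mod <- unclass(ctl)
  mod$k_conv <- 9; mod$cl_5fu <- 1; mod$cld_5fu <- 0.2
  mod$v1_5fu <- 2; mod$v2_5fu <- 3
  mod <- do.call(structural_params, mod)
  expect_equal(analytic_auc(mod, 5)$tegafur, base)
  dense <- seq(0, 100, 0.05)
  expect_equal(simulate_profile(mod, dose_event(0, 5), dense)$tegafur,
               simulate_profile(ctl, dose_event(0, 5), dense)$tegafur,
               tolerance = 1e-10)
})

test_that("no metabolite formation means zero 5-FU AUC", {
  mod <- unclass(ctl)
  mod$f_met <- 0
  mod$ka_met <- 1e-300  # rate constants must stay positive
  mod <- do.call(structural_params, mod)
  expect_equal(analytic_auc(mod, 5)$fu, 0, tolerance = 1e-290)
})

test_that("oral tegafur and 5-FU share the same terminal slope", {
  lam_teg <- terminal_slope(ctl, "tegafur")
  lam_fu <- terminal_slope(ctl, "fu")
  expect_equal(lam_teg, lam_fu, tolerance = 1e-12)
  # cross-check: log-linear regression on the simulated tail (window chosen
  # late enough that the next-slowest mode, 0.418/h, has fully decayed)
  tail_t <- seq(150, 250, by = 2)
  prof <- simulate_profile(ctl, dose_event(0, 5), tail_t)
  expect_equal(-unname(coef(lm(log(prof$tegafur) ~ tail_t))[2]), lam_teg,
               tolerance = 1e-4)
  expect_equal(-unname(coef(lm(log(prof$fu) ~ tail_t))[2]), lam_fu,
               tolerance = 1e-4)
})

test_that("gut exit governs the terminal slope when it is the slowest rate", {
  slow <- unclass(ctl)
  slow$ka <- 0.05; slow$ka_met <- 0.02  # gut exit 0.07/h, slower than disposition
  slow <- do.call(structural_params, slow)
  expect_equal(terminal_slope(slow, "tegafur"), 0.07, tolerance = 1e-10)
  expect_equal(terminal_slope(slow, "fu"), 0.07, tolerance = 1e-10)
})

test_that("one-compartment limit: slope is min of elimination and gut exit", {
  mod <- unclass(ctl)
  mod$cld_teg <- 1e-9
  mod <- do.call(structural_params, mod)
  k_el <- mod$cl_teg / mod$v1_teg
  k_gut <- mod$ka + mod$ka_met
  expect_equal(terminal_slope(mod, "tegafur"), min(k_el, k_gut),
               tolerance = 1e-4)
})

test_that("IV 5-FU terminal half-life comes from the disposition subsystem", {
  lam <- terminal_slope(ctl, "fu", route = "iv")
  # 2x2 eigenvalue formula computed directly
  k10 <- ctl$cl_5fu / ctl$v1_5fu
  k12 <- ctl$cld_5fu / ctl$v1_5fu
  k21 <- ctl$cld_5fu / ctl$v2_5fu
  beta <- ((k10 + k12 + k21) - sqrt((k10 + k12 + k21)^2 - 4 * k10 * k21)) / 2
  expect_equal(lam, beta, tolerance = 1e-12)
  expect_error(terminal_slope(ctl, "tegafur", route = "iv"), "5-FU")
})

test_that("IV doses enter the 5-FU central compartment", {
  prof <- simulate_profile(ctl, dose_event(0, 10, "iv_5fu"),
                           c(0.05, 0.25, 0.5, 1))
  expect_equal(prof$tegafur, rep(0, 4))
  expect_equal(prof$fu[1], s1pk:::.predict_iv_5fu(ctl, 0.05, 10),
               tolerance = 1e-10)
})
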