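sched <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 8, 12, 24)

test_that("lambda-z on exact monoexponential data recovers the rate", {
  t <- sched[sched > 0]
  conc <- 100 * exp(-0.3465 * t)
  lz <- select_lambda_z(t, conc)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 0.3465, tolerance = 1e-10)
  expect_equal(log(2) / lz$lambda_z, 2.000, tolerance = 1e-3)
  # ties in adjusted R^2 (here all subsets fit perfectly) go to more points
  expect_equal(lz$n_points, sum(t > t[which.max(conc)]))
})

test_that("lambda-z selection equals brute-force subset enumeration", {
  set.seed(42)
  for (rep in 1:25) {
    t <- sched[sched > 0]
    conc <- 800 * exp(-runif(1, 0.2, 0.6) * t) *
      (1 - exp(-runif(1, 1, 3) * t)) * exp(rnorm(length(t), 0, 0.15))
    lz <- select_lambda_z(t, conc)
    oracle <- brute_lambda_z(t, conc)
    if (is.null(oracle)) {
      expect_false(lz$estimable)
    } else {
      expect_equal(lz$lambda_z, oracle$lambda_z, tolerance = 1e-10)
      expect_equal(lz$n_points, oracle$n_points)
    }
  }
})

test_that("too few usable points is flagged, not an error", {
  lz <- select_lambda_z(c(1, 2), c(10, 5))
  expect_false(lz$estimable)
  expect_true(is.na(lz$lambda_z))
  res <- compute_nca(c(1, 2, 3), c(5, 10, 8), dose = 5)
  expect_false(res$estimable)
  expect_true(is.na(res$auc_inf) && is.na(res$cl_f) && is.na(res$vz_f))
  expect_equal(res$cmax, 10)  # Cmax/Tmax still read from the observations
})

test_that("triangle AUC and interpolation invariance hold", {
  res <- compute_nca(1, 100, dose = 5)
  expect_equal(res$auc_all, 50)  # (0,0) anchor to (1,100)
  # inserting a point on a straight segment leaves the linear trapezoid AUC unchanged
  t1 <- c(1, 2, 4, 8)
  c1 <- c(100, 80, 40, 10)
  t2 <- c(1, 2, 3, 4, 8)
  c2 <- c(100, 80, 60, 40, 10)
  expect_equal(compute_nca(t1, c1, 5)$auc_all, compute_nca(t2, c2, 5)$auc_all)
})

test_that("monoexponential AUCinf equals C0 over lambda", {
  t <- c(0.5, 1, 2, 4, 8, 12, 24)
  conc <- 200 * exp(-0.25 * t)
  res <- compute_nca(t, conc, dose = 5)
  # extrapolation uses observed Clast: AUCinf = AUCall + Clast/lambda; on
  # noise-free monoexponential data this is C0/lambda up to trapezoid error
  expect_equal(res$auc_inf, 200 / 0.25, tolerance = 0.02)
  expect_equal(res$t_half, log(2) / 0.25, tolerance = 1e-8)
  expect_gte(res$auc_inf, res$auc_all)
  expect_equal(res$extrap_frac, (res$auc_inf - res$auc_all) / res$auc_inf)
})

test_that("CL/F and Vz/F are unit-consistent with dose and AUC", {
  t <- c(0.5, 1, 2, 4, 8, 12, 24)
  res <- compute_nca(t, 200 * exp(-0.25 * t), dose = 5)
  # CL/F in mL/min/kg times AUCinf in ng.h/mL reproduces the dose in mg/kg
  expect_equal(res$cl_f * 60 / 1e6 * res$auc_inf, 5, tolerance = 1e-10)
  expect_equal(res$vz_f, res$cl_f * 60 / 1000 / res$lambda_z, tolerance = 1e-10)
})

test_that("BLQ handling: excluded after first quantifiable, predose as zero", {
  t <- c(0, 0.5, 1, 2, 4, 8, 12)
  conc <- c(0, 120, 200, 150, 80, 8, 4)
  blq <- c(1, 0, 0, 0, 0, 1, 1)
  res <- compute_nca(t, conc, dose = 5, blq = blq)
  expect_equal(res$auc_all,
               trapz(c(0, 0.5, 1, 2, 4), c(0, 120, 200, 150, 80)))
})

test_that("log-down trapezoid lies below linear on convex decline", {
  t <- c(1, 2, 4, 8, 12)
  conc <- 300 * exp(-0.4 * t)
  lin <- compute_nca(t, conc, 5, auc_method = "linear")$auc_all
  logd <- compute_nca(t, conc, 5, auc_method = "linear-log")$auc_all
  expect_lt(logd, lin)
  # exact for a pure exponential segment
  expect_equal(logd - trapz(c(0, 1), c(0, conc[1])),
               (conc[1] - conc[5]) / 0.4, tolerance = 1e-10)
})

test_that("noise-free typical profiles reproduce published NCA summaries", {
  ds <- simulate_study(degenerate_pop(), design_11pt(2), seed = 1)
  res <- nca_dataset(ds)
  teg <- res[res$analyte == "tegafur" & res$GROUP == 0, ][1, ]
  # published control tegafur terminal half-life: 2.2 +/- 1.4 h
  expect_gt(teg$t_half, 2.2 - 1.4)
  expect_lt(teg$t_half, 2.2 + 1.4)
  fu <- res[res$analyte == "fu" & res$GROUP == 0, ][1, ]
  expect_equal(fu$auc_inf, analytic_auc(reference_params("control"), 5)$fu,
               tolerance = 0.05)
})

test_that("every subject of a degenerate group gets identical NCA results", {
  ds <- simulate_study(degenerate_pop(), design_11pt(3), seed = 2)
  res <- nca_dataset(ds)
  ctl_teg <- res[res$analyte == "tegafur" & res$GROUP == 0, ]
  expect_equal(ctl_teg$auc_all, rep(ctl_teg$auc_all[1], 3), tolerance = 1e-9)
  expect_equal(ctl_teg$lambda_z, rep(ctl_teg$lambda_z[1], 3), tolerance = 1e-9)
})

test_that("pooled t-test matches its distributional definition", {
  x <- c(340, 300, 380, 360, 359)
  y <- c(150, 120, 160, 140, 141)
  res <- compare_groups(x, y)
  # independent route: pooled-variance statistic and t-density quadrature
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  df <- length(x) + length(y) - 2
  p_quad <- 2 * integrate(function(u) dt(u, df), lower = abs(tstat),
                          upper = Inf)$value
  expect_equal(res$p_value, p_quad, tolerance = 1e-6)
})

test_that("degenerate group comparisons are flagged", {
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  diff <- compare_groups(c(1, 1, 1), c(2, 2, 2))
  expect_equal(diff$p_value, 0)
  expect_true(diff$significant)
})

test_that("samples matching the published gimeracil Cmax summary separate", {
  # construct n = 5 samples with exactly the published mean and SD
  make <- function(m, s, n = 5) {
    z <- scale(seq_len(n))
    as.vector(m + s * z / sd(z))
  }
  ctl <- make(347.8, 42.7)
  sdt <- make(142.3, 41.8)
  expect_equal(c(mean(ctl), sd(ctl)), c(347.8, 42.7))
  res <- compare_groups(ctl, sdt)
  expect_true(res$significant)
})

test_that("group summary carries significance stars from the t-test", {
  ds <- simulate_study(default_population_model(), design_11pt(), seed = 31,
                       gimeracil = gimeracil_model())
  summ <- nca_summary(nca_dataset(ds))
  gim_cmax <- summ[summ$analyte == "gimeracil" & summ$parameter == "cmax", ]
  expect_lt(gim_cmax$p_value, 0.05)
  expect_match(gim_cmax$label, "\\*")
})
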