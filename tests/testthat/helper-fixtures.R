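# shared fixtures: small populations, designs and independent oracles

design_11pt <- function(n = 5) study_design(n_per_group = n)

# population with no BSV and near-zero residual noise (additive floor keeps
# the residual model valid); profiles are then the deterministic model output
degenerate_pop <- function(add = 1e-9) {
  population_model(
    typical = reference_params("control"),
    group_mult = c(ka = 0.5),
    bsv = numeric(0),
    residual = list(tegafur = residual_error(add, 0),
                    fu = residual_error(add, 0))
  )
}

# independent brute-force lambda-z oracle: enumerate every contiguous
# terminal subset of post-Tmax points and refit with lm()
brute_lambda_z <- function(time, conc) {
  keep <- conc > 0
  time <- time[keep]; conc <- conc[keep]
  i_max <- which.max(conc)
  time <- time[-seq_len(i_max)]; conc <- conc[-seq_len(i_max)]
  m <- length(time)
  if (m < 3) return(NULL)
  best <- NULL
  for (k in 3:m) {
    idx <- (m - k + 1):m
    fit <- stats::lm(log(conc[idx]) ~ time[idx])
    if (coef(fit)[2] >= 0) next
    adj <- summary(fit)$adj.r.squared
    if (is.null(best) || adj >= best$adj_r2 - 1e-12) {
      best <- list(lambda_z = -unname(coef(fit)[2]), n_points = k, adj_r2 = adj)
    }
  }
  best
}

# linear trapezoid, written independently of the package internals
trapz <- function(t, c) sum(diff(t) * (head(c, -1) + tail(c, -1)) / 2)
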