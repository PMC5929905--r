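# shared fixtures: quick constructors for summaries and series

make_summary <- function(rho_a, rho_b, var_ax = 1, var_ay = 1,
                         var_bx = 1, var_by = 1, dof = 200, n = 230) {
  two_state_summary(
    state_covariance(var_ax, var_ay, rho_a * sqrt(var_ax * var_ay), n,
                     dof_eff = dof, state_label = "A"),
    state_covariance(var_bx, var_by, rho_b * sqrt(var_bx * var_by), n,
                     dof_eff = dof, state_label = "B"))
}

# bivariate Gaussian series with given correlation
rho_series <- function(n, rho, state = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(2 * n), ncol = 2)
  x <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  colnames(x) <- c("x", "y")
  state_series(x, state_label = state)
}

ar1_series <- function(n, phi, k = 2, state = "A", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- vapply(seq_len(k), function(j) {
    if (abs(phi) < 1e-12) rnorm(n)
    else as.numeric(stats::arima.sim(list(ar = phi), n)) * sqrt(1 - phi^2)
  }, numeric(n))
  colnames(x) <- paste0("n", seq_len(k))
  state_series(x, state_label = state)
}

# direct Wishart-sampled covariance summaries (fast calibration fixtures)
wishart_summary_pair <- function(sigma_a, sigma_b, dof, n = dof + 1) {
  qa <- stats::rWishart(1, dof, sigma_a / dof)[, , 1]
  qb <- stats::rWishart(1, dof, sigma_b / dof)[, , 1]
  two_state_summary(
    state_covariance(qa[1, 1], qa[2, 2], qa[1, 2], n, dof_eff = dof,
                     state_label = "A"),
    state_covariance(qb[1, 1], qb[2, 2], qb[1, 2], n, dof_eff = dof,
                     state_label = "B"))
}
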