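#' Per-state covariance summary of a node pair
#'
#' Estimates the unbiased sample (co)variances of a demeaned node pair in one
#' state, together with the effective degrees of freedom of the estimate.
#' The variances and covariance are the empirical counterparts of the
#' underlying 2x2 covariance of the stationary node processes, and feed the
#' additive-signal bounds and the Monte-Carlo inference.
#'
#' @param series A [state_series()].
#' @param pair Character vector of two node labels present in `series`.
#' @param detrend If `TRUE`, remove a linear trend per channel before
#'   estimation (default only demeans).
#' @param dof_eff Optional effective degrees of freedom; when `NULL`
#'   (default) it is estimated with [estimate_effective_dof()].
#'
#' @return An object of class `state_cov`: list with `var_x`, `var_y`,
#'   `cov_xy`, `n_timepoints`, `dof_eff`, `pair`, `state_label`.
#' @seealso [correlation()], [two_state_summary()]
#' @export
estimate_state_covariance <- function(series, pair, detrend = FALSE,
                                      dof_eff = NULL) {
  stopifnot(inherits(series, "state_series"))
  pair <- as.character(pair)
  if (length(pair) != 2L)
    stop("'pair' must name exactly two nodes", call. = FALSE)
  missing_lab <- setdiff(pair, series$node_labels)
  if (length(missing_lab))
    stop("unknown node label(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  m <- series$values[, pair, drop = FALSE]
  if (nrow(m) < 3L)
    stop("need at least 3 time points to estimate a covariance",
         call. = FALSE)
  if (detrend) {
    t_idx <- seq_len(nrow(m))
    m <- apply(m, 2L, function(col) stats::residuals(stats::lm(col ~ t_idx)))
  } else {
    m <- sweep(m, 2L, colMeans(m))
  }
  v <- crossprod(m) / (nrow(m) - 1)
  if (any(diag(v) <= 0) || any(diag(v) < 1e-12 * max(diag(v))))
    stop("zero-variance channel in pair (", paste(pair, collapse = ", "),
         ")", call. = FALSE)
  if (is.null(dof_eff))
    dof_eff <- estimate_effective_dof(series, pair = pair)
  new_state_cov(var_x = v[1, 1], var_y = v[2, 2], cov_xy = v[1, 2],
                n_timepoints = nrow(m), dof_eff = dof_eff, pair = pair,
                state_label = series$state_label)
}

new_state_cov <- function(var_x, var_y, cov_xy, n_timepoints, dof_eff,
                          pair = c("x", "y"), state_label = "A") {
  if (var_x <= 0 || var_y <= 0)
    stop("variances must be positive", call. = FALSE)
  if (abs(cov_xy) > sqrt(var_x * var_y) * (1 + 1e-12))
    stop("|cov_xy| exceeds sqrt(var_x * var_y)", call. = FALSE)
  if (dof_eff < 2)
    stop("dof_eff must be at least 2", call. = FALSE)
  if (dof_eff > n_timepoints) dof_eff <- n_timepoints
  structure(
    list(var_x = var_x, var_y = var_y, cov_xy = cov_xy,
         n_timepoints = as.integer(n_timepoints), dof_eff = dof_eff,
         pair = as.character(pair), state_label = as.character(state_label)),
    class = "state_cov"
  )
}

#' Construct a covariance summary from known values
#'
#' Convenience constructor used when covariances are precomputed (or known by
#' design, as in simulation studies) rather than estimated from a series.
#'
#' @param var_x,var_y Positive variances of the two nodes.
#' @param cov_xy Covariance between the nodes.
#' @param n_timepoints Number of time points behind the estimate.
#' @param dof_eff Effective degrees of freedom (defaults to
#'   `n_timepoints - 1`).
#' @param pair Two node labels.
#' @param state_label State name.
#' @return A `state_cov` object.
#' @export
state_covariance <- function(var_x, var_y, cov_xy, n_timepoints,
                             dof_eff = n_timepoints - 1,
                             pair = c("x", "y"), state_label = "A") {
  new_state_cov(var_x, var_y, cov_xy, n_timepoints, dof_eff, pair,
                state_label)
}

#' @export
print.state_cov <- function(x, ...) {
  cat(sprintf(
    "state '%s' pair (%s, %s): var = (%.4g, %.4g), cov = %.4g, r = %.4f\n",
    x$state_label, x$pair[1], x$pair[2], x$var_x, x$var_y, x$cov_xy,
    correlation(x)))
  cat(sprintf("  n = %d time points, effective dof = %.1f\n",
              x$n_timepoints, x$dof_eff))
  invisible(x)
}

#' Pearson correlation of a covariance summary
#'
#' @param sc A `state_cov` object.
#' @return `cov_xy / sqrt(var_x * var_y)`, in \[-1, 1\].
#' @export
correlation <- function(sc) {
  stopifnot(inherits(sc, "state_cov"))
  r <- sc$cov_xy / sqrt(sc$var_x * sc$var_y)
  max(-1, min(1, r))
}

#' Effective degrees of freedom of autocorrelated channels
#'
#' Autocorrelation inflates the sampling variance of correlation estimates;
#' the effective dof is the equivalent number of independent samples. Each
#' channel gets an AR(p) fit (Yule-Walker, order by AIC, p <= 10); the
#' implied autocorrelation sequence rho_k gives a Bartlett-style inflation
#' factor `sum_k rho_k^2` and a per-channel dof `n / sum_k rho_k^2`. For a
#' pair of channels the harmonic mean of the two per-channel values is
#' returned; with more channels (no `pair`), the harmonic mean over all of
#' them. For white noise the factor is ~1 and the dof is ~n; for two AR(1)
#' channels with coefficient phi it approaches `n (1 - phi^2) / (1 + phi^2)`.
#'
#' @param series A [state_series()].
#' @param pair Optional two node labels; default uses all channels.
#' @param order_max Maximum AR order considered (default 10).
#' @return A positive scalar, at most `n_timepoints`. Below 30 time points a
#'   warning is raised and `n - 1` returned.
#' @export
estimate_effective_dof <- function(series, pair = NULL, order_max = 10) {
  stopifnot(inherits(series, "state_series"))
  m <- series$values
  if (!is.null(pair)) {
    pair <- as.character(pair)
    missing_lab <- setdiff(pair, series$node_labels)
    if (length(missing_lab))
      stop("unknown node label(s): ", paste(missing_lab, collapse = ", "),
           call. = FALSE)
    m <- m[, pair, drop = FALSE]
  }
  n <- nrow(m)
  if (n < 30) {
    warning("fewer than 30 time points: falling back to dof = n - 1")
    return(n - 1)
  }
  dof_ch <- apply(m, 2L, function(x) channel_dof(x, n, order_max))
  dof <- length(dof_ch) / sum(1 / dof_ch)  # harmonic mean
  min(dof, n)
}

channel_dof <- function(x, n, order_max) {
  fit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = min(order_max, n %/% 10),
              method = "yule-walker", demean = TRUE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("AR fit failed; falling back to dof = n - 1")
    return(n - 1)
  }
  if (fit$order == 0L) return(n)
  coefs <- fit$ar
  if (any(Mod(polyroot(c(1, -coefs))) <= 1 + 1e-8)) {
    warning("non-stationary AR fit; falling back to dof = n - 1")
    return(n - 1)
  }
  lag_max <- min(n - 1L, 500L)
  rho <- stats::ARMAacf(ar = coefs, lag.max = lag_max)[-1]
  infl <- 1 + 2 * sum(rho^2)
  max(2, min(n, n / infl))
}

#' Two-state covariance summary of a node pair
#'
#' Bundles the observed state-A and state-B covariance estimates of one node
#' pair; the central input to the additive-signal class tests.
#'
#' @param state_a,state_b `state_cov` objects for the same node pair.
#' @return An object of class `two_state_summary`.
#' @export
two_state_summary <- function(state_a, state_b) {
  stopifnot(inherits(state_a, "state_cov"), inherits(state_b, "state_cov"))
  if (!identical(state_a$pair, state_b$pair))
    stop("the two states must summarize the same node pair", call. = FALSE)
  structure(list(state_a = state_a, state_b = state_b,
                 pair_labels = state_a$pair),
            class = "two_state_summary")
}

#' @export
print.two_state_summary <- function(x, ...) {
  cat(sprintf("two-state summary, pair (%s, %s):\n",
              x$pair_labels[1], x$pair_labels[2]))
  print(x$state_a); print(x$state_b)
  invisible(x)
}

#' Flatten covariance summaries to a table
#'
#' @param ... `state_cov` objects (or one list of them).
#' @return Data frame with columns `node_x`, `node_y`, `state`, `var_x`,
#'   `var_y`, `cov_xy`, `n`, `dof_eff`.
#' @export
state_cov_table <- function(...) {
  scs <- list(...)
  if (length(scs) == 1L && !inherits(scs[[1]], "state_cov"))
    scs <- scs[[1]]
  do.call(rbind, lapply(scs, function(sc) {
    data.frame(node_x = sc$pair[1], node_y = sc$pair[2],
               state = sc$state_label, var_x = sc$var_x, var_y = sc$var_y,
               cov_xy = sc$cov_xy, n = sc$n_timepoints, dof_eff = sc$dof_eff,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild covariance summaries from a table
#'
#' Inverse of [state_cov_table()]; accepts a data frame or a CSV path.
#'
#' @param x Data frame or path to a CSV written from [state_cov_table()].
#' @return List of `state_cov` objects.
#' @export
read_state_cov_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    new_state_cov(row$var_x, row$var_y, row$cov_xy, row$n, row$dof_eff,
                  pair = c(row$node_x, row$node_y), state_label = row$state)
  })
}
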