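# Synthetic two-state data with controlled additive-signal structure.
#
# Node signals are zero-mean stationary Gaussian processes: per-node
# standardized AR series (white noise when no autocorrelation is requested)
# mixed through the Cholesky factor of the target covariance, which imposes
# the cross-sectional covariance exactly in expectation. State B applies
# the configured injections by forward construction of the added signals
# from the state-B base realization plus fresh latent processes.

#' Specify a two-state simulation scenario
#'
#' @param n_nodes Number of nodes.
#' @param n_timepoints Time points per state (default 230, a typical
#'   five-minute acquisition).
#' @param base_covariance N x N positive-definite covariance of the state-A
#'   (and pre-injection state-B) process.
#' @param autocorr Per-node AR(1) coefficients (recycled; `NULL` or 0 for
#'   white noise).
#' @param injections List of injections applied in state B. Each element is
#'   a list with fields `nodes` (labels or indices), `class` (one of
#'   `"common"`, `"uncorrelated"`, `"spec"`), `var_increase` (fractional
#'   variance increase per node; must exceed -1) and, for `class = "spec"`,
#'   a `spec` field holding an [additive_signal_spec()] for a node pair.
#' @param node_labels Node labels (default `node1..nodeN`).
#' @param seed Integer seed stored with the scenario.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_nodes, n_timepoints = 230, base_covariance,
                          autocorr = NULL, injections = list(),
                          node_labels = paste0("node", seq_len(n_nodes)),
                          seed = 1) {
  base_covariance <- as.matrix(base_covariance)
  if (!isTRUE(all.equal(dim(base_covariance), c(n_nodes, n_nodes))))
    stop("base_covariance must be ", n_nodes, " x ", n_nodes, call. = FALSE)
  ev <- eigen(base_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("base_covariance must be positive definite", call. = FALSE)
  if (is.null(autocorr)) autocorr <- 0
  autocorr <- rep_len(autocorr, n_nodes)
  if (any(abs(autocorr) >= 1))
    stop("AR(1) coefficients must lie in (-1, 1)", call. = FALSE)
  for (inj in injections) {
    if (!is.list(inj) || is.null(inj$nodes) || is.null(inj$class))
      stop("each injection needs 'nodes' and 'class' fields", call. = FALSE)
    if (!is.null(inj$var_increase) && any(inj$var_increase <= -1))
      stop("var_increase must exceed -1", call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 base_covariance = base_covariance,
                 autocorr = autocorr, injections = injections,
                 node_labels = node_labels, seed = as.integer(seed)),
            class = "scenario_spec")
}

# standardized (unit-variance) AR(1) series, one column per node
standardized_ar <- function(n, phi) {
  vapply(phi, function(p) {
    if (abs(p) < 1e-12) return(stats::rnorm(n))
    as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - p^2)), p,
                             method = "recursive",
                             init = stats::rnorm(1)))
  }, numeric(n))
}

#' Generate one state of a scenario
#'
#' State A draws the base process; state B draws an independent realization
#' of the base process and adds the configured injections, so the two
#' states are independent recordings of the pre- and post-change process.
#'
#' @param spec A [scenario_spec()].
#' @param state `"A"` or `"B"`.
#' @param seed Override of the scenario seed (the state label still selects
#'   an independent substream).
#' @return A [state_series()].
#' @export
generate_state <- function(spec, state = c("A", "B"), seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  state <- match.arg(state)
  set.seed(child_seed(seed, if (state == "A") 1L else 2L))
  n <- spec$n_timepoints
  z <- standardized_ar(n, spec$autocorr)
  x <- z %*% chol(spec$base_covariance)
  colnames(x) <- spec$node_labels
  if (state == "B") {
    for (inj in spec$injections) x <- apply_injection(x, inj, spec)
  }
  state_series(x, state_label = state)
}

apply_injection <- function(x, inj, spec) {
  idx <- if (is.character(inj$nodes)) match(inj$nodes, spec$node_labels)
         else as.integer(inj$nodes)
  if (anyNA(idx) || any(idx < 1 | idx > spec$n_nodes))
    stop("injection targets unknown node(s)", call. = FALSE)
  n <- nrow(x)
  base_var <- diag(spec$base_covariance)[idx]
  cls <- match.arg(inj$class, c("common", "uncorrelated", "spec"))
  if (cls == "common") {
    frac <- rep_len(inj$var_increase, length(idx))
    latent <- standardized_ar(n, mean(spec$autocorr[idx]))[, 1]
    for (k in seq_along(idx))
      x[, idx[k]] <- x[, idx[k]] + sqrt(frac[k] * base_var[k]) * latent
  } else if (cls == "uncorrelated") {
    frac <- rep_len(inj$var_increase, length(idx))
    for (k in seq_along(idx))
      x[, idx[k]] <- x[, idx[k]] +
        sqrt(frac[k] * base_var[k]) * standardized_ar(n, spec$autocorr[idx[k]])[, 1]
  } else {
    if (length(idx) != 2L)
      stop("'spec' injections apply to exactly one node pair", call. = FALSE)
    x <- add_spec_signals(x, idx, inj$spec, spec)
  }
  x
}

# Construct added signals for a node pair from an additive_signal_spec:
# population-standardized basis of the pair's base signals plus fresh
# orthogonal latent processes, mixed with the spec's correlation loadings.
add_spec_signals <- function(x, idx, sigspec, spec) {
  stopifnot(inherits(sigspec, "additive_signal_spec"))
  if (sigspec$direction_x != "added_in_B" ||
      sigspec$direction_y != "added_in_B")
    stop("the generator realizes additions in state B; use state relabeling",
         " for removals", call. = FALSE)
  n <- nrow(x)
  sig <- spec$base_covariance[idx, idx]
  sdv <- sqrt(diag(sig))
  rho <- sig[1, 2] / prod(sdv)
  s <- sqrt(1 - rho^2)
  z1 <- x[, idx[1]] / sdv[1]
  z2 <- (x[, idx[2]] / sdv[2] - rho * z1) / s
  e3 <- standardized_ar(n, mean(spec$autocorr[idx]))[, 1]
  e4 <- standardized_ar(n, mean(spec$autocorr[idx]))[, 1]
  u1 <- sigspec$rho_xa_xn
  u2 <- (sigspec$rho_ya_xn - rho * u1) / s
  u3 <- sqrt(max(0, 1 - u1^2 - u2^2))
  w1 <- sigspec$rho_xa_yn
  w2 <- (sigspec$rho_ya_yn - rho * w1) / s
  w3 <- if (u3 > 1e-9) (sigspec$rho_xn_yn - u1 * w1 - u2 * w2) / u3 else 0
  w4 <- sqrt(max(0, 1 - w1^2 - w2^2 - w3^2))
  xn <- sigspec$scale_xn * (u1 * z1 + u2 * z2 + u3 * e3)
  yn <- sigspec$scale_yn * (w1 * z1 + w2 * z2 + w3 * e3 + w4 * e4)
  x[, idx[1]] <- x[, idx[1]] + xn
  x[, idx[2]] <- x[, idx[2]] + yn
  x
}

#' Two-node validation scenario
#'
#' Two unit-variance nodes with correlation 0.58 by default; the variants
#' add signal raising both standard deviations by `sd_increase` (20% by
#' default): uncorrelated additions, or the common-signal / general
#' additive configuration minimizing or maximizing the state-B correlation.
#'
#' @param variant One of `"none"`, `"uncorrelated"`, `"common_min"`,
#'   `"common_max"`, `"additive_min"`, `"additive_max"`.
#' @param rho Initial correlation (default 0.58).
#' @param sd_increase Fractional SD increase in both nodes (default 0.2).
#' @param n_timepoints Time points per state (default 230).
#' @param autocorr AR(1) coefficient of the node signals (default 0).
#' @param seed Scenario seed.
#' @return A [scenario_spec()].
#' @export
two_node_scenario <- function(variant = c("none", "uncorrelated",
                                          "common_min", "common_max",
                                          "additive_min", "additive_max"),
                              rho = 0.58, sd_increase = 0.2,
                              n_timepoints = 230, autocorr = 0, seed = 1) {
  variant <- match.arg(variant)
  base <- matrix(c(1, rho, rho, 1), 2, 2)
  var_b <- (1 + sd_increase)^2
  inj <- switch(
    variant,
    none = list(),
    uncorrelated = list(list(nodes = 1:2, class = "uncorrelated",
                             var_increase = var_b - 1)),
    {
      bounds_fun <- if (startsWith(variant, "common")) common_signal_bounds
                    else additive_bounds
      iv <- bounds_fun(rho, 1, 1, var_b, var_b)
      sg <- if (endsWith(variant, "min")) iv$argmin_spec else iv$argmax_spec
      list(list(nodes = 1:2, class = "spec", spec = sg,
                var_increase = var_b - 1))
    })
  scenario_spec(2L, n_timepoints = n_timepoints, base_covariance = base,
                autocorr = autocorr, injections = inj,
                node_labels = c("x", "y"), seed = seed)
}

# Fixed initial correlations among nodes 1-6 of the network scenario
# (nodes 7-10 are uncorrelated with everything in state A). The strongest
# initial correlations are placed on injected-to-non-injected pairs so the
# decorrelation produced by the injection is detectable at moderate series
# lengths; all values lie in [0.3, 0.7].
NETWORK_SCENARIO_PAIRS <- rbind(
  c(1, 2, 0.45), c(1, 3, 0.40), c(2, 3, 0.50),
  c(1, 4, 0.65), c(2, 4, 0.35), c(3, 4, 0.45),
  c(1, 5, 0.40), c(2, 5, 0.68), c(3, 5, 0.35),
  c(1, 6, 0.35), c(2, 6, 0.40), c(3, 6, 0.70),
  c(4, 5, 0.45), c(4, 6, 0.40), c(5, 6, 0.45))

#' Ten-node network validation scenario
#'
#' Ten unit-variance nodes. Nodes 1-6 carry fixed pairwise initial
#' correlations between 0.3 and 0.7 (nearest-positive-definite repaired);
#' nodes 7-10 are uncorrelated. In state B one shared latent process,
#' orthogonal to all existing activity, is added to nodes 1-3, raising each
#' of their variances by 20%.
#'
#' @param n_timepoints Time points per state (default 230).
#' @param autocorr AR(1) coefficient of the node signals (default 0).
#' @param seed Scenario seed.
#' @return A [scenario_spec()].
#' @export
network_scenario <- function(n_timepoints = 230, autocorr = 0, seed = 1) {
  k <- 10L
  R <- diag(k)
  for (i in seq_len(nrow(NETWORK_SCENARIO_PAIRS))) {
    a <- NETWORK_SCENARIO_PAIRS[i, 1]; b <- NETWORK_SCENARIO_PAIRS[i, 2]
    R[a, b] <- R[b, a] <- NETWORK_SCENARIO_PAIRS[i, 3]
  }
  R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  scenario_spec(k, n_timepoints = n_timepoints, base_covariance = R,
                autocorr = autocorr,
                injections = list(list(nodes = 1:3, class = "common",
                                       var_increase = 0.2)),
                seed = seed)
}

#' Surrogate series matching a template's spectra and a target covariance
#'
#' Fits an AR(p) model (AIC order selection) to each template channel,
#' simulates fresh standardized series through those filters, and mixes
#' them with the Cholesky factor of the target covariance. Channel spectra
#' are exact when the template channels share similar AR structure (each
#' output channel is then a mixture of like-spectrum processes) and
#' approximate otherwise.
#'
#' @param template A [state_series()] with at least 100 time points.
#' @param target_cov Positive-definite covariance for the surrogate,
#'   dimension equal to the number of template channels.
#' @param seed Integer seed.
#' @return A [state_series()] with the template's size and labels.
#' @export
spectra_matched_surrogate <- function(template, target_cov, seed = 1) {
  stopifnot(inherits(template, "state_series"))
  n <- nrow(template$values)
  if (n < 100)
    stop("template needs at least 100 time points", call. = FALSE)
  k <- ncol(template$values)
  target_cov <- as.matrix(target_cov)
  if (!isTRUE(all.equal(dim(target_cov), c(k, k))))
    stop("target_cov dimension must match the template", call. = FALSE)
  ev <- eigen(target_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("target_cov must be positive definite", call. = FALSE)
  set.seed(seed)
  z <- vapply(seq_len(k), function(j) {
    fit <- stats::ar(template$values[, j], aic = TRUE,
                     order.max = min(10, n %/% 10),
                     method = "yule-walker")
    if (fit$order == 0L) return(stats::rnorm(n))
    as.numeric(stats::arima.sim(list(ar = fit$ar), n))
  }, numeric(n))
  # standardize channels so the Cholesky mixing hits the target covariance
  z <- scale(z, center = TRUE, scale = apply(z, 2, stats::sd))
  out <- z %*% chol(target_cov)
  colnames(out) <- template$node_labels
  state_series(out, state_label = paste0(template$state_label,
                                         "_surrogate"))
}

#' Write a scenario's two states and ground truth to a directory
#'
#' Writes `state_a.csv`, `state_b.csv` and `truth.json` (the generating
#' scenario: covariance, autocorrelation, injections, seed).
#'
#' @param spec A [scenario_spec()].
#' @param path Output directory.
#' @param seed Override of the scenario seed.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path, seed = spec$seed) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_state_series(generate_state(spec, "A", seed = seed),
                     file.path(path, "state_a.csv"))
  write_state_series(generate_state(spec, "B", seed = seed),
                     file.path(path, "state_b.csv"))
  truth <- list(
    n_nodes = spec$n_nodes, n_timepoints = spec$n_timepoints,
    node_labels = spec$node_labels,
    base_covariance = spec$base_covariance, autocorr = spec$autocorr,
    injections = lapply(spec$injections, function(inj) {
      inj$spec <- if (!is.null(inj$spec)) unclass(inj$spec) else NULL
      inj
    }),
    seed = seed)
  jsonlite::write_json(truth, file.path(path, "truth.json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
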