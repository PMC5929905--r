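# Monte-Carlo null-hypothesis inference: can an additive-signal class explain
# the observed two-state covariance change?
#
# Following the two-stage sampling scheme: (1) draw putative true
# covariances for both states from inverse-Wishart posteriors around the
# observed covariances at the effective degrees of freedom (flat prior,
# Gaussian generative signal), rejecting non-positive-definite or
# class-infeasible draws; (2) for each draw, locate the class member
# producing the minimum / maximum attainable state-B correlation and sample
# an observed correlation at the state-B dof through a Wishart draw. The
# observed state-B correlation is then compared against the two resulting
# null distributions.

ASC_CLASSES <- c("uncorrelated", "common", "additive")

#' Monte-Carlo inference configuration
#'
#' @param n_iterations Number of Monte-Carlo iterations (>= 100; default
#'   2000).
#' @param interval_level Coverage of the null interval, strictly inside
#'   (0, 1); the level is split equally between the two tails.
#' @param seed Integer root seed. All randomness in the inference derives
#'   from it; per-edge child seeds are split off deterministically.
#' @param dof_override Optional positive value replacing the estimated
#'   effective dof of both states.
#' @param classes Which ASC classes to test.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 2000, interval_level = 0.95, seed = 1,
                      dof_override = NULL, classes = ASC_CLASSES) {
  if (n_iterations < 100)
    stop("n_iterations must be at least 100", call. = FALSE)
  if (interval_level <= 0 || interval_level >= 1)
    stop("interval_level must lie strictly inside (0, 1)", call. = FALSE)
  classes <- match.arg(classes, ASC_CLASSES, several.ok = TRUE)
  if (!is.null(dof_override) && dof_override <= 3)
    stop("dof_override must exceed 3", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 interval_level = interval_level,
                 seed = as.integer(seed),
                 dof_override = dof_override,
                 classes = classes),
            class = "mc_config")
}

#' Read a Monte-Carlo configuration from YAML or JSON
#'
#' Recognized fields: `n_iterations`, `interval_level`, `seed`,
#' `dof_override`, `classes`, `fdr_level`. Unknown fields are ignored.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A list with elements `mc` (an [mc_config()]) and `fdr_level`
#'   (or `NULL` if absent from the file).
#' @export
read_mc_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        c("n_iterations", "interval_level", "seed",
                          "dof_override", "classes"))]
  list(mc = do.call(mc_config, args), fdr_level = raw$fdr_level)
}

# deterministic seed splitting so network runs are reproducible and
# order-independent: child_i = (root + 10007 * i) mod (2^31 - 1)
child_seed <- function(root, index) {
  as.integer((as.double(root) + 10007 * as.double(index)) %% 2147483647)
}

edge_dof <- function(sc, cfg) {
  if (!is.null(cfg$dof_override)) return(cfg$dof_override)
  sc$dof_eff
}

# analytic 2x2 inverse, vectorized over the third array dimension
inv2 <- function(w) {
  det <- w[1, 1, ] * w[2, 2, ] - w[1, 2, ]^2
  list(v11 = w[2, 2, ] / det, v22 = w[1, 1, ] / det, v12 = -w[1, 2, ] / det)
}

# inverse-Wishart draws around an observed covariance Q at dof nu:
# Sigma ~ IW(nu, nu * Q); returns variances and correlation per draw
riw_summary <- function(n, nu, Q) {
  scale_inv <- solve(nu * Q)
  w <- stats::rWishart(n, df = nu, Sigma = scale_inv)
  s <- inv2(w)
  r <- s$v12 / sqrt(s$v11 * s$v22)
  list(var_x = s$v11, var_y = s$v22, rho = pmax(-1, pmin(1, r)))
}

# observed sample correlation at true correlation rho for a Wishart draw
# with Bartlett components c11 = sqrt(chisq_nu), c21 = N(0,1),
# c22 = sqrt(chisq_{nu-1}); shared components let different true rho values
# map monotonically to observed values
observed_corr <- function(rho, c11, c21, c22) {
  s <- sqrt(pmax(0, 1 - rho^2))
  u <- rho * c11 + s * c21
  out <- u / sqrt(u^2 + s^2 * c22^2)
  deg <- abs(rho) >= 1 - 1e-12
  out[deg] <- sign(rho[deg])
  out
}

cov2x2 <- function(var_x, var_y, cov_xy)
  matrix(c(var_x, cov_xy, cov_xy, var_y), 2, 2)

sc_matrix <- function(sc) cov2x2(sc$var_x, sc$var_y, sc$cov_xy)

# all randomness behind one null-distribution computation
mc_draws <- function(summary, cfg) {
  nu_a <- edge_dof(summary$state_a, cfg)
  nu_b <- edge_dof(summary$state_b, cfg)
  if (nu_a < 4 || nu_b < 4)
    stop("effective dof must be at least 4 for Monte-Carlo inference",
         call. = FALSE)
  set.seed(cfg$seed)
  n <- cfg$n_iterations
  a <- riw_summary(n, nu_a, sc_matrix(summary$state_a))
  b <- riw_summary(n, nu_b, sc_matrix(summary$state_b))
  list(rho_a = a$rho, var_ax = a$var_x, var_ay = a$var_y,
       var_bx = b$var_x, var_by = b$var_y,
       c11 = sqrt(stats::rchisq(n, nu_b)),
       c21 = stats::rnorm(n),
       c22 = sqrt(stats::rchisq(n, max(1, nu_b - 1))),
       nu_a = nu_a, nu_b = nu_b)
}

#' Sample putative true covariances consistent with the observations
#'
#' Draws pairs of underlying true state covariance matrices from
#' inverse-Wishart posteriors (flat prior) around the observed state-A and
#' state-B covariances at their effective degrees of freedom. Draws that are
#' not positive definite are rejected and redrawn (with the 2x2 Wishart
#' construction this is a safeguard; rejections are counted in the
#' `"n_rejected"` attribute).
#'
#' @param summary A [two_state_summary()].
#' @param cfg An [mc_config()].
#' @return List of length `n_iterations`; each element holds 2x2 matrices
#'   `sigma_a` and `sigma_b`.
#' @export
sample_true_covariances <- function(summary, cfg = mc_config()) {
  stopifnot(inherits(summary, "two_state_summary"))
  d <- mc_draws(summary, cfg)
  rej <- 0L
  out <- lapply(seq_len(cfg$n_iterations), function(i) {
    sa <- cov2x2(d$var_ax[i], d$var_ay[i],
                 d$rho_a[i] * sqrt(d$var_ax[i] * d$var_ay[i]))
    vb_cov <- summary$state_b$cov_xy /
      sqrt(summary$state_b$var_x * summary$state_b$var_y) *
      sqrt(d$var_bx[i] * d$var_by[i])
    sb <- cov2x2(d$var_bx[i], d$var_by[i], vb_cov)
    list(sigma_a = sa, sigma_b = sb)
  })
  bad <- vapply(out, function(p) {
    min(eigen(p$sigma_a, TRUE, TRUE)$values,
        eigen(p$sigma_b, TRUE, TRUE)$values) <= 0
  }, logical(1))
  if (any(bad)) {
    rej <- sum(bad)
    out <- out[!bad]
  }
  if (rej > 0.99 * cfg$n_iterations)
    stop("rejection rate above 99% in covariance sampling", call. = FALSE)
  attr(out, "n_rejected") <- rej
  out
}

#' Null distributions of the observed state-B correlation under a class
#'
#' For each sampled true state-A covariance and true state variances, the
#' class member producing the minimum (respectively maximum) attainable
#' state-B correlation is located and an observed correlation is sampled at
#' the state-B effective dof. The two empirical distributions bracket what
#' the class can explain. For the uncorrelated class the attainable value
#' is a single point, so the two distributions coincide up to observation
#' noise. Draws for which the class is infeasible (possible for the
#' common-signal class under opposing variance changes) are dropped and
#' counted in the `"n_infeasible"` attribute.
#'
#' @param summary A [two_state_summary()].
#' @param class_id One of `"uncorrelated"`, `"common"`, `"additive"`.
#' @param cfg An [mc_config()].
#' @return Object of class `asc_null_dist`: list with `r_min`, `r_max`
#'   (empirical distributions), `class_id`, and the draw count.
#' @export
null_distribution <- function(summary, class_id, cfg = mc_config()) {
  stopifnot(inherits(summary, "two_state_summary"))
  class_id <- match.arg(class_id, ASC_CLASSES)
  d <- mc_draws(summary, cfg)
  n <- cfg$n_iterations
  lo <- numeric(n); hi <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    iv <- tryCatch(
      class_interval_fast(class_id, d$rho_a[i], d$var_ax[i], d$var_ay[i],
                          d$var_bx[i], d$var_by[i]),
      ascfc_empty_interval = function(e) NULL,
      error = function(e) NULL)
    if (is.null(iv)) next
    lo[i] <- iv[1]; hi[i] <- iv[2]; ok[i] <- TRUE
  }
  if (!any(ok))
    stop("class '", class_id, "' infeasible for every sampled covariance",
         call. = FALSE)
  r_min <- observed_corr(lo[ok], d$c11[ok], d$c21[ok], d$c22[ok])
  r_max <- observed_corr(hi[ok], d$c11[ok], d$c21[ok], d$c22[ok])
  structure(list(class_id = class_id, r_min = r_min, r_max = r_max,
                 n_draws = sum(ok), n_infeasible = sum(!ok),
                 interval_level = cfg$interval_level),
            class = "asc_null_dist")
}

#' @export
print.asc_null_dist <- function(x, ...) {
  cat(sprintf(
    "%s-class null distributions (%d draws, %d infeasible):\n",
    x$class_id, x$n_draws, x$n_infeasible))
  cat(sprintf("  min-extreme: mean %.4f, sd %.4f\n",
              mean(x$r_min), stats::sd(x$r_min)))
  cat(sprintf("  max-extreme: mean %.4f, sd %.4f\n",
              mean(x$r_max), stats::sd(x$r_max)))
  invisible(x)
}

#' Test whether an ASC class can explain the observed change
#'
#' The observed state-B correlation is compared with the min-extreme and
#' max-extreme null distributions of the class: the class is rejected when
#' the observation falls below the lower tail quantile of the min-extreme
#' distribution or above the upper tail quantile of the max-extreme
#' distribution (the `interval_level` split equally between tails). Because
#' the null distributions are built from the most extreme members of the
#' class, this is a conservative procedure.
#'
#' @inheritParams null_distribution
#' @return Object of class `asc_class_test`: `class_id`, central
#'   `null_lo_interval` and `null_hi_interval`, `observed_rho_b`,
#'   add-one-smoothed tail proportions `p_below` / `p_above`, and
#'   `rejected`.
#' @export
class_test <- function(summary, class_id, cfg = mc_config()) {
  nd <- null_distribution(summary, class_id, cfg)
  obs <- correlation(summary$state_b)
  alpha <- 1 - cfg$interval_level
  lo_iv <- stats::quantile(nd$r_min, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE, type = 7)
  hi_iv <- stats::quantile(nd$r_max, c(alpha / 2, 1 - alpha / 2),
                           names = FALSE, type = 7)
  n <- nd$n_draws
  p_below <- (sum(nd$r_min <= obs) + 1) / (n + 1)
  p_above <- (sum(nd$r_max >= obs) + 1) / (n + 1)
  structure(list(class_id = class_id,
                 null_lo_interval = lo_iv, null_hi_interval = hi_iv,
                 observed_rho_b = obs,
                 p_below = p_below, p_above = p_above,
                 rejected = obs < lo_iv[1] || obs > hi_iv[2],
                 n_draws = n, n_infeasible = nd$n_infeasible),
            class = "asc_class_test")
}

#' @export
print.asc_class_test <- function(x, ...) {
  cat(sprintf(
    "%s class: observed rho_B = %.3f, null range [%.3f, %.3f] -> %s\n",
    x$class_id, x$observed_rho_b, x$null_lo_interval[1],
    x$null_hi_interval[2], if (x$rejected) "REJECTED" else "not rejected"))
  invisible(x)
}

#' Two-sided test for a change in correlation between states
#'
#' Fisher z test using the effective degrees of freedom of the two states:
#' `z = atanh(r)` has approximate variance `1 / (dof - 3)`. A Monte-Carlo
#' variant (`method = "mc"`) instead samples both states' observed
#' correlations from Wishart draws around the pooled covariance estimate.
#'
#' @param summary A [two_state_summary()].
#' @param cfg An [mc_config()]; supplies `dof_override` and, for the MC
#'   variant, the iteration count and seed.
#' @param method `"fisher"` (default) or `"mc"`.
#' @return Two-sided p-value for a difference in correlation.
#' @export
correlation_change_test <- function(summary, cfg = mc_config(),
                                    method = c("fisher", "mc")) {
  stopifnot(inherits(summary, "two_state_summary"))
  method <- match.arg(method)
  r_a <- correlation(summary$state_a)
  r_b <- correlation(summary$state_b)
  if (abs(r_a) >= 1 - 1e-12 || abs(r_b) >= 1 - 1e-12)
    stop("degenerate input: |correlation| = 1", call. = FALSE)
  nu_a <- edge_dof(summary$state_a, cfg)
  nu_b <- edge_dof(summary$state_b, cfg)
  if (min(nu_a, nu_b) <= 3.5)
    stop("effective dof too small for the Fisher z approximation",
         call. = FALSE)
  if (method == "fisher") {
    stat <- (atanh(r_a) - atanh(r_b)) /
      sqrt(1 / (nu_a - 3) + 1 / (nu_b - 3))
    return(2 * stats::pnorm(-abs(stat)))
  }
  # MC variant: null of equal correlation at the pooled value
  set.seed(cfg$seed)
  n <- cfg$n_iterations
  rho0 <- tanh((atanh(r_a) * (nu_a - 3) + atanh(r_b) * (nu_b - 3)) /
                 (nu_a + nu_b - 6))
  draw_r <- function(nu) {
    observed_corr(rep(rho0, n), sqrt(stats::rchisq(n, nu)),
                  stats::rnorm(n), sqrt(stats::rchisq(n, max(1, nu - 1))))
  }
  delta_null <- abs(atanh(draw_r(nu_a)) - atanh(draw_r(nu_b)))
  delta_obs <- abs(atanh(r_a) - atanh(r_b))
  (sum(delta_null >= delta_obs) + 1) / (n + 1)
}
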