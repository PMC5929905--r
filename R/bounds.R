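# Deterministic bounds on the state-B correlation attainable under additive
# signal change (ASC) classes.
#
# Geometry used throughout: after orienting the problem so that the state-A
# correlation rho is non-negative (Y sign-flipped otherwise), the two state-A
# node signals define an orthonormal basis f1 = unit(XA), f2 with
# unit(YA) = g1 = rho f1 + s f2, s = sqrt(1 - rho^2). The added unit signals
# live in at most two further orthogonal dimensions: u (added to X) in
# span{f1, f2, f3}, w (added to Y) in span{f1, f2, f3, f4}. The variance
# equality of each node pins the projection of its added signal onto its own
# state-A signal, leaving the added-signal scales (n_x, n_y) and the free
# orientation angles as optimization variables. For fixed (n_x, n_y, u) the
# objective is linear in w's free direction, so that inner extremum is
# closed-form; what remains is a smooth box-constrained problem in at most
# three variables, solved by a dense grid plus quasi-Newton polish and
# verified in the test suite against an independent random-search oracle.

DIR_TOL <- 1e-10

node_geometry <- function(a, b) {
  D <- b^2 - a^2
  if (abs(D) < DIR_TOL * a^2)
    return(list(dir = 0L, eps = 0, nlo = 0, nhi = 0, D = 0))
  if (D > 0) list(dir = 1L, eps = 1, nlo = b - a, nhi = sqrt(D), D = D)
  else       list(dir = -1L, eps = -1, nlo = a - b, nhi = sqrt(-D), D = D)
}

# projection of the unit added signal onto the unit state-A signal, given
# the added-signal scale n (vectorized over n)
node_proj <- function(n, a, geom) {
  if (geom$dir == 0L) return(rep(0, length(n)))
  out <- numeric(length(n))
  pos <- n > 0
  if (geom$dir > 0L) out[pos] <- (geom$D - n[pos]^2) / (2 * a * n[pos])
  else out[pos] <- (-geom$D + n[pos]^2) / (2 * a * n[pos])
  pmin(1, pmax(0, out))
}

# inverse map: added-signal scale from projection
node_scale_from_proj <- function(p, a, geom) {
  if (geom$dir == 0L) return(rep(0, length(p)))
  if (geom$dir > 0L) -a * p + sqrt(a^2 * p^2 + geom$D)
  else a * p - sqrt(pmax(0, a^2 * p^2 + geom$D))  # D < 0; smaller root
}

# Objective pieces for the general additive class. The target state-B
# covariance equals base + wt1 * A + wt2 * B over the unit disc of w's free
# direction (wt1, wt2), so the inner extremum is base +/- sqrt(A^2 + B^2).
additive_cov_parts <- function(nx, ny, u2, rho, ax, ay, gx, gy) {
  s <- sqrt(1 - rho^2)
  px <- node_proj(nx, ax, gx)
  py <- node_proj(ny, ay, gy)
  ru <- sqrt(pmax(0, 1 - px^2))
  rw <- sqrt(pmax(0, 1 - py^2))
  u3 <- sqrt(pmax(0, 1 - u2^2))
  Ex <- gx$eps * ay * nx
  Ey <- gy$eps * ax * ny
  Exy <- gx$eps * gy$eps * nx * ny
  q <- rho * px + s * ru * u2            # <u, g1>
  base <- rho * ax * ay + Ex * q + Ey * rho * py + Exy * py * q
  A <- rw * (Ey * s + Exy * (s * px - rho * ru * u2))
  B <- rw * Exy * ru * u3
  list(base = base, A = A, B = B, px = px, py = py, ru = ru, rw = rw,
       u3 = u3)
}

additive_objective <- function(nx, ny, u2, rho, ax, ay, gx, gy, sign) {
  p <- additive_cov_parts(nx, ny, u2, rho, ax, ay, gx, gy)
  p$base + sign * sqrt(p$A^2 + p$B^2)
}

# One extremum (sign = +1 max, -1 min) of the general additive class.
# Returns the extremal covariance and the optimizer state needed to
# reconstruct the extremal signal specification.
optimize_additive <- function(rho, ax, ay, bx, by, sign, n_grid = 33,
                              polish = TRUE) {
  gx <- node_geometry(ax, bx)
  gy <- node_geometry(ay, by)
  free <- c(gx$dir != 0L, gy$dir != 0L, gx$dir != 0L)  # tx, ty, u2
  nx_of <- function(t) if (gx$dir == 0L) t * 0 else gx$nlo + t * (gx$nhi - gx$nlo)
  ny_of <- function(t) if (gy$dir == 0L) t * 0 else gy$nlo + t * (gy$nhi - gy$nlo)
  obj <- function(th)
    additive_objective(nx_of(th[[1]]), ny_of(th[[2]]), th[[3]],
                       rho, ax, ay, gx, gy, sign)
  tg <- seq(0, 1, length.out = n_grid)
  ug <- seq(-1, 1, length.out = n_grid)
  grid <- expand.grid(tx = if (free[1]) tg else 0,
                      ty = if (free[2]) tg else 0,
                      u2 = if (free[3]) ug else 0)
  vals <- obj(list(grid$tx, grid$ty, grid$u2))
  best <- if (sign > 0) which.max(vals) else which.min(vals)
  th <- c(grid$tx[best], grid$ty[best], grid$u2[best])
  val <- vals[best]
  if (polish && any(free)) {
    lower <- c(0, 0, -1)
    upper <- c(1, 1, 1)
    expand <- function(par) { z <- th; z[free] <- par; z }
    scalar_obj <- function(par) {
      z <- expand(par)
      -sign * obj(list(z[1], z[2], z[3]))
    }
    starts <- list(th[free])
    corner_axes <- lapply(which(free), function(i)
      c(lower[i] + 1e-7, upper[i] - 1e-7))
    corners <- as.matrix(do.call(expand.grid, corner_axes))
    for (i in seq_len(nrow(corners))) starts <- c(starts, list(corners[i, ]))
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(st, scalar_obj, method = "L-BFGS-B",
                     lower = lower[free], upper = upper[free],
                     control = list(factr = 1e4)),
        error = function(e) NULL)
      if (is.null(opt)) next
      cand <- -opt$value / sign  # scalar_obj = -sign * cov
      if (sign * cand > sign * val) {
        val <- cand
        th <- expand(opt$par)
      }
    }
  }
  nx <- nx_of(th[1]); ny <- ny_of(th[2])
  parts <- additive_cov_parts(nx, ny, th[3], rho, ax, ay, gx, gy)
  list(cov = val, nx = nx, ny = ny, u2 = th[3], parts = parts,
       gx = gx, gy = gy, sign = sign)
}

# Common-signal class: both nodes receive scaled copies of one latent unit
# process Nc. Both variance equalities then pin Nc's projections onto the
# two state-A signals, so the target covariance is a function of the two
# added-signal scales alone:
#   cov_B = rho ax ay + Ex * py + Ey * px + Exy
# subject to Nc being a valid unit vector: px^2 + ((py - rho px)/s)^2 <= 1.
# Parameterized by (px, t) where t in [0, 1] spans, for each px, the
# intersection of that disc constraint with the attainable py range; this
# makes the feasible set a box and the boundary (where the minimum often
# sits) exactly representable.
common_objective <- function(px, py, rho, ax, ay, gx, gy) {
  nx <- node_scale_from_proj(px, ax, gx)
  ny <- node_scale_from_proj(py, ay, gy)
  Ex <- gx$eps * ay * nx
  Ey <- gy$eps * ax * ny
  Exy <- gx$eps * gy$eps * nx * ny
  rho * ax * ay + Ex * py + Ey * px + Exy
}

common_py_window <- function(px, rho, s, py_range) {
  half <- s * sqrt(pmax(0, 1 - px^2))
  lo <- pmax(rho * px - half, py_range[1])
  hi <- pmin(rho * px + half, py_range[2])
  cbind(lo, hi)
}

optimize_common <- function(rho, ax, ay, bx, by, sign, n_grid = 61,
                            polish = TRUE) {
  gx <- node_geometry(ax, bx)
  gy <- node_geometry(ay, by)
  # a node without variance change contributes no common-signal amplitude;
  # the mutual-correlation constraint is then vacuous and the class
  # coincides with the general additive class restricted to the other node
  if (gx$dir == 0L || gy$dir == 0L)
    return(optimize_additive(rho, ax, ay, bx, by, sign,
                             n_grid = max(n_grid, 33), polish = polish))
  s <- sqrt(1 - rho^2)
  px_range <- sort(node_proj(c(gx$nlo, gx$nhi), ax, gx))
  py_range <- sort(node_proj(c(gy$nlo, gy$nhi), ay, gy))
  pxg <- seq(px_range[1], px_range[2], length.out = n_grid)
  win <- common_py_window(pxg, rho, s, py_range)
  ok <- win[, 1] <= win[, 2]
  if (!any(ok))
    stop(empty_interval_error(rho, ax, ay, bx, by))
  tg <- seq(0, 1, length.out = n_grid)
  px_m <- rep(pxg[ok], each = n_grid)
  lo_m <- rep(win[ok, 1], each = n_grid)
  hi_m <- rep(win[ok, 2], each = n_grid)
  py_m <- lo_m + rep(tg, sum(ok)) * (hi_m - lo_m)
  vals <- common_objective(px_m, py_m, rho, ax, ay, gx, gy)
  best <- if (sign > 0) which.max(vals) else which.min(vals)
  val <- vals[best]
  th <- c(px_m[best], (py_m[best] - lo_m[best]) /
            max(hi_m[best] - lo_m[best], 1e-300))
  if (polish) {
    scalar_obj <- function(par) {
      w <- common_py_window(par[1], rho, s, py_range)
      if (w[1] > w[2]) return(1e10)
      py <- w[1] + par[2] * (w[2] - w[1])
      -sign * common_objective(par[1], py, rho, ax, ay, gx, gy)
    }
    opt <- tryCatch(
      stats::optim(th, scalar_obj, method = "L-BFGS-B",
                   lower = c(px_range[1], 0), upper = c(px_range[2], 1),
                   control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e9) {
      cand <- -opt$value / sign
      if (sign * cand > sign * val) { val <- cand; th <- opt$par }
    }
  }
  px <- th[1]
  w <- common_py_window(px, rho, s, py_range)
  py <- w[1] + th[2] * (w[2] - w[1])
  nx <- node_scale_from_proj(px, ax, gx)
  ny <- node_scale_from_proj(py, ay, gy)
  nu2 <- (py - rho * px) / s
  nu3 <- sqrt(max(0, 1 - px^2 - nu2^2))
  list(cov = val, nx = nx, ny = ny, common = TRUE,
       nu = c(px, nu2, nu3, 0), px = px, py = py, gx = gx, gy = gy,
       sign = sign)
}

empty_interval_error <- function(rho, ax, ay, bx, by) {
  structure(
    class = c("ascfc_empty_interval", "error", "condition"),
    list(message = sprintf(
      paste0("common-signal class is infeasible for rho_A = %.3f with SD ",
             "changes (%.3f -> %.3f, %.3f -> %.3f)"), rho, ax, bx, ay, by),
      call = NULL))
}

# Build the f-basis coordinates of the added unit signals at an optimum.
extremal_vectors <- function(sol, rho) {
  s <- sqrt(1 - rho^2)
  if (isTRUE(sol$common)) {
    return(list(u = sol$nu, w = sol$nu))
  }
  p <- sol$parts
  u <- c(p$px, p$ru * sol$u2, p$ru * p$u3, 0)
  nrm <- sqrt(p$A^2 + p$B^2)
  if (nrm > 1e-14) wt <- sol$sign * c(p$A, p$B, 0) / nrm
  else wt <- c(0, 0, 1)
  g1 <- c(rho, s, 0, 0)
  g2p <- c(s, -rho, 0, 0)
  w <- p$py * g1 + p$rw * (wt[1] * g2p + wt[2] * c(0, 0, 1, 0) +
                             wt[3] * c(0, 0, 0, 1))
  list(u = u, w = w)
}

# Assemble an additive_signal_spec from an optimizer solution (computed in
# the rho >= 0 orientation; `flip` maps back when the original rho_A < 0).
spec_from_solution <- function(sol, rho, class_id, flip) {
  vec <- extremal_vectors(sol, rho)
  s <- sqrt(1 - rho^2)
  g1 <- c(rho, s, 0, 0)
  rho_ya_xn <- sum(vec$u * g1)
  rho_xa_yn <- vec$w[1]
  rho_ya_yn <- sum(vec$w * g1)
  rho_xn_yn <- if (class_id == "common" && isTRUE(sol$common)) 1
               else sum(vec$u * vec$w)
  if (sol$nx == 0 || sol$ny == 0)
    rho_xn_yn <- if (class_id == "common") 1 else 0
  spec <- additive_signal_spec(
    scale_xn = sol$nx, scale_yn = sol$ny,
    rho_xa_xn = if (sol$nx > 0) vec$u[1] else 0,
    rho_ya_yn = if (sol$ny > 0) rho_ya_yn else 0,
    rho_xa_yn = if (sol$ny > 0) rho_xa_yn else 0,
    rho_ya_xn = if (sol$nx > 0) rho_ya_xn else 0,
    rho_xn_yn = rho_xn_yn,
    direction_x = if (sol$gx$dir >= 0) "added_in_B" else "added_in_A",
    direction_y = if (sol$gy$dir >= 0) "added_in_B" else "added_in_A")
  if (flip) flip_spec(spec) else spec
}

flip_spec <- function(spec) {
  spec$rho_xa_yn <- -spec$rho_xa_yn
  spec$rho_ya_xn <- -spec$rho_ya_xn
  spec$rho_xn_yn <- -spec$rho_xn_yn
  spec
}

zero_spec <- function() {
  additive_signal_spec(0, 0, 0, 0, 0, 0, 0, "added_in_B", "added_in_B")
}

#' Parameterization of an additive signal change
#'
#' Describes the pair of signals added to the two nodes: their scales
#' (standard deviations), their correlations with the existing state-A
#' signals, their mutual correlation, and the state each addition occurs in
#' (`added_in_B` for a variance increase from A to B, `added_in_A` for a
#' decrease).
#'
#' @param scale_xn,scale_yn Non-negative standard deviations of the added
#'   signals.
#' @param rho_xa_xn,rho_ya_yn Correlation of each added signal with the
#'   existing signal in its own node.
#' @param rho_xa_yn,rho_ya_xn Cross-correlations with the other node's
#'   existing signal.
#' @param rho_xn_yn Mutual correlation of the two added signals (fixed at 1
#'   for the common-signal class).
#' @param direction_x,direction_y `"added_in_B"` or `"added_in_A"`.
#' @return An object of class `additive_signal_spec`.
#' @export
additive_signal_spec <- function(scale_xn, scale_yn, rho_xa_xn, rho_ya_yn,
                                 rho_xa_yn, rho_ya_xn, rho_xn_yn,
                                 direction_x = "added_in_B",
                                 direction_y = "added_in_B") {
  direction_x <- match.arg(direction_x, c("added_in_B", "added_in_A"))
  direction_y <- match.arg(direction_y, c("added_in_B", "added_in_A"))
  if (scale_xn < 0 || scale_yn < 0)
    stop("added-signal scales must be non-negative", call. = FALSE)
  rhos <- c(rho_xa_xn, rho_ya_yn, rho_xa_yn, rho_ya_xn, rho_xn_yn)
  if (any(abs(rhos) > 1 + 1e-9))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  structure(list(scale_xn = scale_xn, scale_yn = scale_yn,
                 rho_xa_xn = min(1, max(-1, rho_xa_xn)),
                 rho_ya_yn = min(1, max(-1, rho_ya_yn)),
                 rho_xa_yn = min(1, max(-1, rho_xa_yn)),
                 rho_ya_xn = min(1, max(-1, rho_ya_xn)),
                 rho_xn_yn = min(1, max(-1, rho_xn_yn)),
                 direction_x = direction_x, direction_y = direction_y),
            class = "additive_signal_spec")
}

#' @export
print.additive_signal_spec <- function(x, ...) {
  cat(sprintf("additive signal spec: scales (%.4g, %.4g), %s / %s\n",
              x$scale_xn, x$scale_yn, x$direction_x, x$direction_y))
  cat(sprintf("  rho(XA,XN)=%.3f rho(YA,YN)=%.3f rho(XA,YN)=%.3f\n",
              x$rho_xa_xn, x$rho_ya_yn, x$rho_xa_yn))
  cat(sprintf("  rho(YA,XN)=%.3f rho(XN,YN)=%.3f\n",
              x$rho_ya_xn, x$rho_xn_yn))
  invisible(x)
}

#' Is an additive change feasible given the variance change?
#'
#' An additive change in one direction requires the added variance not to
#' exceed the absolute change in total variance.
#'
#' @param var_a,var_b Positive variances in the two states.
#' @param var_n Non-negative variance of the putative added signal.
#' @return `TRUE` iff `var_n <= |var_b - var_a|` (to numerical tolerance).
#' @export
additive_direction_feasible <- function(var_a, var_b, var_n) {
  stopifnot(var_a > 0, var_b > 0, var_n >= 0)
  var_n <= abs(var_b - var_a) + 1e-12 * max(var_a, var_b)
}

#' State-B correlation implied by an additive signal specification
#'
#' Expands the state-B covariance as the state-A covariance plus the cross
#' terms contributed by the added signals, and divides by the implied
#' state-B standard deviations. Directions are honoured: an addition "in A"
#' subtracts the added signal when moving from A to B.
#'
#' @param rho_a State-A correlation.
#' @param var_ax,var_ay State-A variances.
#' @param spec An [additive_signal_spec()].
#' @return The implied state-B correlation.
#' @export
forward_correlation <- function(rho_a, var_ax, var_ay, spec) {
  stopifnot(inherits(spec, "additive_signal_spec"))
  if (abs(rho_a) > 1) stop("rho_a must lie in [-1, 1]", call. = FALSE)
  ax <- sqrt(var_ax); ay <- sqrt(var_ay)
  nx <- spec$scale_xn; ny <- spec$scale_yn
  sx <- if (spec$direction_x == "added_in_B") 1 else -1
  sy <- if (spec$direction_y == "added_in_B") 1 else -1
  validate_spec_psd(rho_a, spec)
  var_bx <- var_ax + nx^2 + 2 * sx * spec$rho_xa_xn * ax * nx
  var_by <- var_ay + ny^2 + 2 * sy * spec$rho_ya_yn * ay * ny
  if (var_bx <= 0 || var_by <= 0)
    stop("spec implies non-positive state-B variance", call. = FALSE)
  cov_b <- rho_a * ax * ay +
    sy * spec$rho_xa_yn * ax * ny +
    sx * spec$rho_ya_xn * ay * nx +
    sx * sy * spec$rho_xn_yn * nx * ny
  min(1, max(-1, cov_b / sqrt(var_bx * var_by)))
}

validate_spec_psd <- function(rho_a, spec) {
  idx <- c(spec$scale_xn > 0, spec$scale_yn > 0)
  R <- matrix(c(1, rho_a, spec$rho_xa_xn, spec$rho_xa_yn,
                rho_a, 1, spec$rho_ya_xn, spec$rho_ya_yn,
                spec$rho_xa_xn, spec$rho_ya_xn, 1, spec$rho_xn_yn,
                spec$rho_xa_yn, spec$rho_ya_yn, spec$rho_xn_yn, 1), 4, 4)
  keep <- c(TRUE, TRUE, idx)
  R <- R[keep, keep, drop = FALSE]
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stop("infeasible spec: implied correlation matrix is not positive ",
         "semi-definite (min eigenvalue ", signif(min(ev), 3), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Predicted state-B correlation under addition of uncorrelated signal
#'
#' When the signal added to each node is uncorrelated with the other node's
#' signals, the covariance between the nodes is unchanged and the state-B
#' correlation is fully determined by the variance changes:
#' `rho_B = rho_A / (sd_ratio_x * sd_ratio_y)`.
#'
#' @param rho_a State-A correlation.
#' @param sd_ratio_x,sd_ratio_y Positive ratios of state-B to state-A
#'   standard deviation in each node. A ratio below 1 means the uncorrelated
#'   signal was added in state A; the prediction is unchanged.
#' @return Predicted state-B correlation.
#' @examples
#' uncorrelated_predicted_correlation(0.58, 1.2, 1.2)  # 0.4028
#' @export
uncorrelated_predicted_correlation <- function(rho_a, sd_ratio_x,
                                               sd_ratio_y) {
  stopifnot(sd_ratio_x > 0, sd_ratio_y > 0, abs(rho_a) <= 1)
  rho_a / (sd_ratio_x * sd_ratio_y)
}

# shared front-end: orientation handling and degenerate-input checks
bounds_inputs <- function(rho_a, var_ax, var_ay, var_bx, var_by) {
  stopifnot(var_ax > 0, var_ay > 0, var_bx > 0, var_by > 0)
  if (abs(rho_a) > 1) stop("rho_a must lie in [-1, 1]", call. = FALSE)
  if (abs(rho_a) > 1 - 1e-12)
    stop("degenerate input: |rho_a| = 1", call. = FALSE)
  list(flip = rho_a < 0, rho = abs(rho_a),
       ax = sqrt(var_ax), ay = sqrt(var_ay),
       bx = sqrt(var_bx), by = sqrt(var_by))
}

make_interval <- function(class_id, lo_sol, hi_sol, inp, rho_a,
                          var_ax, var_ay, var_bx, var_by) {
  lo <- max(-1, min(1, lo_sol$cov / (inp$bx * inp$by)))
  hi <- max(-1, min(1, hi_sol$cov / (inp$bx * inp$by)))
  argmin <- spec_from_solution(lo_sol, inp$rho, class_id, inp$flip)
  argmax <- spec_from_solution(hi_sol, inp$rho, class_id, inp$flip)
  if (inp$flip) {
    tmp <- lo; lo <- -hi; hi <- -tmp
    tmp2 <- argmin; argmin <- argmax; argmax <- tmp2
  }
  structure(list(class_id = class_id, lo = lo, hi = hi,
                 argmin_spec = argmin, argmax_spec = argmax,
                 inputs = list(rho_a = rho_a, var_ax = var_ax,
                               var_ay = var_ay, var_bx = var_bx,
                               var_by = var_by)),
            class = "corr_interval")
}

#' @export
print.corr_interval <- function(x, ...) {
  cat(sprintf("%s class: attainable state-B correlation [%.4f, %.4f]\n",
              x$class_id, x$lo, x$hi))
  invisible(x)
}

#' Attainable correlation interval under a common-signal addition
#'
#' Minimum and maximum state-B correlation over all additions of one shared
#' latent process to both nodes (perfectly correlated added signals),
#' consistent with the observed variance changes. For negatively correlated
#' node pairs the common signal is taken with opposite signs in the two
#' nodes, so that it drives the correlation away from zero.
#'
#' @param rho_a State-A correlation.
#' @param var_ax,var_ay State-A variances.
#' @param var_bx,var_by State-B variances.
#' @param n_grid Grid resolution of the search (default 61).
#' @param polish Refine the grid optimum with quasi-Newton steps.
#' @return A `corr_interval` with `class_id = "common"`, endpoints `lo`,
#'   `hi`, and the extremal signal specifications.
#' @export
common_signal_bounds <- function(rho_a, var_ax, var_ay, var_bx, var_by,
                                 n_grid = 61, polish = TRUE) {
  inp <- bounds_inputs(rho_a, var_ax, var_ay, var_bx, var_by)
  lo_sol <- optimize_common(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, -1,
                            n_grid = n_grid, polish = polish)
  hi_sol <- optimize_common(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, 1,
                            n_grid = n_grid, polish = polish)
  make_interval("common", lo_sol, hi_sol, inp, rho_a, var_ax, var_ay,
                var_bx, var_by)
}

#' Attainable correlation interval under general additive signal change
#'
#' Minimum and maximum state-B correlation over all pairs of added signals
#' satisfying the additive-change constraints: each added signal is
#' non-negatively correlated with the existing signal of its own node in
#' the state it is added to, the added variance accounts exactly for the
#' observed variance change, and the joint correlation structure is
#' positive semi-definite. Contains the uncorrelated-addition point and the
#' common-signal interval.
#'
#' @inheritParams common_signal_bounds
#' @return A `corr_interval` with `class_id = "additive"`.
#' @export
additive_bounds <- function(rho_a, var_ax, var_ay, var_bx, var_by,
                            n_grid = 33, polish = TRUE) {
  inp <- bounds_inputs(rho_a, var_ax, var_ay, var_bx, var_by)
  lo_sol <- optimize_additive(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, -1,
                              n_grid = n_grid, polish = polish)
  hi_sol <- optimize_additive(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, 1,
                              n_grid = n_grid, polish = polish)
  make_interval("additive", lo_sol, hi_sol, inp, rho_a, var_ax, var_ay,
                var_bx, var_by)
}

#' Extremal signal specifications of a bounds interval
#'
#' @param interval A `corr_interval` from [common_signal_bounds()] or
#'   [additive_bounds()].
#' @return List with elements `argmin` and `argmax`, the
#'   [additive_signal_spec()]s whose forward evaluation reproduces the
#'   interval endpoints.
#' @export
extremal_specs <- function(interval) {
  stopifnot(inherits(interval, "corr_interval"))
  list(argmin = interval$argmin_spec, argmax = interval$argmax_spec)
}

# Fast interval computation used inside the Monte-Carlo loops: coarse grid,
# no polish, values only.
class_interval_fast <- function(class_id, rho_a, var_ax, var_ay, var_bx,
                                var_by) {
  if (class_id == "uncorrelated") {
    r <- rho_a * sqrt(var_ax * var_ay) / sqrt(var_bx * var_by)
    r <- max(-1, min(1, r))
    return(c(r, r))
  }
  inp <- bounds_inputs(rho_a, var_ax, var_ay, var_bx, var_by)
  optfun <- if (class_id == "common") optimize_common else optimize_additive
  ng <- if (class_id == "common") 25 else 15
  lo <- optfun(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, -1, n_grid = ng,
               polish = FALSE)$cov
  hi <- optfun(inp$rho, inp$ax, inp$ay, inp$bx, inp$by, 1, n_grid = ng,
               polish = FALSE)$cov
  out <- c(lo, hi) / (inp$bx * inp$by)
  out <- pmax(-1, pmin(1, out))
  if (inp$flip) out <- c(-out[2], -out[1])
  out
}
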