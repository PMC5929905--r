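test_that("additive-direction feasibility follows the variance-change bound", {
  expect_true(additive_direction_feasible(1.0, 1.44, 0.44))
  expect_false(additive_direction_feasible(1.0, 1.0, 0.01))
  expect_true(additive_direction_feasible(1.0, 0.5, 0.5))
})

test_that("forward correlation reproduces hand expansions", {
  # no added signal leaves the correlation unchanged
  none <- additive_signal_spec(0, 0, 0, 0, 0, 0, 0)
  expect_equal(forward_correlation(0.58, 1, 1, none), 0.58)

  # shared latent orthogonal to both existing signals, scaled for +20% SD:
  # cov gains the added variance 0.44, each variance becomes 1.44
  common_orth <- additive_signal_spec(
    scale_xn = sqrt(0.44), scale_yn = sqrt(0.44),
    rho_xa_xn = 0, rho_ya_yn = 0, rho_xa_yn = 0, rho_ya_xn = 0,
    rho_xn_yn = 1)
  expect_equal(forward_correlation(0.58, 1, 1, common_orth),
               (0.58 + 0.44) / 1.44, tolerance = 1e-12)

  # fully uncorrelated additions at +20% SD must equal the closed form
  unc <- additive_signal_spec(
    scale_xn = sqrt(0.44), scale_yn = sqrt(0.44),
    rho_xa_xn = 0, rho_ya_yn = 0, rho_xa_yn = 0, rho_ya_xn = 0,
    rho_xn_yn = 0)
  expect_equal(forward_correlation(0.58, 1, 1, unc),
               uncorrelated_predicted_correlation(0.58, 1.2, 1.2),
               tolerance = 1e-12)

  # an impossible joint correlation structure is rejected
  bad <- additive_signal_spec(1, 1, rho_xa_xn = 0.9, rho_ya_yn = 0.9,
                              rho_xa_yn = 0.9, rho_ya_xn = 0.9,
                              rho_xn_yn = -0.9)
  expect_error(forward_correlation(0.1, 1, 1, bad), "positive semi-definite")
})

test_that("uncorrelated-addition prediction matches arithmetic and
          simulation", {
  expect_equal(uncorrelated_predicted_correlation(0.58, 1.2, 1.2),
               0.58 / 1.44)
  expect_equal(round(uncorrelated_predicted_correlation(0.58, 1.2, 1.2), 2),
               0.40)
  expect_equal(uncorrelated_predicted_correlation(0.33, 1, 1), 0.33)

  # simulation oracle: add independent noise at 20% SD increase
  set.seed(31)
  n <- 200000
  z <- matrix(rnorm(2 * n), ncol = 2)
  x <- z[, 1]
  y <- 0.58 * z[, 1] + sqrt(1 - 0.58^2) * z[, 2]
  xb <- x + sqrt(0.44) * rnorm(n)
  yb <- y + sqrt(0.44) * rnorm(n)
  expect_lt(abs(cor(xb, yb) -
                  uncorrelated_predicted_correlation(0.58, 1.2, 1.2)),
            0.005)
})

test_that("zero variance change collapses every class to the initial
          correlation", {
  for (rho in c(-0.6, 0, 0.33)) {
    for (fn in list(common_signal_bounds, additive_bounds)) {
      iv <- fn(rho, 1, 1, 1, 1)
      expect_equal(iv$lo, rho, tolerance = 1e-9)
      expect_equal(iv$hi, rho, tolerance = 1e-9)
      specs <- extremal_specs(iv)
      expect_equal(specs$argmin$scale_xn, 0)
      expect_equal(specs$argmax$scale_yn, 0)
    }
  }
})

test_that("extremal specs reproduce the interval endpoints by forward
          evaluation", {
  set.seed(41)
  for (i in 1:12) {
    rho <- runif(1, -0.85, 0.85)
    vb <- runif(2, 0.7, 1.4)^2
    for (fn in list(common_signal_bounds, additive_bounds)) {
      iv <- tryCatch(fn(rho, 1, 1, vb[1], vb[2]),
                     ascfc_empty_interval = function(e) NULL)
      if (is.null(iv)) next
      expect_lte(iv$lo, iv$hi + 1e-9)
      expect_true(all(c(iv$lo, iv$hi) >= -1 & c(iv$lo, iv$hi) <= 1))
      expect_lt(abs(forward_correlation(rho, 1, 1, iv$argmin_spec) - iv$lo),
                1e-6)
      expect_lt(abs(forward_correlation(rho, 1, 1, iv$argmax_spec) - iv$hi),
                1e-6)
    }
  }
})

test_that("class nesting holds: additive contains the uncorrelated point
          and the common interval", {
  # The closed-form uncorrelated prediction is only a member of the
  # additive class when the uncorrelated configuration is geometrically
  # embeddable: a node whose variance *decreases* must shed signal whose
  # correlation with its own state-A signal is at least sqrt(|dvar|)/sd_A,
  # which precludes cross-uncorrelated removal once that exceeds
  # sqrt(1 - rho^2). Nesting is asserted where the member exists.
  unc_member_exists <- function(rho, r) {
    r >= 1 || sqrt(1 - r^2) <= sqrt(1 - rho^2)
  }
  set.seed(51)
  for (i in 1:25) {
    rho <- runif(1, -0.9, 0.9)
    rx <- runif(1, 0.7, 1.4); ry <- runif(1, 0.7, 1.4)
    add <- additive_bounds(rho, 1, 1, rx^2, ry^2)
    unc <- uncorrelated_predicted_correlation(rho, rx, ry)
    if (unc_member_exists(rho, rx) && unc_member_exists(rho, ry)) {
      expect_lte(add$lo, unc + 1e-6)
      expect_gte(add$hi, unc - 1e-6)
    }
    com <- tryCatch(common_signal_bounds(rho, 1, 1, rx^2, ry^2),
                    ascfc_empty_interval = function(e) NULL)
    if (!is.null(com)) {
      expect_lte(add$lo, com$lo + 1e-6)
      expect_gte(add$hi, com$hi - 1e-6)
    }
  }
})

test_that("enlarging the variance change never shrinks the additive
          interval", {
  for (rho in c(-0.5, 0.2, 0.6)) {
    sds <- c(1.05, 1.15, 1.25, 1.35)
    ivs <- lapply(sds, function(r) additive_bounds(rho, 1, 1, r^2, r^2))
    for (k in seq_len(length(ivs) - 1)) {
      expect_lte(ivs[[k + 1]]$lo, ivs[[k]]$lo + 1e-6)
      expect_gte(ivs[[k + 1]]$hi, ivs[[k]]$hi - 1e-6)
    }
  }
})

test_that("negating the initial correlation negates and swaps the interval", {
  set.seed(61)
  for (i in 1:8) {
    rho <- runif(1, 0.05, 0.85)
    rx <- runif(1, 0.75, 1.35); ry <- runif(1, 0.75, 1.35)
    for (fn in list(common_signal_bounds, additive_bounds)) {
      pos <- tryCatch(fn(rho, 1, 1, rx^2, ry^2),
                      ascfc_empty_interval = function(e) NULL)
      neg <- tryCatch(fn(-rho, 1, 1, rx^2, ry^2),
                      ascfc_empty_interval = function(e) NULL)
      if (is.null(pos)) { expect_null(neg); next }
      expect_equal(neg$lo, -pos$hi, tolerance = 1e-6)
      expect_equal(neg$hi, -pos$lo, tolerance = 1e-6)
    }
  }
})

test_that("the benchmark common-signal maximum dominates the orthogonal
          shared-latent construction", {
  iv <- common_signal_bounds(0.58, 1, 1, 1.44, 1.44)
  expect_gte(iv$hi, (0.58 + 0.44) / 1.44 - 1e-9)
  specs <- extremal_specs(iv)
  expect_equal(specs$argmin$rho_xn_yn, 1, tolerance = 1e-9)
  expect_equal(specs$argmax$rho_xn_yn, 1, tolerance = 1e-9)
})

test_that("optimized bounds match the independent random-search oracle", {
  set.seed(71)
  for (i in 1:6) {
    rho <- runif(1, -0.8, 0.8)
    rx <- runif(1, 0.75, 1.35); ry <- runif(1, 0.75, 1.35)
    add <- additive_bounds(rho, 1, 1, rx^2, ry^2)
    expect_lt(abs(add$lo - oracle_additive_extreme(rho, 1, 1, rx, ry,
                                                   "min")), 1e-3)
    expect_lt(abs(add$hi - oracle_additive_extreme(rho, 1, 1, rx, ry,
                                                   "max")), 1e-3)
  }
})

test_that("a common signal cannot always be removed from weakly correlated
          nodes", {
  expect_error(common_signal_bounds(0.05, 1, 1, 0.25, 0.25),
               class = "ascfc_empty_interval")
})

test_that("a single-node variance change makes the common and additive
          classes coincide", {
  com <- common_signal_bounds(0.4, 1, 1, 1.3, 1)
  add <- additive_bounds(0.4, 1, 1, 1.3, 1)
  expect_equal(com$lo, add$lo, tolerance = 1e-6)
  expect_equal(com$hi, add$hi, tolerance = 1e-6)
})
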