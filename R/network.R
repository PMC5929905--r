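# Network-level pipeline: per-edge change tests, FDR control, and four-way
# additive-signal classification of the significantly changing edges.

ASC_CATEGORIES <- c("uncorrelated", "common", "other_additive",
                    "non_additive")

#' Classify one edge from its per-class test results
#'
#' Applies the most-specific-first precedence: an edge is labelled
#' `uncorrelated` if the uncorrelated class is not rejected; otherwise
#' `common` if the common class is not rejected; otherwise `other_additive`
#' if the general additive class is not rejected; otherwise `non_additive`.
#' Edges falling inside a subclass are thereby excluded from the more
#' general classes. When both subclasses survive, a secondary annotation
#' records a sign heuristic (variance and absolute correlation moving
#' together suggests a common-signal change; moving oppositely suggests an
#' uncorrelated one) in the `"annotation"` attribute; the primary label
#' still follows the fixed precedence.
#'
#' @param results Named list with `asc_class_test` entries `uncorrelated`,
#'   `common` and `additive` for one edge.
#' @param delta_rho Observed change in correlation (B minus A).
#' @param delta_var Optional numeric of the two nodes' variance changes,
#'   used only for the annotation.
#' @return One of `"uncorrelated"`, `"common"`, `"other_additive"`,
#'   `"non_additive"`.
#' @export
classify_edge <- function(results, delta_rho, delta_var = NULL) {
  missing_cls <- setdiff(ASC_CLASSES, names(results))
  if (length(missing_cls))
    stop("missing class result(s): ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  rej <- vapply(results[ASC_CLASSES], function(r) isTRUE(r$rejected),
                logical(1))
  category <- if (!rej[["uncorrelated"]]) "uncorrelated"
  else if (!rej[["common"]]) "common"
  else if (!rej[["additive"]]) "other_additive"
  else "non_additive"
  if (!rej[["uncorrelated"]] && !rej[["common"]] && !is.null(delta_var)) {
    same_dir <- sign(mean(delta_var)) * sign(abs(
      results[["uncorrelated"]]$observed_rho_b) -
        abs(results[["uncorrelated"]]$observed_rho_b - delta_rho))
    attr(category, "annotation") <-
      if (isTRUE(same_dir > 0)) "common_like" else "uncorrelated_like"
  }
  category
}

#' Run the additive-signal-change analysis over a whole network
#'
#' For every unordered node pair: estimate the two states' covariance
#' summaries (with per-state, per-pair effective dof), test for a change in
#' correlation, control the false discovery rate across all pairs with the
#' Benjamini-Hochberg procedure, and classify each surviving edge by
#' Monte-Carlo class tests of the three additive-signal classes. Edges with
#' negligible correlation in both states (|r| < 0.05) and no significant
#' change are skipped from class testing.
#'
#' @param series_a,series_b [state_series()] objects sharing one node set.
#' @param cfg An [mc_config()]; each edge receives a deterministic child
#'   seed split from `cfg$seed` so results do not depend on edge order.
#' @param fdr_level FDR level for the Benjamini-Hochberg correction
#'   (default 0.2).
#' @param detrend Passed to [estimate_state_covariance()].
#' @return Object of class `asc_network`: node labels, per-node variance
#'   summaries for both states, an `edges` data frame (one row per pair,
#'   with correlations, variances, p- and q-values, category and per-class
#'   null intervals), the per-edge `class_results`, and the configuration.
#' @export
analyze_network <- function(series_a, series_b, cfg = mc_config(),
                            fdr_level = 0.2, detrend = FALSE) {
  stopifnot(inherits(series_a, "state_series"),
            inherits(series_b, "state_series"))
  if (!setequal(series_a$node_labels, series_b$node_labels))
    stop("the two states must share one node set", call. = FALSE)
  labels <- series_a$node_labels
  if (length(labels) < 2L) stop("need at least 2 nodes", call. = FALSE)
  pairs <- utils::combn(labels, 2L)
  n_edge <- ncol(pairs)

  summaries <- vector("list", n_edge)
  p_change <- numeric(n_edge)
  for (i in seq_len(n_edge)) {
    pr <- pairs[, i]
    sc_a <- estimate_state_covariance(series_a, pr, detrend = detrend)
    sc_b <- estimate_state_covariance(series_b, pr, detrend = detrend)
    summaries[[i]] <- two_state_summary(sc_a, sc_b)
    p_change[i] <- correlation_change_test(summaries[[i]], cfg)
  }
  q_value <- stats::p.adjust(p_change, method = "BH")
  significant <- q_value <= fdr_level

  class_results <- vector("list", n_edge)
  category <- rep(NA_character_, n_edge)
  annotation <- rep(NA_character_, n_edge)
  interval_cols <- matrix(NA_real_, n_edge, 6,
                          dimnames = list(NULL, c(
                            "unc_lo", "unc_hi", "com_lo", "com_hi",
                            "add_lo", "add_hi")))
  for (i in which(significant)) {
    sm <- summaries[[i]]
    r_a <- correlation(sm$state_a); r_b <- correlation(sm$state_b)
    ecfg <- cfg
    ecfg$seed <- child_seed(cfg$seed, i)
    res <- lapply(ASC_CLASSES, function(cl)
      tryCatch(class_test(sm, cl, ecfg),
               ascfc_empty_interval = function(e) infeasible_class_result(
                 cl, r_b, ecfg$interval_level),
               error = function(e) infeasible_class_result(
                 cl, r_b, ecfg$interval_level)))
    names(res) <- ASC_CLASSES
    class_results[[i]] <- res
    dv <- c(sm$state_b$var_x - sm$state_a$var_x,
            sm$state_b$var_y - sm$state_a$var_y)
    cat_i <- classify_edge(res, r_b - r_a, dv)
    category[i] <- as.character(cat_i)
    if (!is.null(attr(cat_i, "annotation")))
      annotation[i] <- attr(cat_i, "annotation")
    interval_cols[i, ] <- c(
      res$uncorrelated$null_lo_interval[1],
      res$uncorrelated$null_hi_interval[2],
      res$common$null_lo_interval[1], res$common$null_hi_interval[2],
      res$additive$null_lo_interval[1], res$additive$null_hi_interval[2])
  }

  edges <- data.frame(
    node_x = pairs[1, ], node_y = pairs[2, ],
    rho_a = vapply(summaries, function(s) correlation(s$state_a),
                   numeric(1)),
    rho_b = vapply(summaries, function(s) correlation(s$state_b),
                   numeric(1)),
    var_ax = vapply(summaries, function(s) s$state_a$var_x, numeric(1)),
    var_ay = vapply(summaries, function(s) s$state_a$var_y, numeric(1)),
    var_bx = vapply(summaries, function(s) s$state_b$var_x, numeric(1)),
    var_by = vapply(summaries, function(s) s$state_b$var_y, numeric(1)),
    dof_a = vapply(summaries, function(s) s$state_a$dof_eff, numeric(1)),
    dof_b = vapply(summaries, function(s) s$state_b$dof_eff, numeric(1)),
    p_change = p_change, q_value = q_value, significant = significant,
    category = category, annotation = annotation,
    stringsAsFactors = FALSE)
  edges$delta_rho <- edges$rho_b - edges$rho_a
  edges <- cbind(edges, as.data.frame(interval_cols))

  node_var <- function(series) {
    apply(series$values[, labels, drop = FALSE], 2L, stats::var)
  }
  structure(list(node_labels = labels,
                 node_variances = data.frame(
                   node = labels, var_a = node_var(series_a),
                   var_b = node_var(series_b), row.names = NULL,
                   stringsAsFactors = FALSE),
                 edges = edges, class_results = class_results,
                 fdr_level = fdr_level, cfg = cfg),
            class = "asc_network")
}

# a class that is infeasible for every sampled covariance cannot explain
# the observation: treated as rejected with an empty null interval
infeasible_class_result <- function(class_id, observed, level) {
  structure(list(class_id = class_id,
                 null_lo_interval = c(NA_real_, NA_real_),
                 null_hi_interval = c(NA_real_, NA_real_),
                 observed_rho_b = observed,
                 p_below = NA_real_, p_above = NA_real_,
                 rejected = TRUE, n_draws = 0L, n_infeasible = NA_integer_),
            class = "asc_class_test")
}

#' @export
print.asc_network <- function(x, ...) {
  n_sig <- sum(x$edges$significant)
  cat(sprintf("ASC network analysis: %d nodes, %d edges, %d significant ",
              length(x$node_labels), nrow(x$edges), n_sig))
  cat(sprintf("(BH-FDR %.2g)\n", x$fdr_level))
  if (n_sig > 0) {
    tab <- table(factor(x$edges$category[x$edges$significant],
                        levels = ASC_CATEGORIES))
    for (nm in names(tab))
      cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Export a network analysis to files
#'
#' Writes `edges.csv` (human-readable edge table), `results.json`
#' (full-precision round-trippable record) and `run.json` (configuration,
#' seed and software versions) into `path`.
#'
#' @param net An `asc_network` from [analyze_network()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_results <- function(net, path) {
  stopifnot(inherits(net, "asc_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(net$edges, file.path(path, "edges.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(node_labels = net$node_labels,
         node_variances = net$node_variances,
         edges = net$edges, fdr_level = net$fdr_level),
    file.path(path, "results.json"),
    digits = NA, auto_unbox = TRUE, na = "null")
  jsonlite::write_json(
    list(config = list(n_iterations = net$cfg$n_iterations,
                       interval_level = net$cfg$interval_level,
                       seed = net$cfg$seed,
                       dof_override = net$cfg$dof_override,
                       classes = net$cfg$classes),
         fdr_level = net$fdr_level,
         package_version = as.character(utils::packageVersion("ascfc")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(path, "run.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
  invisible(path)
}

#' Re-import an exported network analysis
#'
#' Reconstructs the numeric fields of an `asc_network` from the
#' `results.json` written by [export_results()] (the per-edge Monte-Carlo
#' draw objects are not stored).
#'
#' @param path Directory written by [export_results()].
#' @return List with `node_labels`, `node_variances`, `edges`,
#'   `fdr_level` and the run metadata.
#' @export
read_network_results <- function(path) {
  res <- jsonlite::fromJSON(file.path(path, "results.json"),
                            simplifyVector = TRUE)
  run <- jsonlite::fromJSON(file.path(path, "run.json"),
                            simplifyVector = TRUE)
  res$edges <- as.data.frame(res$edges, stringsAsFactors = FALSE)
  res$node_variances <- as.data.frame(res$node_variances,
                                      stringsAsFactors = FALSE)
  res$run <- run
  res
}

#' Plot the four-way edge classification of a network analysis
#'
#' Simple circular layout: nodes on a circle (fill shaded by variance
#' change), significant edges drawn in one panel per ASC category, red for
#' increased and blue for decreased correlation.
#'
#' @param x An `asc_network`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.asc_network <- function(x, ...) {
  labels <- x$node_labels
  k <- length(labels)
  theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  xs <- cos(theta); ys <- sin(theta)
  dv <- x$node_variances$var_b - x$node_variances$var_a
  node_col <- ifelse(dv > 0, "tomato", "steelblue")
  old <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  for (cat_id in ASC_CATEGORIES) {
    graphics::plot(xs, ys, pch = 21, bg = node_col, cex = 2, axes = FALSE,
                   xlab = "", ylab = "", main = cat_id,
                   xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1)
    graphics::text(1.18 * xs, 1.18 * ys, labels, cex = 0.7)
    sel <- which(x$edges$significant & x$edges$category == cat_id)
    for (i in sel) {
      a <- match(x$edges$node_x[i], labels)
      b <- match(x$edges$node_y[i], labels)
      graphics::segments(xs[a], ys[a], xs[b], ys[b],
                         col = if (x$edges$delta_rho[i] > 0) "red"
                               else "blue", lwd = 2)
    }
  }
  invisible(x)
}
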