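fake_test_result <- function(class_id, rejected) {
  structure(list(class_id = class_id,
                 null_lo_interval = c(0, 0.1), null_hi_interval = c(0.5, 0.6),
                 observed_rho_b = 0.3, p_below = 0.5, p_above = 0.5,
                 rejected = rejected, n_draws = 100L, n_infeasible = 0L),
            class = "asc_class_test")
}

make_results <- function(unc, com, add) {
  list(uncorrelated = fake_test_result("uncorrelated", unc),
       common = fake_test_result("common", com),
       additive = fake_test_result("additive", add))
}

test_that("edge classification follows most-specific-first precedence", {
  expect_equal(as.character(classify_edge(make_results(FALSE, FALSE, FALSE),
                                          0.1)), "uncorrelated")
  expect_equal(as.character(classify_edge(make_results(TRUE, FALSE, FALSE),
                                          0.1)), "common")
  expect_equal(as.character(classify_edge(make_results(TRUE, TRUE, FALSE),
                                          0.1)), "other_additive")
  expect_equal(as.character(classify_edge(make_results(TRUE, TRUE, TRUE),
                                          0.1)), "non_additive")
  expect_error(classify_edge(make_results(TRUE, TRUE, TRUE)[-2], 0.1),
               "missing class")
})

test_that("a two-node network without change yields no significant edges", {
  # "no change" in the trivial sense: state B records the same process
  # realization, so the change test is exactly null (p = 1)
  a <- rho_series(300, 0.4, "A", seed = 81)
  b <- state_series(a$values, state_label = "B")
  net <- analyze_network(a, b, mc_config(n_iterations = 100, seed = 1))
  expect_equal(sum(net$edges$significant), 0)
  expect_true(all(is.na(net$edges$category)))
})

test_that("mismatched node sets are rejected", {
  a <- rho_series(100, 0.4, "A", seed = 83)
  b <- rho_series(100, 0.4, "B", seed = 84)
  b$node_labels <- c("x", "zz"); colnames(b$values) <- b$node_labels
  expect_error(analyze_network(a, b), "share one node set")
})

test_that("results are invariant to node order up to relabeling", {
  set.seed(85)
  sp <- network_scenario(n_timepoints = 400, seed = 44)
  a <- generate_state(sp, "A"); b <- generate_state(sp, "B")
  keep <- c("node1", "node2", "node4")
  sub <- function(s, ord) state_series(s$values[, ord],
                                       state_label = s$state_label)
  cfg <- mc_config(n_iterations = 150, seed = 3)
  n1 <- analyze_network(sub(a, keep), sub(b, keep), cfg)
  n2 <- analyze_network(sub(a, rev(keep)), sub(b, rev(keep)), cfg)
  key <- function(net) {
    e <- net$edges
    lab <- ifelse(e$node_x < e$node_y, paste(e$node_x, e$node_y),
                  paste(e$node_y, e$node_x))
    e <- e[order(lab), ]
    list(lab = sort(lab), p = e$p_change, sig = e$significant,
         cat = e$category)
  }
  expect_equal(key(n1), key(n2), tolerance = 1e-12)
})

test_that("exported results round-trip and categories partition the
          significant edges", {
  sp <- network_scenario(n_timepoints = 1200, seed = 46)
  a <- generate_state(sp, "A"); b <- generate_state(sp, "B")
  net <- analyze_network(a, b, mc_config(n_iterations = 150, seed = 5))
  out <- file.path(tempdir(), "ascnet")
  export_results(net, out)
  expect_true(file.exists(file.path(out, "edges.csv")))
  expect_true(file.exists(file.path(out, "run.json")))
  back <- read_network_results(out)
  expect_equal(back$edges$p_change, net$edges$p_change, tolerance = 1e-15)
  expect_equal(back$edges$rho_a, net$edges$rho_a, tolerance = 1e-15)
  expect_identical(back$edges$category[net$edges$significant],
                   net$edges$category[net$edges$significant])
  expect_equal(back$run$config$seed, 5)

  sig <- net$edges[net$edges$significant, ]
  expect_false(anyNA(sig$category))
  expect_true(all(sig$category %in% c("uncorrelated", "common",
                                      "other_additive", "non_additive")))
  expect_true(all(is.na(net$edges$category[!net$edges$significant])))
})

test_that("an empty significant set still writes a well-formed edge table", {
  a <- rho_series(200, 0.3, "A", seed = 87)
  b <- state_series(rho_series(200, 0.3, "A", seed = 87)$values,
                    state_label = "B")
  net <- analyze_network(a, b, mc_config(n_iterations = 100, seed = 2))
  out <- file.path(tempdir(), "ascnet_empty")
  export_results(net, out)
  tab <- utils::read.csv(file.path(out, "edges.csv"))
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("node_x", "node_y", "p_change", "q_value",
                    "category") %in% names(tab)))
  expect_true(all(is.na(tab$category)))
})

test_that("the command-line interface prints bounds and runs the
          simulate/analyze pipeline end to end", {
  out <- capture.output(status <- asc_cli(c("bounds", "--rho", "0.58",
                                            "--sdx", "1.2",
                                            "--sdy", "1.2")))
  expect_identical(status, 0L)
  expect_true(any(grepl("0.40", out, fixed = TRUE)))
  expect_true(any(grepl("common-signal class", out)))

  simdir <- file.path(tempdir(), "asc_sim")
  resdir <- file.path(tempdir(), "asc_res")
  expect_identical(suppressMessages(asc_cli(c(
    "simulate", "--scenario", "two_node", "--variant", "common_max",
    "--timepoints", "400", "--seed", "3", "--out", simdir))), 0L)
  expect_true(file.exists(file.path(simdir, "state_a.csv")))
  expect_true(file.exists(file.path(simdir, "truth.json")))
  invisible(suppressMessages(capture.output(status2 <- asc_cli(c(
    "analyze", "--state-a", file.path(simdir, "state_a.csv"),
    "--state-b", file.path(simdir, "state_b.csv"),
    "--iterations", "150", "--seed", "4", "--out", resdir)))))
  expect_identical(status2, 0L)
  expect_true(file.exists(file.path(resdir, "edges.csv")))

  # identical invocation reproduces identical result files
  resdir2 <- file.path(tempdir(), "asc_res2")
  invisible(suppressMessages(capture.output(asc_cli(c(
    "analyze", "--state-a", file.path(simdir, "state_a.csv"),
    "--state-b", file.path(simdir, "state_b.csv"),
    "--iterations", "150", "--seed", "4", "--out", resdir2)))))
  expect_identical(readLines(file.path(resdir, "edges.csv")),
                   readLines(file.path(resdir2, "edges.csv")))

  expect_identical(asc_cli(c("bounds")), 1L)  # missing --rho
  expect_identical(asc_cli(c("nosuch")), 1L)
})
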