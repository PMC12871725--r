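make_cells <- function(types_a, types_b, cond_a = "Control", cond_b = "DPN") {
  data.frame(condition = rep(c(cond_a, cond_b), c(length(types_a), length(types_b))),
             cell_type = c(types_a, types_b), stringsAsFactors = FALSE)
}

test_that("proportion estimates follow the epsilon-guarded log2FD", {
  cells <- make_cells(rep(c("T", "other"), c(30, 70)),
                      rep(c("T", "other"), c(60, 40)))
  est <- proportion_estimates(cells, "Control", "DPN", "cell_type")
  row <- est[est$cell_type == "T", ]
  expect_equal(row$prop_a, 0.3)
  expect_equal(row$prop_b, 0.6)
  expect_lt(abs(row$obs_log2FD - 1), 0.02)

  # equal proportions -> exactly 0
  eq <- proportion_estimates(make_cells(rep("T", 50), rep("T", 50)),
                             "Control", "DPN", "cell_type")
  expect_equal(eq$obs_log2FD, 0)

  # type absent in one condition stays finite
  ab <- proportion_estimates(make_cells(rep("other", 50),
                                        rep(c("T", "other"), c(10, 40))),
                             "Control", "DPN", "cell_type")
  expect_true(is.finite(ab$obs_log2FD[ab$cell_type == "T"]))
  expect_gt(ab$obs_log2FD[ab$cell_type == "T"], 0)

  expect_error(proportion_estimates(cells, "Control", "DPN", "nope"),
               "cluster_field")
})

test_that("permutation p-values match exhaustive enumeration on small instances", {
  set.seed(71)
  for (rep_i in 1:4) {
    types <- sample(c("A", "B", "C"), 12, TRUE)
    in_b <- rep(c(FALSE, TRUE), each = 6)
    cells <- data.frame(condition = ifelse(in_b, "DPN", "Control"),
                        cell_type = types)
    exact <- oracle_exact_prop_p(types, in_b)
    mc <- permutation_test(cells, "Control", "DPN", "cell_type",
                           n_perm = 8000, seed = rep_i)
    expect_lt(max(abs(mc$p_perm - exact)), 0.02)
  }
})

test_that("self-comparison is null and the add-one estimator never gives 0", {
  set.seed(72)
  types <- sample(c("A", "B"), 40, TRUE)
  cells <- data.frame(condition = rep(c("Control", "DPN"), each = 40),
                      cell_type = rep(types, 2))
  r <- permutation_test(cells, "Control", "DPN", "cell_type", n_perm = 500,
                        seed = 1)
  expect_true(all(r$p_perm > 0.5))
  expect_true(all(r$p_perm > 0))
  expect_warning(permutation_test(cells, "Control", "DPN", "cell_type",
                                  n_perm = 50, seed = 1), "resolution")
})

test_that("swapping conditions negates the observed log2FD", {
  set.seed(73)
  cells <- make_cells(sample(c("A", "B", "C"), 200, TRUE, c(0.5, 0.3, 0.2)),
                      sample(c("A", "B", "C"), 150, TRUE, c(0.2, 0.5, 0.3)))
  f <- proportion_estimates(cells, "Control", "DPN", "cell_type")
  b <- proportion_estimates(cells, "DPN", "Control", "cell_type")
  expect_equal(f$obs_log2FD, -b$obs_log2FD, tolerance = 1e-12)
})

test_that("bootstrap interval behaves on degenerate and scaling inputs", {
  # single-type data: the interval is exactly [0, 0]
  one <- make_cells(rep("T", 30), rep("T", 40))
  ci <- bootstrap_ci(one, "Control", "DPN", "cell_type", n_boot = 200, seed = 2)
  expect_equal(ci$ci_low, 0)
  expect_equal(ci$ci_high, 0)

  # width shrinks roughly 1/sqrt(n) when sizes scale x4
  set.seed(74)
  mk <- function(n) make_cells(sample(c("T", "o"), n, TRUE, c(0.3, 0.7)),
                               sample(c("T", "o"), n, TRUE, c(0.3, 0.7)))
  w <- vapply(c(500, 2000), function(n) {
    ci <- bootstrap_ci(mk(n), "Control", "DPN", "cell_type",
                       n_boot = 400, seed = 3)
    ci$ci_high[ci$cell_type == "T"] - ci$ci_low[ci$cell_type == "T"]
  }, numeric(1))
  expect_gt(w[2] / w[1], 0.4)
  expect_lt(w[2] / w[1], 0.6)

  # percentile interval contains the observed statistic on typical data
  cells <- mk(800)
  est <- proportion_estimates(cells, "Control", "DPN", "cell_type")
  ci2 <- bootstrap_ci(cells, "Control", "DPN", "cell_type", n_boot = 500,
                      seed = 4)
  expect_true(all(ci2$ci_low <= est$obs_log2FD & est$obs_log2FD <= ci2$ci_high))
})

test_that("shift classification applies the FDR and magnitude conjunction", {
  res <- data.frame(cell_type = c("a", "b", "c"),
                    obs_log2FD = c(0.3, 2.0, 1.0),
                    p_perm = c(0.001, 0.2, 0.001))
  out <- classify_shift(res)
  expect_false(out$significant[1])   # fails magnitude
  expect_false(out$significant[2])   # fails FDR
  expect_true(out$significant[3])

  # the laxer 0.42 rule admits smaller shifts
  lax <- classify_shift(data.frame(cell_type = "a", obs_log2FD = 0.5,
                                   p_perm = 0.001),
                        lfc_threshold = 0.42)
  expect_true(lax$significant)
  strict <- classify_shift(data.frame(cell_type = "a", obs_log2FD = 0.5,
                                      p_perm = 0.001))
  expect_false(strict$significant)
})

test_that("the combined proportion_test returns a coherent table", {
  set.seed(75)
  cells <- make_cells(sample(c("A", "B"), 300, TRUE, c(0.2, 0.8)),
                      sample(c("A", "B"), 300, TRUE, c(0.5, 0.5)))
  pt <- proportion_test(cells, "Control", "DPN", "cell_type",
                        n_perm = 300, n_boot = 300, seed = 5)
  expect_s3_class(pt, "prop_test")
  expect_true(all(c("prop_a", "prop_b", "obs_log2FD", "ci_low", "ci_high",
                    "p_perm", "p_adj", "significant") %in% names(pt)))
  expect_true(pt$significant[pt$cell_type == "A"])
})

test_that("nodule-adjacency fold changes recover planted compositions", {
  mk_group <- function(n, p_t, group, samples = 2) {
    data.frame(group = group,
               neuron_type = sample(c("T", "o"), n, TRUE, c(p_t, 1 - p_t)),
               sample_id = sample(paste0(group, 1:samples), n, TRUE))
  }
  set.seed(76)
  neurons <- rbind(mk_group(4000, 0.10, "control"),
                   mk_group(4000, 0.30, "dpn_adjacent"),
                   mk_group(4000, 0.10, "dpn_nonadjacent"))
  fc <- nodule_adjacency_fold_change(neurons)
  t_row <- fc[fc$neuron_type == "T", ]
  expect_equal(t_row$fc_adjacent, 3, tolerance = 0.25)
  expect_equal(t_row$fc_nonadjacent, 1, tolerance = 0.15)

  # identical composition everywhere -> all fold changes ~1
  same <- rbind(mk_group(2000, 0.2, "control"),
                mk_group(2000, 0.2, "dpn_adjacent"),
                mk_group(2000, 0.2, "dpn_nonadjacent"))
  fc2 <- nodule_adjacency_fold_change(same)
  expect_true(all(abs(fc2$fc_adjacent - 1) < 0.15))
  expect_true(all(abs(fc2$fc_nonadjacent - 1) < 0.15))

  expect_error(nodule_adjacency_fold_change(neurons[neurons$group != "control", ]),
               "non-empty")
})
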