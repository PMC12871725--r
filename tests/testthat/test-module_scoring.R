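# random log-normalized dataset for scoring checks
random_scored_dataset <- function(n_genes = 30, n_cells = 20, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 5) + 1, n_genes, n_cells)
  rownames(counts) <- sprintf("G%03d", seq_len(n_genes))
  log_normalize(make_toy_dataset(counts))
}

test_that("module score equals the naive oracle for any seed", {
  for (seed in c(1, 7, 123)) {
    ds <- random_scored_dataset(seed = seed + 500)
    gene_set <- sample(rownames(ds$lognorm), 6)
    got <- score_gene_module(ds, gene_set, n_bins = 5, n_ctrl = 10, seed = seed)
    want <- oracle_module_score(ds$lognorm, gene_set, n_bins = 5, n_ctrl = 10,
                                seed = seed)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("module score is forced when set and background are constant", {
  # every set gene lognorm 2.0, every other gene 1.0 -> score exactly 1
  n_genes <- 40; n_cells <- 8
  ln <- matrix(1, n_genes, n_cells,
               dimnames = list(sprintf("G%03d", 1:n_genes), NULL))
  set_genes <- c("G005", "G017", "G030")
  ln[set_genes, ] <- 2
  ds <- make_toy_dataset(matrix(1L, n_genes, n_cells))
  ds$lognorm <- methods::as(ln, "CsparseMatrix")
  dimnames(ds$lognorm) <- list(rownames(ln), colnames(ds$counts))
  for (seed in c(2, 9)) {
    s <- score_gene_module(ds, set_genes, n_bins = 2, n_ctrl = 5, seed = seed)
    expect_equal(unname(s), rep(1, n_cells), tolerance = 1e-12)
  }
})

test_that("adding a constant to one cell's genes leaves its score unchanged", {
  # a uniform shift of a cell moves every gene's mean equally, so the bins,
  # the control draw and the set-minus-control difference are all unchanged
  ds <- random_scored_dataset(seed = 33)
  gene_set <- rownames(ds$lognorm)[c(3, 11, 25)]
  base <- score_gene_module(ds, gene_set, n_bins = 4, n_ctrl = 8, seed = 5)
  shifted <- ds
  shifted$lognorm[, 7] <- shifted$lognorm[, 7] + 0.3
  s2 <- score_gene_module(shifted, gene_set, n_bins = 4, n_ctrl = 8, seed = 5)
  expect_lt(abs(s2[7] - base[7]), 1e-10)
  expect_equal(unname(s2[-7]), unname(base[-7]), tolerance = 1e-12)
})

test_that("scoring validates inputs", {
  ds <- random_scored_dataset()
  expect_error(score_gene_module(ds, c("NOPE1", "NOPE2")), "none of the module genes")
  expect_warning(score_gene_module(ds, c("G001", "MISSING"), n_bins = 3,
                                   n_ctrl = 5, seed = 1), "absent")
  expect_error(score_gene_module(ds, "G001", n_bins = 500), "n_bins")
  ds$lognorm <- NULL
  expect_error(score_gene_module(ds, "G001"), "lognorm")
})

test_that("trigger score follows the composite formula and sign convention", {
  scores <- list(apoptosis = 0.2, p53 = 0.1, dna_repair = 0.0, upr = 0.1,
                 survival = 0.3)
  expect_equal(apoptosis_trigger_score(scores), 0.1, tolerance = 1e-12)
  zeros <- lapply(scores, function(x) 0)
  expect_equal(apoptosis_trigger_score(zeros), 0)
  surv_only <- list(apoptosis = 0, p53 = 0, dna_repair = 0, upr = 0,
                    survival = 0.7)
  expect_equal(apoptosis_trigger_score(surv_only), -0.7)
  expect_error(apoptosis_trigger_score(scores[-2]), "p53")

  # identity to 1e-12 on vectors
  set.seed(4)
  v <- lapply(setNames(1:5, names(scores)), function(i) rnorm(100))
  expect_equal(apoptosis_trigger_score(v),
               v$apoptosis + v$p53 + v$dna_repair + v$upr - v$survival,
               tolerance = 1e-12)
})

test_that("ApopHigh classification uses the pooled interpolated quantile", {
  labels <- classify_apop_high(1:10)
  expect_equal(attr(labels, "threshold"), 9.1)
  expect_identical(which(labels == "ApopHigh"), 10L)

  set.seed(8)
  n <- 10000
  frac <- mean(classify_apop_high(rnorm(n)) == "ApopHigh")
  expect_lt(abs(frac - 0.10), 1 / n + 1e-12)

  expect_warning(all_high <- classify_apop_high(rep(2, 5)), "constant")
  expect_true(all(all_high == "ApopHigh"))
  expect_error(classify_apop_high(numeric(0)), "empty")
  expect_error(classify_apop_high(1:5, quantile = 1.2), "quantile")
})

test_that("ApopHigh summaries partition counts exactly", {
  set.seed(14)
  n <- 300
  tab <- data.frame(
    condition = sample(c("Control", "Diabetic", "DPN"), n, TRUE),
    neuron_subtype = sample(c("A", "B", "C"), n, TRUE),
    donor_id = sample(paste0("D", 1:6), n, TRUE),
    apop_class = sample(c("ApopHigh", "ApopLow"), n, TRUE, prob = c(0.1, 0.9)))
  by_cond <- apop_high_summary(tab, "condition")
  by_sub <- apop_high_summary(tab, "subtype_condition")
  expect_equal(sum(by_cond$total), n)
  expect_equal(by_cond$prop_high, by_cond$n_high / by_cond$total)
  for (cc in by_cond$condition) {
    expect_equal(sum(by_sub$n_high[by_sub$condition == cc]),
                 by_cond$n_high[by_cond$condition == cc])
  }
  # 3 high among 10 -> 0.3
  small <- data.frame(condition = rep("DPN", 10),
                      apop_class = rep(c("ApopHigh", "ApopLow"), c(3, 7)))
  expect_equal(apop_high_summary(small, "condition")$prop_high, 0.3)
})

test_that("donor-level condition test behaves on degenerate and null input", {
  flat <- data.frame(donor_id = paste0("D", 1:9),
                     condition = rep(c("Control", "Diabetic", "DPN"), each = 3),
                     prop_high = rep(0.1, 9))
  r <- donor_condition_test(flat)
  expect_equal(r$omnibus$p_value, 1)
  expect_equal(nrow(r$pairwise), 3)

  few <- data.frame(donor_id = paste0("D", 1:5),
                    condition = c("Control", "Control", "Diabetic", "Diabetic", "DPN"),
                    prop_high = c(0.1, 0.2, 0.15, 0.12, 0.3))
  expect_warning(r2 <- donor_condition_test(few), "DPN")
  expect_equal(nrow(r2$pairwise), 1)
})

test_that("raising apoptosis-gene expression never lowers the trigger score", {
  ds <- generate_cohort(tiny_cohort(seed = 61))$dataset
  suppressMessages(ds <- log_normalize(qc_filter(ds, min_genes = 50)))
  mods <- default_modules(200)
  s1 <- score_apoptosis(ds, mods, seed = 2)
  boosted <- ds
  target_cells <- which(boosted$cells$major_type == "Neurons")[1:20]
  apop_idx <- match(mods$apoptosis, rownames(boosted$lognorm))
  boosted$lognorm[apop_idx, target_cells] <-
    boosted$lognorm[apop_idx, target_cells] + 0.5
  s2 <- score_apoptosis(boosted, mods, seed = 2)
  shared <- intersect(s1$barcode, s2$barcode)
  tc <- intersect(colnames(ds$counts)[target_cells], shared)
  d1 <- s1$trigger_score[match(tc, s1$barcode)]
  d2 <- s2$trigger_score[match(tc, s2$barcode)]
  expect_true(all(d2 >= d1 - 1e-10))
})
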