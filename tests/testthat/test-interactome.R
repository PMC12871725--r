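# hand-built inputs for criterion-level checks: one comparison, small DE
# tables and expression matrices whose values sit just around the thresholds
base_inputs <- function() {
  de_tab <- function(genes, lfc, padj) {
    data.frame(gene = genes, log2FC = lfc, p_adj = padj,
               stringsAsFactors = FALSE)
  }
  list(
    pairs = data.frame(ligand = "LIG1", receptor = "REC1",
                       stringsAsFactors = FALSE),
    de_nonneuronal = list(control_vs_dpn = de_tab("LIG1", 1, 0.01)),
    de_neuronal = list(control_vs_dpn = de_tab("REC1", 0.2, 0.5)),
    pop_expr = matrix(0.5, 1, 3, dimnames = list("REC1", paste0("P", 1:3))),
    pct_lig = matrix(0.01, 1, 3, dimnames = list("LIG1", CONDS)),
    pct_rec = matrix(0.10, 1, 3, dimnames = list("REC1", CONDS)))
}
CONDS <- c("Control", "Diabetic", "DPN")

run_filter <- function(inp) {
  filter_interactions(inp$pairs, inp$de_nonneuronal, inp$de_neuronal,
                      inp$pop_expr, inp$pct_lig, inp$pct_rec)
}

test_that("a pair meeting all criteria is eligible", {
  rec <- run_filter(base_inputs())
  expect_identical(nrow(rec), 1L)
  expect_true(rec$eligible)
  expect_true(all(unlist(rec[c("C1", "C2", "C3a", "C3b", "C3c")])))
})

test_that("each criterion individually excludes a constructed violation", {
  # C1: neither gene differentially expressed
  inp <- base_inputs()
  inp$de_nonneuronal$control_vs_dpn$p_adj <- 0.5
  rec <- run_filter(inp)
  expect_false(rec$C1); expect_false(rec$eligible)
  expect_true(all(unlist(rec[c("C2", "C3a", "C3b", "C3c")])))

  # C2: both significant in opposite directions
  inp <- base_inputs()
  inp$de_neuronal$control_vs_dpn$log2FC <- -1
  inp$de_neuronal$control_vs_dpn$p_adj <- 0.01
  rec <- run_filter(inp)
  expect_false(rec$C2); expect_false(rec$eligible)
  expect_true(rec$C1)

  # same direction significant in both: C2 holds
  inp$de_neuronal$control_vs_dpn$log2FC <- 1
  expect_true(run_filter(inp)$C2)

  # C3a: receptor below the 0.01 pseudobulk floor in every population
  inp <- base_inputs()
  inp$pop_expr[] <- 0.009
  rec <- run_filter(inp)
  expect_false(rec$C3a); expect_false(rec$eligible)

  # C3b: receptor under 5% of neurons in every condition
  inp <- base_inputs()
  inp$pct_rec[] <- 0.04
  rec <- run_filter(inp)
  expect_false(rec$C3b); expect_false(rec$eligible)

  # C3c: ligand under 0.1% of all cells in every condition
  inp <- base_inputs()
  inp$pct_lig[] <- 0.0009
  rec <- run_filter(inp)
  expect_false(rec$C3c); expect_false(rec$eligible)
})

test_that("genes absent from DE tables count as not differentially expressed", {
  inp <- base_inputs()
  inp$de_nonneuronal$control_vs_dpn <- inp$de_nonneuronal$control_vs_dpn[0, ]
  rec <- run_filter(inp)
  expect_true(rec$ligand_absent)
  expect_equal(rec$ligand_p_adj, 1)
  expect_false(rec$C1)
})

test_that("LR table loading upper-cases and dedups", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ligand\treceptor", "ngf\tNTRK1", "NGF\tntrk1", "bdnf\tNTRK2"), f)
  tab <- load_lr_pairs(f)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$ligand, c("NGF", "BDNF"))
  expect_identical(tab$receptor, c("NTRK1", "NTRK2"))

  writeLines(c("ligand\tother", "a\tb"), f)
  expect_error(load_lr_pairs(f), "receptor")

  writeLines("ligand\treceptor", f)
  expect_identical(nrow(load_lr_pairs(f)), 0L)
})

test_that("population pseudobulk lognorm follows the formula and depth invariance", {
  counts <- matrix(c(1, 99, 2, 198), 2, 2,
                   dimnames = list(c("REC", "OTHER"), c("c1", "c2")))
  ds <- cell_dataset(counts,
                     cells = data.frame(neuron_subtype = c("P1", "P1")))
  pe <- receptor_population_expression(ds)
  # receptor is 1% of pseudobulk mass -> ln(1 + 0.01 * 1e4) = ln(101)
  expect_equal(pe["REC", "P1"], log(101), tolerance = 1e-12)

  # duplicating every cell leaves values unchanged
  ds2 <- cell_dataset(cbind(counts, counts),
                      cells = data.frame(neuron_subtype = rep("P1", 4)))
  expect_equal(receptor_population_expression(ds2)["REC", "P1"],
               pe["REC", "P1"], tolerance = 1e-12)

  # all-zero receptor fails the criterion downstream
  z <- cell_dataset(matrix(c(0L, 5L), 2, 1,
                           dimnames = list(c("REC", "OTHER"), "c1")),
                    cells = data.frame(neuron_subtype = "P1"))
  expect_equal(receptor_population_expression(z)["REC", "P1"], 0)
})

test_that("scoring is monotone and ranking dedups pairs", {
  mk_rec <- function(lig, rec, lfc_l, score_extra = 0, comparison = "control_vs_dpn") {
    data.frame(ligand = lig, receptor = rec, comparison = comparison,
               ligand_log2FC = lfc_l, ligand_p_adj = 0.01, ligand_pct = 0.5,
               ligand_absent = FALSE, receptor_log2FC = 1,
               receptor_p_adj = 0.01, receptor_pct = 0.5,
               receptor_absent = FALSE, source_type = "Fibroblasts",
               C1 = TRUE, C2 = TRUE, C3a = TRUE, C3b = TRUE, C3c = TRUE,
               eligible = TRUE, stringsAsFactors = FALSE)
  }
  # single eligible record -> rank 1; oversized k warns and returns all
  one <- score_and_rank(mk_rec("L", "R", 1), k = 1)
  expect_identical(one$top$rank, 1L)
  expect_warning(score_and_rank(mk_rec("L", "R", 1), k = 5), "eligible unique pairs")

  # monotonicity: larger |log2FC| outranks, all else equal
  two <- score_and_rank(rbind(mk_rec("L1", "R1", 2), mk_rec("L2", "R2", 1)),
                        k = 2)
  expect_identical(two$top$ligand, c("L1", "L2"))

  # same pair in two comparisons: overall score is the max, exported once
  dup <- rbind(mk_rec("L1", "R1", 2),
               mk_rec("L1", "R1", 1, comparison = "control_vs_diabetic"),
               mk_rec("L2", "R2", 1))
  suppressWarnings(rk <- score_and_rank(dup, k = 10))
  expect_identical(anyDuplicated(rk$top[c("ligand", "receptor")]), 0L)
  expect_identical(nrow(rk$top), 2L)
  expect_equal(rk$top$score[1], max(rk$records$score[rk$records$ligand == "L1"]))

  # ties broken lexicographically by (ligand, receptor)
  tie <- score_and_rank(rbind(mk_rec("B", "R", 1), mk_rec("A", "R", 1)), k = 2)
  expect_identical(tie$top$ligand, c("A", "B"))

  # ineligible records carry no rank
  mixed <- rbind(mk_rec("L1", "R1", 1),
                 transform(mk_rec("L3", "R3", 5), eligible = FALSE, C1 = FALSE))
  rk2 <- score_and_rank(mixed, k = 1)
  expect_true(is.na(rk2$records$rank[2]))
  expect_error(score_and_rank(transform(mk_rec("L", "R", 1),
                                        eligible = FALSE), k = 1),
               "no eligible")

  # sankey export mirrors the top table
  sk <- sankey_edges(rk$top)
  expect_identical(names(sk), c("source_type", "ligand", "receptor", "score"))
  expect_identical(nrow(sk), nrow(rk$top))
})
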