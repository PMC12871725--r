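# Seeded simulation experiments that measure the pipeline's operating
# characteristics on synthetic cohorts: recovery of planted apoptosis
# priming, calibration and power of the proportion test, DE engine
# sensitivity/FDR and type-I error, and interactome recovery. These back the
# reproducibility script and the acceptance checks; each returns plain
# numbers computed from scratch at call time.

#' Recovery of planted apoptosis priming in susceptible subtypes
#'
#' For each seed, simulates the default cohort (14/10/6 donors, 1000 cells
#' per donor, 2000 genes) with the apoptosis module up-regulated (log2FC
#' `lfc`) in three Ab-LTMR subtypes under DPN, runs QC, normalization and
#' the apoptosis-priming composite over neurons, and records whether the
#' three planted subtypes hold the three largest DPN ApopHigh proportions
#' among neuronal subtypes, plus the donor-level Kruskal-Wallis p across
#' conditions.
#'
#' @param n_seeds number of replicate cohorts (default 10)
#' @param base_seed seed offset
#' @param lfc planted log2 fold change (default 1)
#' @param cohort list of [cohort_config()] overrides (defaults are used for
#'   the study design)
#' @return data.frame: seed, top3_hit, kw_p, apop_frac
#' @export
apoptosis_recovery_experiment <- function(n_seeds = 10, base_seed = 1,
                                          lfc = 1, cohort = list()) {
  planted_subtypes <- c("Ab-LTMR.ETV1", "Ab-LTMR.NSG2", "Ab-LTMR.LGI2")
  res <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + 97L * i
    cohort$seed <- seed
    cohort$planted_effects <- list(
      expression_shift(default_modules(if (is.null(cohort$n_genes)) 2000 else
        cohort$n_genes)$apoptosis,
        condition = "DPN", log2fc = lfc, subtype = planted_subtypes))
    cfg <- do.call(cohort_config, cohort)
    sim <- generate_cohort(cfg)
    ds <- log_normalize(qc_filter(sim$dataset, verbose = FALSE))
    scores <- score_apoptosis(ds, default_modules(cfg$n_genes), seed = seed)
    by_sub <- apop_high_summary(scores, "subtype_condition")
    dpn <- by_sub[by_sub$condition == "DPN", ]
    top3 <- dpn$neuron_subtype[order(-dpn$prop_high)][1:3]
    kw <- donor_condition_test(apop_high_summary(scores, "donor_condition"))
    res[[i]] <- data.frame(
      seed = seed,
      top3_hit = setequal(top3, planted_subtypes),
      kw_p = kw$omnibus$p_value,
      apop_frac = mean(scores$apop_class == "ApopHigh"))
    rm(sim, ds, scores); gc(verbose = FALSE)
  }
  do.call(rbind, res)
}

#' Type-I calibration of the permutation proportion test
#'
#' Simulates null cohorts (no planted effects), compares Control vs DPN
#' major-type proportions with the permutation test, and returns the pooled
#' per-type rejection rate at `alpha` on the unadjusted permutation p.
#'
#' @param n_sims number of null cohorts (default 500)
#' @param cells_per_donor cells per donor per condition (default 500)
#' @param n_perm permutations per test (default 1000)
#' @param alpha nominal level (default 0.05)
#' @param base_seed seed offset
#' @return list: rejection_rate, n_tests
#' @export
proportion_null_calibration <- function(n_sims = 500, cells_per_donor = 500,
                                        n_perm = 1000, alpha = 0.05,
                                        base_seed = 1) {
  rej <- 0L; n_tests <- 0L
  for (i in seq_len(n_sims)) {
    cfg <- cohort_config(n_donors = c(Control = 1, Diabetic = 1, DPN = 1),
                         cells_per_donor = cells_per_donor, n_genes = 160,
                         lowq_frac = 0, seed = base_seed + i)
    cells <- generate_cohort(cfg)$dataset$cells
    pt <- permutation_test(cells, "Control", "DPN", "major_type",
                           n_perm = n_perm, seed = base_seed + i)
    rej <- rej + sum(pt$p_perm < alpha)
    n_tests <- n_tests + nrow(pt)
  }
  list(rejection_rate = rej / n_tests, n_tests = n_tests)
}

#' Power of the proportion test for a planted two-fold shift
#'
#' Plants a log2FD = 1 shift of a ~10%-abundance class (Fibroblasts) under
#' DPN with `cells_per_condition` cells per condition, and counts how often
#' the shift is called significant (BH-adjusted permutation p < fdr and
#' |log2FD| > lfc_threshold).
#'
#' @param n_sims number of simulated cohorts (default 100)
#' @param cells_per_condition cells per condition (default 1000)
#' @param n_perm permutations per test (default 1000)
#' @param fdr,lfc_threshold significance rule (defaults 0.05, 0.585)
#' @param base_seed seed offset
#' @return list: power, n_sims
#' @export
proportion_power_experiment <- function(n_sims = 100,
                                        cells_per_condition = 1000,
                                        n_perm = 1000, fdr = 0.05,
                                        lfc_threshold = 0.585,
                                        base_seed = 1) {
  target <- "Fibroblasts"   # baseline abundance 0.10
  hits <- 0L
  for (i in seq_len(n_sims)) {
    cfg <- cohort_config(
      n_donors = c(Control = 1, Diabetic = 1, DPN = 1),
      cells_per_donor = cells_per_condition, n_genes = 160, lowq_frac = 0,
      seed = base_seed + i,
      planted_effects = list(proportion_shift(target, "DPN", log2fc = 1)))
    cells <- generate_cohort(cfg)$dataset$cells
    pt <- permutation_test(cells, "Control", "DPN", "major_type",
                           n_perm = n_perm, seed = base_seed + i)
    cls <- classify_shift(pt, fdr = fdr, lfc_threshold = lfc_threshold)
    hits <- hits + cls$significant[cls$cell_type == target]
  }
  list(power = hits / n_sims, n_sims = n_sims)
}

#' Sensitivity and FDR of the rank-sum DE engine on planted genes
#'
#' For each seed, simulates two 200-cell groups (Control vs DPN neurons and
#' glia pooled) with the 100 module genes up-regulated two-fold under DPN,
#' runs the rank-sum engine and measures sensitivity over planted genes and
#' the empirical false discovery rate over null genes at `fdr`.
#'
#' @param n_seeds replicate cohorts (default 10)
#' @param cells_per_group cells per condition (default 200)
#' @param lfc planted log2 fold change (default 1)
#' @param fdr discovery threshold (default 0.05)
#' @param base_seed seed offset
#' @return list: sensitivity, empirical_fdr, n_planted, n_null
#' @export
de_ranksum_recovery <- function(n_seeds = 10, cells_per_group = 200, lfc = 1,
                                fdr = 0.05, base_seed = 1) {
  tp <- 0L; fn <- 0L; fp <- 0L; disc <- 0L
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + 31L * i
    planted <- unlist(default_modules(2000), use.names = FALSE)
    cfg <- cohort_config(
      n_donors = c(Control = 2, Diabetic = 1, DPN = 2),
      cells_per_donor = cells_per_group / 2, n_genes = 2000, lowq_frac = 0,
      seed = seed,
      planted_effects = list(expression_shift(planted, "DPN", log2fc = lfc)))
    ds <- log_normalize(generate_cohort(cfg)$dataset)
    de <- de_rank_sum(ds, ds$cells$condition == "Control",
                      ds$cells$condition == "DPN")
    sig <- de$p_adj < fdr & de$gene %in% rownames(ds$counts)
    is_planted <- de$gene %in% planted
    tp <- tp + sum(sig & is_planted)
    fn <- fn + sum(!sig & is_planted)
    fp <- fp + sum(sig & !is_planted)
    disc <- disc + sum(sig)
  }
  list(sensitivity = tp / (tp + fn),
       empirical_fdr = if (disc > 0) fp / disc else 0,
       n_planted = tp + fn, n_null = n_seeds * 2000L - (tp + fn))
}

#' Type-I error of the pseudobulk NB Wald engine on Poisson nulls
#'
#' Simulates Poisson counts (NB dispersion -> 0) for `n_genes` null genes at
#' 6 vs 6 replicates with mean `mu` and returns the rejection rate of the
#' Wald p at `alpha`.
#'
#' @param n_sims simulation rounds (default 200)
#' @param n_genes genes per round (default 300)
#' @param mu Poisson mean (default 100)
#' @param alpha nominal level (default 0.05)
#' @param base_seed seed offset
#' @return list: type1_rate, n_tests
#' @export
nb_type1_experiment <- function(n_sims = 200, n_genes = 300, mu = 100,
                                alpha = 0.05, base_seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  cond <- rep(c("Control", "DPN"), each = 6)
  rej <- 0L; n_tests <- 0L
  for (i in seq_len(n_sims)) {
    set.seed(base_seed + i)
    y <- matrix(stats::rpois(n_genes * 12, mu), n_genes, 12,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)), NULL))
    de <- de_pseudobulk_nb(y, cond, "Control", "DPN")
    rej <- rej + sum(de$p < alpha)
    n_tests <- n_tests + nrow(de)
  }
  list(type1_rate = rej / n_tests, n_tests = n_tests)
}

#' Recovery of a planted ligand-receptor interaction among decoys
#'
#' For each seed, simulates a cohort in which one ligand gene is strongly
#' up-regulated in fibroblasts under DPN (a 32-fold within-fibroblast shift;
#' with fibroblasts at ~10% abundance this reads as roughly a two-unit
#' log2 fold change among all DRG cells, the scale the eligibility filter
#' sees), builds the three per-comparison DE tables (all cells; neurons),
#' and runs the interactome filter/rank over the planted pair plus
#' `n_decoys` decoy pairs. Returns how often the planted pair lands in the
#' top 10.
#'
#' @param n_seeds replicate cohorts (default 10)
#' @param n_decoys decoy pairs (default 200)
#' @param base_seed seed offset
#' @return data.frame: seed, rank (NA when ineligible), top10_hit
#' @export
interactome_recovery_experiment <- function(n_seeds = 10, n_decoys = 200,
                                            base_seed = 1) {
  ligand <- "GENE00050"; receptor <- "GENE00120"
  res <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + 53L * i
    cfg <- cohort_config(
      n_donors = c(Control = 2, Diabetic = 2, DPN = 2),
      cells_per_donor = 2000, n_genes = 2000, lowq_frac = 0, seed = seed,
      planted_effects = list(
        expression_shift(ligand, "DPN", log2fc = 5,
                         major_type = "Fibroblasts")))
    ds <- log_normalize(generate_cohort(cfg)$dataset)
    neurons <- ds$cells$major_type == "Neurons"
    de_all <- list(); de_neur <- list()
    for (cmp in list(c("Control", "Diabetic"), c("Diabetic", "DPN"),
                     c("Control", "DPN"))) {
      lab <- comparison_label(cmp[1], cmp[2])
      in_a <- ds$cells$condition == cmp[1]
      in_b <- ds$cells$condition == cmp[2]
      de_all[[lab]] <- de_rank_sum(ds, in_a, in_b, comparison = lab)
      de_neur[[lab]] <- de_rank_sum(ds, in_a & neurons, in_b & neurons,
                                    comparison = lab)
    }
    pairs <- synthetic_lr_pairs(2000, n_pairs = n_decoys,
                                planted = data.frame(ligand = ligand,
                                                     receptor = receptor),
                                seed = seed)
    inter <- suppressWarnings(
      build_interactome(ds, pairs, de_all, de_neur, k = 10))
    hit <- any(inter$top$ligand == ligand & inter$top$receptor == receptor)
    rk <- inter$records$rank[inter$records$ligand == ligand &
                               inter$records$receptor == receptor]
    rk <- if (all(is.na(rk))) NA_integer_ else min(rk, na.rm = TRUE)
    res[[i]] <- data.frame(seed = seed, rank = rk, top10_hit = hit)
    rm(ds); gc(verbose = FALSE)
  }
  do.call(rbind, res)
}
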