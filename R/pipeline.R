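# Configuration-driven orchestration: simulate -> QC -> normalize -> score ->
# proportions -> DE -> interactome, with per-stage TSV outputs, a manifest
# (config hash, seeds, versions, per-file checksums) and deterministic
# reruns. Also the Nageotte-burden stratification labels.

#' Stratify Nageotte scores into burden labels
#'
#' The published bins overlap at 4 (Low 1-2, Moderate-High 3-4, High 4-5);
#' the default resolution assigns 4 to High. Mapping: `score <= 2` Low,
#' `2 < score < high_cut` Moderate-High, `score >= high_cut` High, missing
#' scores Unscored.
#'
#' @param score numeric vector in \[0, 5\] (NA allowed)
#' @param high_cut boundary resolving the overlap (default 4, High-wins)
#' @return character vector of labels
#' @export
stratify_nageotte <- function(score, high_cut = 4) {
  bad <- !is.na(score) & (score < 0 | score > 5)
  if (any(bad)) stop("Nageotte scores must lie in [0, 5]; got ",
                     paste(score[bad], collapse = ", "))
  out <- rep("Unscored", length(score))
  ok <- !is.na(score)
  out[ok & score <= 2] <- "Low"
  out[ok & score > 2 & score < high_cut] <- "Moderate-High"
  out[ok & score >= high_cut] <- "High"
  out
}

#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis: QC at
#' >1000 genes and <10% mitochondrial reads, natural-log normalization at
#' scale 1e4, ApopHigh at the pooled 90th percentile over neurons,
#' proportion tests at FDR < 0.05 with |log2FD| > 0.585, DE thresholds at
#' FDR < 0.05 with |log2FC| > log2(1.33), interactome top-50.
#'
#' @param out_dir output directory for the run
#' @param seed master seed; stage seeds derive from it
#' @param cohort list of overrides passed to [cohort_config()]
#' @param ... scalar overrides: min_genes, max_mito_frac, scale, quantile,
#'   n_bins, n_ctrl, n_perm, n_boot, prop_fdr, prop_lfc, de_fdr, de_lfc,
#'   alpha, k, n_lr_pairs, nageotte_high_cut
#' @return a `run_config` list
#' @export
run_config <- function(out_dir = tempfile("drgpn_run_"), seed = 1L,
                       cohort = list(), ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
    min_genes = 1000, max_mito_frac = 0.10, scale = 1e4,
    quantile = 0.90, n_bins = 24, n_ctrl = 100,
    comparisons = list(c("Control", "Diabetic"), c("Diabetic", "DPN"),
                       c("Control", "DPN")),
    cluster_field = "neuron_subtype",
    n_perm = 1000, n_boot = 1000, prop_fdr = 0.05, prop_lfc = 0.585,
    de_fdr = 0.05, de_lfc = log2(1.33),
    alpha = 0.05, k = 50, n_lr_pairs = 200,
    nageotte_high_cut = 4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$quantile > 0, cfg$quantile < 1,
            cfg$prop_fdr > 0, cfg$prop_fdr < 1,
            cfg$de_fdr > 0, cfg$de_fdr < 1,
            cfg$max_mito_frac > 0, cfg$scale > 0,
            cfg$n_perm >= 1, cfg$n_boot >= 1, cfg$k >= 1)
  for (cmp in cfg$comparisons) {
    if (length(cmp) != 2 || !all(cmp %in% CONDITIONS)) {
      stop("comparison references unknown condition label(s): ",
           paste(cmp, collapse = " vs "))
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [run_config()]
#'   arguments (`cohort` as a nested mapping)
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$comparisons)) {
    y$comparisons <- lapply(y$comparisons, unlist)
  }
  if (!is.null(y$cohort$n_donors)) y$cohort$n_donors <- unlist(y$cohort$n_donors)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

comparison_label <- function(a, b) {
  tolower(paste0(gsub("[^A-Za-z]", "", a), "_vs_", gsub("[^A-Za-z]", "", b)))
}

#' Run the full pipeline
#'
#' Simulates the cohort, applies QC and log-normalization, scores the
#' apoptosis-priming composite over neurons, summarizes and tests ApopHigh
#' proportions, runs the proportion tests for every configured comparison,
#' computes rank-sum DE over neurons and over all cells, builds the
#' ligand-receptor interactome, and writes every stage table plus a manifest
#' under `config$out_dir`. Rerunning with an identical config yields
#' byte-identical tables.
#'
#' @param config a `run_config` (or path to a YAML file)
#' @return the output directory, invisibly; the manifest lists all files
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] %s",
                                             format(Sys.time(), "%H:%M:%S"),
                                             sprintf(...)))
  outputs <- character(0)
  emit <- function(df, name) {
    outputs[[name]] <<- write_tsv(df, file.path(config$out_dir, name))
  }

  # --- simulate ------------------------------------------------------------
  log_stage("simulate: generating cohort")
  cohort_args <- config$cohort
  cohort_args$seed <- if (is.null(cohort_args$seed)) config$seed else cohort_args$seed
  ccfg <- do.call(cohort_config, cohort_args)
  sim <- generate_cohort(ccfg)
  emit(sim$truth, "truth.tsv")
  tenx_dir <- file.path(config$out_dir, "counts_10x")
  write_counts_10x(sim$dataset, tenx_dir)

  # --- QC + normalize ------------------------------------------------------
  log_stage("qc: filtering and normalizing")
  ds <- qc_filter(sim$dataset, min_genes = config$min_genes,
                  max_mito_frac = config$max_mito_frac)
  ds <- log_normalize(ds, scale = config$scale)

  # --- module scoring ------------------------------------------------------
  log_stage("score: apoptosis-priming composite over neurons")
  modules <- default_modules(ccfg$n_genes)
  scores <- score_apoptosis(ds, modules, quantile = config$quantile,
                            n_bins = config$n_bins, n_ctrl = config$n_ctrl,
                            seed = config$seed)
  emit(scores, "scores.tsv")
  emit(apop_high_summary(scores, "condition"), "apop_by_condition.tsv")
  emit(apop_high_summary(scores, "subtype_condition"), "apop_by_subtype.tsv")
  donor_tab <- apop_high_summary(scores, "donor_condition")
  emit(donor_tab, "apop_by_donor.tsv")
  dt <- donor_condition_test(donor_tab)
  emit(data.frame(test = c("kruskal_wallis",
                           paste(dt$pairwise$group_a, dt$pairwise$group_b, sep = "_vs_")),
                  statistic = c(dt$omnibus$statistic, rep(NA, nrow(dt$pairwise))),
                  p = c(dt$omnibus$p_value, dt$pairwise$p),
                  p_adj = c(NA, dt$pairwise$p_adj)),
       "apop_donor_tests.tsv")

  # --- proportions ---------------------------------------------------------
  neurons <- ds$cells$major_type == "Neurons"
  for (cmp in config$comparisons) {
    lab <- comparison_label(cmp[1], cmp[2])
    log_stage("proportions: %s", lab)
    pt <- proportion_test(ds$cells[neurons, , drop = FALSE], cmp[1], cmp[2],
                          config$cluster_field, n_perm = config$n_perm,
                          n_boot = config$n_boot, fdr = config$prop_fdr,
                          lfc_threshold = config$prop_lfc,
                          seed = config$seed)
    emit(as.data.frame(pt), sprintf("props_%s.tsv", lab))
  }

  # --- differential expression --------------------------------------------
  de_neuronal <- list(); de_nonneuronal <- list()
  for (cmp in config$comparisons) {
    lab <- comparison_label(cmp[1], cmp[2])
    log_stage("de: %s", lab)
    in_a <- ds$cells$condition == cmp[1]
    in_b <- ds$cells$condition == cmp[2]
    de_n <- classify_deg(de_rank_sum(ds, in_a & neurons, in_b & neurons,
                                     comparison = lab),
                         fdr = config$de_fdr, lfc_threshold = config$de_lfc)
    de_all <- classify_deg(de_rank_sum(ds, in_a, in_b, comparison = lab),
                           fdr = config$de_fdr, lfc_threshold = config$de_lfc)
    de_neuronal[[lab]] <- de_n
    de_nonneuronal[[lab]] <- de_all
    emit(de_n, sprintf("de_neurons_%s.tsv", lab))
    emit(de_all, sprintf("de_allcells_%s.tsv", lab))
  }

  # --- interactome ---------------------------------------------------------
  log_stage("interactome: filtering and ranking")
  pairs <- synthetic_lr_pairs(ccfg$n_genes, n_pairs = config$n_lr_pairs,
                              seed = config$seed)
  inter <- tryCatch(
    build_interactome(ds, pairs, de_nonneuronal, de_neuronal,
                      alpha = config$alpha, k = config$k),
    error = function(e) {
      log_stage("interactome: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(inter)) {
    emit(inter$records, "interactome.tsv")
    emit(inter$top, "interactome_top.tsv")
    emit(inter$sankey, "sankey_edges.tsv")
  }

  # --- Nageotte strata (when scores are annotated) -------------------------
  if (!is.null(ds$cells$nageotte_score)) {
    strata <- data.frame(
      donor_id = ds$cells$donor_id,
      nageotte_score = ds$cells$nageotte_score,
      stratum = stratify_nageotte(ds$cells$nageotte_score,
                                  high_cut = config$nageotte_high_cut))
    emit(unique(strata), "nageotte_strata.tsv")
  }

  # --- manifest ------------------------------------------------------------
  cfg_plain <- unclass(config)
  cfg_yaml <- yaml::as.yaml(cfg_plain[order(names(cfg_plain))])
  files <- sort(names(outputs))
  manifest <- list(
    package = "drgpn",
    version = as.character(utils::packageVersion("drgpn")),
    seed = config$seed,
    config_md5 = digest_string(cfg_yaml),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
    files = stats::setNames(
      as.list(unname(tools::md5sum(file.path(config$out_dir, files)))), files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done: %d tables in %s", length(files), config$out_dir)
  invisible(config$out_dir)
}

digest_string <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}
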