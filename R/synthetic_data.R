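# Seeded synthetic single-nucleus cohort emulating a Control/Diabetic/DPN
# human-DRG design: negative-binomial counts over a condensed gene universe,
# 8 major cell classes, 22 neuronal subtypes, deliberate low-quality cells,
# and planted expression / proportion effects recorded in a ground-truth
# table. Everything is drawn from one seeded stream in a fixed order, so a
# cohort is reproducible from its config alone.

MAJOR_TYPES <- c("Neurons", "Satellite glia", "Schwann", "Fibroblasts",
                 "Endothelial", "Immune", "Smooth muscle", "Adipocytes")

NEURON_SUBTYPES <- c(
  "ATF3", "Ab-LTMR.ETV1", "Ab-LTMR.NSG2", "Ab-LTMR.LGI2",
  "Ab-RA-LTMR", "Ab-SA-LTMR", "Ad-LTMR", "C-LTMR",
  "C-PEP.TAC1/CACNG5", "C-PEP.TAC1/GFRA3", "C-PEP.SST", "C-PEP.KIT",
  "C-PEP.TRPM8", "C-PEP.NTRK3", "C-PEP.CHRNA7", "C-NP.GFRA1",
  "C-NP.GFRA2", "C-NP.SSTR2", "C-NP.MRGPRX1", "A-COLD",
  "Proprioceptor.PVALB", "Visceral.PIEZO2")

# the 11 canonical anti-apoptotic / IAP genes seeding the survival module
SURVIVAL_TEMPLATE <- c("BCL2", "BCL2L1", "BCL2L2", "BCL2A1", "MCL1", "XIAP",
                       "BIRC2", "BIRC3", "BIRC5", "BIRC6", "CFLAR")

MITO_GENES <- c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND4", "MT-ND4L", "MT-ND5",
                "MT-ND6", "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6", "MT-ATP8",
                "MT-CYB")

MODULE_SIZE <- 20L

# deterministic gene universe: 5 disjoint 20-gene modules, 13 mitochondrial
# genes, then anonymous fillers
gene_universe <- function(n_genes) {
  module_names <- unlist(default_modules(n_genes), use.names = FALSE)
  n_fill <- n_genes - length(module_names) - length(MITO_GENES)
  c(module_names, MITO_GENES, sprintf("GENE%05d", seq_len(n_fill)))
}

#' Default gene modules for the synthetic cohort
#'
#' Five pairwise-disjoint 20-gene modules over the generated gene universe:
#' apoptosis, p53, dna_repair, upr, and a pro-survival module whose first 11
#' members are the canonical anti-apoptotic/IAP genes (BCL2, BCL2L1, BCL2L2,
#' BCL2A1, MCL1, XIAP, BIRC2, BIRC3, BIRC5, BIRC6, CFLAR) padded with
#' synthetic survival genes.
#'
#' @param n_genes size of the gene universe the modules must fit into
#' @return named list of five character vectors (a `GeneSetCollection`)
#' @export
default_modules <- function(n_genes = 2000) {
  need <- 5L * MODULE_SIZE + length(MITO_GENES) + 20L  # modules + mito + room for controls
  if (n_genes < need) {
    stop("n_genes = ", n_genes, " is too small to host five disjoint ",
         MODULE_SIZE, "-gene modules plus mitochondrial and control genes (need >= ",
         need, ")")
  }
  pad <- function(prefix, k) sprintf("%s%02d", prefix, seq_len(k))
  list(
    apoptosis  = pad("APOPT", MODULE_SIZE),
    p53        = pad("TP53P", MODULE_SIZE),
    dna_repair = pad("DNARE", MODULE_SIZE),
    upr        = pad("UPRSG", MODULE_SIZE),
    survival   = c(SURVIVAL_TEMPLATE,
                   pad("SURVP", MODULE_SIZE - length(SURVIVAL_TEMPLATE)))
  )
}

#' Planted expression shift
#'
#' Multiplies the negative-binomial mean of `genes` by `2^log2fc` in cells of
#' the given condition matching the selector (major type and/or neuronal
#' subtype; `NULL` selects all).
#'
#' @param genes non-empty character vector of target gene symbols
#' @param condition one of Control/Diabetic/DPN
#' @param log2fc log2 fold change applied to the NB mean
#' @param major_type,subtype optional cell selectors
#' @export
expression_shift <- function(genes, condition, log2fc,
                             major_type = NULL, subtype = NULL) {
  if (!length(genes)) stop("expression_shift requires non-empty target_genes")
  stopifnot(condition %in% CONDITIONS, is.finite(log2fc))
  structure(list(kind = "expression_shift", genes = as.character(genes),
                 condition = condition, log2fc = log2fc,
                 major_type = major_type, subtype = subtype),
            class = "planted_effect")
}

#' Planted proportion shift
#'
#' Multiplies the baseline probability of one cell class by `2^log2fc` in the
#' given condition, rescaling the remaining classes. `target_type` may name a
#' major cell class or a neuronal subtype.
#'
#' @param target_type major type or neuronal subtype label
#' @param condition one of Control/Diabetic/DPN
#' @param log2fc log2 fold change of the class probability
#' @export
proportion_shift <- function(target_type, condition, log2fc) {
  stopifnot(condition %in% CONDITIONS, is.finite(log2fc))
  structure(list(kind = "proportion_shift", target_type = target_type,
                 condition = condition, log2fc = log2fc),
            class = "planted_effect")
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study design: 14 Control, 10 Diabetic and 6 DPN
#' donors, 8 major cell classes dominated by neurons and satellite glia, 22
#' neuronal subtypes, shared-dispersion negative-binomial counts with
#' log-normal sequencing depth, and a small fraction of deliberately
#' low-quality cells (depth down-scaled 10x, mitochondrial share inflated to
#' 15%) for exercising QC.
#'
#' @param n_donors named integer vector, donors per condition
#' @param cells_per_donor cells drawn per donor (>= 10)
#' @param n_genes size of the gene universe
#' @param major_type_baseline probability vector over the 8 major classes
#' @param neuron_subtype_baseline probability vector over the 22 subtypes
#' @param nb_dispersion shared NB dispersion (variance = mu + dispersion*mu^2)
#' @param depth_meanlog,depth_sdlog log-normal per-cell depth parameters
#' @param mito_share expected mitochondrial fraction in healthy cells
#' @param lowq_frac fraction of deliberately low-quality cells
#' @param lowq_depth_factor depth multiplier for low-quality cells
#' @param lowq_mito_share mitochondrial share in low-quality cells
#' @param planted_effects list of [expression_shift()] / [proportion_shift()]
#' @param seed integer RNG seed; the cohort is a pure function of the config
#' @return a validated `cohort_config` list
#' @export
cohort_config <- function(n_donors = c(Control = 14, Diabetic = 10, DPN = 6),
                          cells_per_donor = 1000,
                          n_genes = 2000,
                          major_type_baseline = NULL,
                          neuron_subtype_baseline = NULL,
                          nb_dispersion = 0.5,
                          depth_meanlog = log(12000),
                          depth_sdlog = 0.2,
                          mito_share = 0.05,
                          lowq_frac = 0.02,
                          lowq_depth_factor = 0.1,
                          lowq_mito_share = 0.15,
                          planted_effects = list(),
                          seed = 1L) {
  if (is.null(major_type_baseline)) {
    major_type_baseline <- c(0.35, 0.25, 0.12, 0.10, 0.08, 0.05, 0.03, 0.02)
    major_type_baseline <- stats::setNames(major_type_baseline / sum(major_type_baseline),
                                           MAJOR_TYPES)
  }
  if (is.null(neuron_subtype_baseline)) {
    w <- c(0.5, 1.5, 1.2, 1.0, 1.2, 1.0, 1.2, 1.5,
           1.8, 1.2, 1.0, 0.8, 0.8, 0.8, 0.6, 1.2,
           1.0, 0.8, 0.8, 0.6, 0.8, 0.7)
    neuron_subtype_baseline <- stats::setNames(w / sum(w), NEURON_SUBTYPES)
  }
  cfg <- structure(list(
    n_donors = n_donors, cells_per_donor = as.integer(cells_per_donor),
    n_genes = as.integer(n_genes),
    major_type_baseline = major_type_baseline,
    neuron_subtype_baseline = neuron_subtype_baseline,
    nb_dispersion = nb_dispersion,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    mito_share = mito_share,
    lowq_frac = lowq_frac, lowq_depth_factor = lowq_depth_factor,
    lowq_mito_share = lowq_mito_share,
    planted_effects = planted_effects, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(names(cfg$n_donors)) || !setequal(names(cfg$n_donors), CONDITIONS)) {
    stop("n_donors must be named with the three conditions")
  }
  if (any(cfg$n_donors < 1)) stop("every condition needs at least 1 donor")
  if (cfg$cells_per_donor < 10) stop("need at least 10 cells per donor")
  for (nm in c("major_type_baseline", "neuron_subtype_baseline")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be a probability vector summing to 1 (+/- 1e-9)")
    }
  }
  if (!setequal(names(cfg$major_type_baseline), MAJOR_TYPES)) {
    stop("major_type_baseline must cover the 8 major classes")
  }
  if (!setequal(names(cfg$neuron_subtype_baseline), NEURON_SUBTYPES)) {
    stop("neuron_subtype_baseline must cover the 22 neuronal subtypes")
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  for (eff in cfg$planted_effects) {
    if (!inherits(eff, "planted_effect")) stop("planted_effects entries must be planted_effect objects")
    if (eff$kind == "proportion_shift") {
      base <- if (eff$target_type %in% MAJOR_TYPES) cfg$major_type_baseline else
        if (eff$target_type %in% NEURON_SUBTYPES) cfg$neuron_subtype_baseline else
          stop("proportion_shift target '", eff$target_type, "' is not a known class")
      p_new <- base[[eff$target_type]] * 2^eff$log2fc
      if (p_new >= 1 || p_new <= 0) {
        stop("infeasible proportion_shift: ", eff$target_type, " would reach ",
             signif(p_new, 3))
      }
    }
  }
  invisible(cfg)
}

# apply proportion_shift effects for one condition to a baseline vector
shifted_baseline <- function(base, effects, condition, labels) {
  for (eff in effects) {
    if (eff$kind != "proportion_shift" || eff$condition != condition) next
    if (!eff$target_type %in% labels) next
    p_old <- base[[eff$target_type]]
    p_new <- p_old * 2^eff$log2fc
    if (p_new >= 1) stop("infeasible proportion shift for ", eff$target_type)
    others <- setdiff(names(base), eff$target_type)
    base[others] <- base[others] * (1 - p_new) / (1 - p_old)
    base[[eff$target_type]] <- p_new
  }
  base
}

#' Generate a synthetic cohort
#'
#' Draws the full cohort described by `config` from a single seeded RNG
#' stream in a fixed order (gene abundances, then per condition/donor: major
#' types, neuronal subtypes, low-quality flags, depths, counts), so two calls
#' with the same config yield identical datasets. Returns the dataset and a
#' ground-truth table recording every planted effect as realized.
#'
#' @param config a [cohort_config()]
#' @return list with elements `dataset` (a `CellDataset`) and `truth`
#'   (data.frame of realized planted effects)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  genes <- gene_universe(config$n_genes)
  n_genes <- config$n_genes
  is_mito <- genes %in% MITO_GENES

  # gene relative abundances: log-normal, mitochondrial share pinned
  rel <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  rel <- pin_mito_share(rel, is_mito, config$mito_share)
  rel_lowq <- pin_mito_share(rel, is_mito, config$lowq_mito_share)

  expr_effects <- Filter(function(e) e$kind == "expression_shift", config$planted_effects)
  blocks <- list(); cells_list <- list()
  truth_rows <- list()
  shift_cells <- integer(length(expr_effects))

  cell_counter <- 0L
  for (cond in CONDITIONS) {
    nd <- config$n_donors[[cond]]
    major_p <- shifted_baseline(config$major_type_baseline, config$planted_effects,
                                cond, MAJOR_TYPES)
    sub_p <- shifted_baseline(config$neuron_subtype_baseline, config$planted_effects,
                              cond, NEURON_SUBTYPES)
    for (d in seq_len(nd)) {
      nc <- config$cells_per_donor
      donor <- sprintf("%s_D%02d", cond, d)
      major <- sample(MAJOR_TYPES, nc, replace = TRUE, prob = major_p)
      subtype <- rep(NA_character_, nc)
      is_neuron <- major == "Neurons"
      if (any(is_neuron)) {
        subtype[is_neuron] <- sample(NEURON_SUBTYPES, sum(is_neuron),
                                     replace = TRUE, prob = sub_p)
      }
      lowq <- stats::runif(nc) < config$lowq_frac
      depth <- stats::rlnorm(nc, config$depth_meanlog, config$depth_sdlog)
      depth[lowq] <- depth[lowq] * config$lowq_depth_factor

      # per-cell NB means: abundance profile scaled to the cell's depth
      mu <- rel %o% (depth / sum(rel))
      if (any(lowq)) mu[, lowq] <- rel_lowq %o% (depth[lowq] / sum(rel_lowq))
      for (k in seq_along(expr_effects)) {
        eff <- expr_effects[[k]]
        if (eff$condition != cond) next
        sel <- rep(TRUE, nc)
        if (!is.null(eff$major_type)) sel <- sel & major %in% eff$major_type
        if (!is.null(eff$subtype)) sel <- sel & !is.na(subtype) & subtype %in% eff$subtype
        gi <- match(intersect(eff$genes, genes), genes)
        if (any(sel) && length(gi)) {
          mu[gi, sel] <- mu[gi, sel] * 2^eff$log2fc
          shift_cells[k] <- shift_cells[k] + sum(sel)
        }
      }
      cnt <- matrix(stats::rnbinom(n_genes * nc, mu = mu,
                                   size = 1 / config$nb_dispersion),
                    nrow = n_genes)
      blocks[[donor]] <- methods::as(cnt, "CsparseMatrix")
      cells_list[[donor]] <- data.frame(
        barcode = sprintf("%s_C%04d", donor, seq_len(nc)),
        donor_id = donor, condition = cond, major_type = major,
        neuron_subtype = subtype, low_quality = lowq,
        stringsAsFactors = FALSE)
      cell_counter <- cell_counter + nc
    }
  }

  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- cells$barcode
  colnames(counts) <- cells$barcode
  cells$barcode <- NULL

  for (k in seq_along(expr_effects)) {
    eff <- expr_effects[[k]]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      kind = "expression_shift", condition = eff$condition,
      target = paste(eff$genes, collapse = ";"),
      selector = paste(c(eff$major_type, eff$subtype), collapse = ";"),
      log2fc = eff$log2fc, n_cells = shift_cells[k], stringsAsFactors = FALSE)
  }
  for (eff in Filter(function(e) e$kind == "proportion_shift", config$planted_effects)) {
    labels <- if (eff$target_type %in% MAJOR_TYPES) MAJOR_TYPES else NEURON_SUBTYPES
    base <- if (identical(labels, MAJOR_TYPES)) config$major_type_baseline else
      config$neuron_subtype_baseline
    shifted <- shifted_baseline(base, list(eff), eff$condition, labels)
    n_real <- if (identical(labels, MAJOR_TYPES)) {
      sum(cells$condition == eff$condition & cells$major_type == eff$target_type)
    } else {
      sum(cells$condition == eff$condition &
            !is.na(cells$neuron_subtype) & cells$neuron_subtype == eff$target_type)
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      kind = "proportion_shift", condition = eff$condition,
      target = eff$target_type, selector = "",
      log2fc = eff$log2fc, n_cells = n_real,
      baseline_prop = unname(base[[eff$target_type]]),
      planted_prop = unname(shifted[[eff$target_type]]),
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) {
    do.call(rbind, lapply(truth_rows, function(r) {
      r$baseline_prop <- if ("baseline_prop" %in% names(r)) r$baseline_prop else NA_real_
      r$planted_prop <- if ("planted_prop" %in% names(r)) r$planted_prop else NA_real_
      r
    }))
  } else {
    data.frame(kind = character(), condition = character(), target = character(),
               selector = character(), log2fc = numeric(), n_cells = integer(),
               baseline_prop = numeric(), planted_prop = numeric())
  }

  ds <- cell_dataset(counts, cells = cells)
  list(dataset = ds, truth = truth)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# rescale abundances so the mitochondrial genes carry exactly `share` of mass
pin_mito_share <- function(rel, is_mito, share) {
  m <- sum(rel[is_mito]); o <- sum(rel[!is_mito])
  rel[is_mito] <- rel[is_mito] / m * share
  rel[!is_mito] <- rel[!is_mito] / o * (1 - share)
  rel
}

#' Synthetic ligand-receptor pair table
#'
#' Draws decoy ligand/receptor pairs from the cohort's gene universe, with
#' optional known pairs prepended (deduplicated). Used to exercise the
#' interactome stage without a curated database.
#'
#' @param n_genes gene universe size (must match the cohort config)
#' @param n_pairs number of decoy pairs
#' @param planted optional data.frame with columns ligand, receptor placed
#'   at the head of the table
#' @param seed RNG seed
#' @return data.frame with columns ligand, receptor, source
#' @export
synthetic_lr_pairs <- function(n_genes = 2000, n_pairs = 200, planted = NULL,
                               seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  genes <- gene_universe(n_genes)
  pool <- setdiff(genes, MITO_GENES)
  lig <- sample(pool, n_pairs, replace = TRUE)
  rec <- sample(pool, n_pairs, replace = TRUE)
  tab <- data.frame(ligand = toupper(lig), receptor = toupper(rec),
                    source = "synthetic", stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    planted$source <- "planted"
    tab <- rbind(planted[, c("ligand", "receptor", "source")], tab)
  }
  tab[!duplicated(tab[c("ligand", "receptor")]), , drop = FALSE]
}
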