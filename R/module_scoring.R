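# Per-nucleus gene-module scoring with expression-binned control genes, the
# composite apoptosis trigger score, ApopHigh classification and the
# condition/subtype/donor summaries built on it.

REQUIRED_MODULES <- c("apoptosis", "p53", "dna_repair", "upr", "survival")

#' Score a gene module per cell against expression-matched controls
#'
#' Genes are ranked by their mean log-normalized expression across cells and
#' cut into `n_bins` near-equal-size bins. For every module gene, `n_ctrl`
#' control genes are drawn from the same bin (excluding module genes;
#' without replacement when the bin is large enough, with replacement
#' otherwise). The per-cell score is the mean log-normalized expression of
#' the module genes minus the mean over the pooled control draw (a multiset:
#' genes drawn repeatedly are weighted accordingly). Deterministic given
#' `seed`; the caller's RNG stream is left untouched.
#'
#' @param ds a `CellDataset` with the lognorm layer present
#' @param gene_set character vector of module gene symbols; symbols absent
#'   from the dataset are dropped with a warning
#' @param n_bins number of mean-expression bins (default 24)
#' @param n_ctrl control genes sampled per module gene (default 100)
#' @param seed integer seed for the control draw
#' @return numeric per-cell score vector (named by barcode)
#' @export
score_gene_module <- function(ds, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(ds, "CellDataset"))
  if (is.null(ds$lognorm)) stop("lognorm layer missing; run log_normalize() first")
  genes <- rownames(ds$lognorm)
  if (n_bins > length(genes)) stop("n_bins exceeds the number of genes")
  present <- intersect(gene_set, genes)
  if (!length(present)) {
    stop("none of the module genes are present in the dataset")
  }
  if (length(present) < length(unique(gene_set))) {
    warning(length(unique(gene_set)) - length(present),
            " module gene(s) absent from the dataset; dropped")
  }

  avg <- Matrix::rowMeans(ds$lognorm)
  # near-equal-size bins over the expression ranking (ties broken by order)
  ord <- order(avg, seq_along(avg))
  bin <- integer(length(avg))
  bin[ord] <- ceiling(seq_along(avg) * n_bins / length(avg))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  set_idx <- match(present, genes)
  ctrl_idx <- integer(0)
  for (gi in set_idx) {
    pool <- which(bin == bin[gi])
    pool <- setdiff(pool, set_idx)
    if (!length(pool)) {
      stop("no control genes available in bin ", bin[gi],
           "; decrease n_bins or enlarge the gene universe")
    }
    draw <- if (length(pool) >= n_ctrl) sample(pool, n_ctrl) else
      sample(pool, n_ctrl, replace = TRUE)
    ctrl_idx <- c(ctrl_idx, draw)
  }

  set_mean <- Matrix::colMeans(ds$lognorm[set_idx, , drop = FALSE])
  # pooled control multiset: repeated draws keep their multiplicity
  tab <- table(ctrl_idx)
  w <- as.numeric(tab)
  rows <- as.integer(names(tab))
  ctrl_mean <- as.numeric(w %*% ds$lognorm[rows, , drop = FALSE]) / sum(w)
  score <- set_mean - ctrl_mean
  names(score) <- colnames(ds$lognorm)
  score
}

#' Composite apoptosis trigger score
#'
#' `apoptosis + p53 + dna_repair + upr - survival`, elementwise over per-cell
#' module scores.
#'
#' @param scores named list (or data.frame) holding the five module score
#'   vectors, equal length
#' @return numeric per-cell trigger score
#' @export
apoptosis_trigger_score <- function(scores) {
  missing <- setdiff(REQUIRED_MODULES, names(scores))
  if (length(missing)) {
    stop("missing module score(s): ", paste(missing, collapse = ", "))
  }
  len <- unique(vapply(REQUIRED_MODULES, function(m) length(scores[[m]]), 1L))
  if (length(len) != 1L) stop("module score vectors must have equal length")
  scores$apoptosis + scores$p53 + scores$dna_repair + scores$upr - scores$survival
}

#' Classify cells as ApopHigh / ApopLow
#'
#' The threshold is the linear-interpolation `quantile` of the pooled trigger
#' scores (computed once over all cells supplied, never per condition); cells
#' at or above the threshold are ApopHigh.
#'
#' @param trigger numeric per-cell trigger scores
#' @param quantile pooled quantile defining the threshold (default 0.90)
#' @return character vector of "ApopHigh"/"ApopLow" labels, plus attributes
#'   `threshold` and `quantile`
#' @export
classify_apop_high <- function(trigger, quantile = 0.90) {
  if (!length(trigger)) stop("empty score vector")
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0, 1)")
  thr <- stats::quantile(trigger, probs = quantile, names = FALSE, type = 7)
  labels <- ifelse(trigger >= thr, "ApopHigh", "ApopLow")
  if (all(labels == "ApopHigh")) {
    warning("trigger score is constant: every cell is at the threshold and ",
            "labeled ApopHigh")
  }
  attr(labels, "threshold") <- thr
  attr(labels, "quantile") <- quantile
  labels
}

#' Score the apoptosis-priming composite for a dataset
#'
#' Convenience wrapper: scores the five modules, forms the trigger score and
#' the ApopHigh classification, and returns one table carrying the cell
#' annotations. By default scoring and the ApopHigh threshold are restricted
#' to neurons (`cell_mask`), mirroring a pooled-across-conditions 90th
#' percentile over all neurons.
#'
#' @param ds a log-normalized `CellDataset`
#' @param modules named list with the five required module gene sets
#' @param cell_mask logical/integer cell selector; `NULL` selects neurons via
#'   `major_type == "Neurons"` when that annotation exists, else all cells
#' @param quantile ApopHigh threshold quantile (default 0.90)
#' @param n_bins,n_ctrl control-gene binning parameters
#' @param seed seed for control sampling
#' @return data.frame (class `module_score_table`): barcode, annotations,
#'   one column per module, `trigger_score`, `apop_class`
#' @export
score_apoptosis <- function(ds, modules, cell_mask = NULL, quantile = 0.90,
                            n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(ds, "CellDataset"))
  missing <- setdiff(REQUIRED_MODULES, names(modules))
  if (length(missing)) stop("modules must include: ", paste(missing, collapse = ", "))
  if (is.null(cell_mask)) {
    cell_mask <- if (!is.null(ds$cells$major_type)) {
      ds$cells$major_type == "Neurons"
    } else rep(TRUE, ncol(ds$counts))
  }
  sub <- subset_cells(ds, cells = cell_mask)
  if (!ncol(sub$counts)) stop("cell mask selects no cells")

  score_cols <- lapply(REQUIRED_MODULES, function(m) {
    score_gene_module(sub, modules[[m]], n_bins = n_bins, n_ctrl = n_ctrl,
                      seed = seed)
  })
  names(score_cols) <- REQUIRED_MODULES
  trigger <- apoptosis_trigger_score(score_cols)
  labels <- classify_apop_high(trigger, quantile = quantile)

  out <- data.frame(barcode = colnames(sub$counts), stringsAsFactors = FALSE)
  for (col in c("donor_id", "condition", "major_type", "neuron_subtype")) {
    if (!is.null(sub$cells[[col]])) out[[col]] <- sub$cells[[col]]
  }
  for (m in REQUIRED_MODULES) out[[m]] <- unname(score_cols[[m]])
  out$trigger_score <- unname(trigger)
  out$apop_class <- as.character(labels)
  attr(out, "threshold") <- attr(labels, "threshold")
  class(out) <- c("module_score_table", "data.frame")
  out
}

#' @export
print.module_score_table <- function(x, ...) {
  cat("module_score_table:", nrow(x), "cells; ApopHigh fraction",
      format(mean(x$apop_class == "ApopHigh"), digits = 3),
      "(threshold", format(attr(x, "threshold"), digits = 4), ")\n")
  NextMethod()
}

#' Summarize ApopHigh proportions by group
#'
#' One row per group with the total cell count, ApopHigh count and
#' `prop_high = n_high / total`. Groups with zero cells are omitted.
#'
#' @param table a `module_score_table` (or data.frame with `apop_class`)
#' @param by grouping: "condition", "subtype_condition" or "donor_condition"
#' @return data.frame with grouping columns, `total`, `n_high`, `prop_high`
#' @export
apop_high_summary <- function(table,
                              by = c("condition", "subtype_condition",
                                     "donor_condition")) {
  by <- match.arg(by)
  stopifnot("apop_class" %in% names(table))
  keys <- switch(by,
    condition = "condition",
    subtype_condition = c("neuron_subtype", "condition"),
    donor_condition = c("donor_id", "condition"))
  for (k in keys) {
    if (is.null(table[[k]])) stop("grouping column missing: ", k)
  }
  df <- table[!Reduce(`|`, lapply(keys, function(k) is.na(table[[k]]))), , drop = FALSE]
  grp <- interaction(df[keys], drop = TRUE, sep = "\r")
  total <- as.integer(table(grp))
  n_high <- as.integer(tapply(df$apop_class == "ApopHigh", grp, sum))
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- keys
  out$total <- total
  out$n_high <- n_high
  out$prop_high <- n_high / total
  rownames(out) <- NULL
  out
}

#' Donor-level condition test on ApopHigh proportions
#'
#' Kruskal-Wallis omnibus across the three conditions on donor-level
#' `prop_high`, followed by pairwise Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment. A condition with fewer than two donors is
#' dropped from the omnibus with a warning.
#'
#' @param summary a donor x condition table from
#'   `apop_high_summary(..., by = "donor_condition")`
#' @return list with `omnibus` (an `np_test`) and `pairwise` (data.frame of
#'   comparisons with p and BH-adjusted p)
#' @export
donor_condition_test <- function(summary) {
  stopifnot(all(c("condition", "prop_high") %in% names(summary)))
  groups <- split(summary$prop_high, summary$condition)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    warning("condition(s) with < 2 donors dropped from the omnibus test: ",
            paste(names(groups)[sizes < 2L], collapse = ", "))
    groups <- groups[sizes >= 2L]
  }
  if (length(groups) < 2L) stop("need at least two conditions with >= 2 donors")
  omnibus <- kruskal_wallis(groups)

  combos <- utils::combn(names(groups), 2L)
  pw <- data.frame(
    group_a = combos[1L, ], group_b = combos[2L, ],
    p = apply(combos, 2L, function(cc) {
      wilcoxon_rank_sum(groups[[cc[1L]]], groups[[cc[2L]]])$p_value
    }), stringsAsFactors = FALSE)
  pw$p_adj <- benjamini_hochberg(pw$p)
  list(omnibus = omnibus, pairwise = pw)
}
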