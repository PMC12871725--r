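# Permutation-based cell-type proportion comparison between two conditions,
# with percentile-bootstrap confidence intervals, BH correction over the cell
# types of one run, and the nodule-adjacency fold-change arithmetic.
#
# Cells (not donors) are the permutation unit, matching the design of the
# permutation proportion tests commonly used on single-cell data;
# donor-level replication is addressed separately by donor_condition_test().

# shared guts: per-type counts and the epsilon-guarded log2 fold difference
prop_log2fd <- function(count_a, count_b, n_a, n_b, eps) {
  log2((count_b / n_b + eps) / (count_a / n_a + eps))
}

prop_setup <- function(cells, cond_a, cond_b, cluster_field) {
  if (is.null(cells[[cluster_field]])) {
    stop("cluster_field '", cluster_field, "' not found in the annotation table")
  }
  if (is.null(cells$condition)) stop("annotation table lacks a condition column")
  sel <- cells$condition %in% c(cond_a, cond_b) & !is.na(cells[[cluster_field]])
  df <- cells[sel, , drop = FALSE]
  for (cond in c(cond_a, cond_b)) {
    if (!sum(df$condition == cond)) stop("condition has no cells: ", cond)
  }
  types <- sort(unique(as.character(df[[cluster_field]])))
  list(type = factor(as.character(df[[cluster_field]]), levels = types),
       in_b = df$condition == cond_b, types = types)
}

#' Per-type proportions and log2 fold difference between two conditions
#'
#' `obs_log2FD = log2((prop_b + eps) / (prop_a + eps))` with the
#' Haldane-style guard `eps = 1 / (2 * min(n_a, n_b))`, so types absent from
#' one condition stay finite. Positive values mean higher abundance in
#' `cond_b`.
#'
#' @param cells per-cell annotation data.frame with a `condition` column
#' @param cond_a,cond_b condition labels to compare
#' @param cluster_field annotation column holding the cell-type labels
#' @return data.frame: cell_type, n_a, n_b, prop_a, prop_b, obs_log2FD
#' @export
proportion_estimates <- function(cells, cond_a, cond_b, cluster_field) {
  s <- prop_setup(cells, cond_a, cond_b, cluster_field)
  n_b <- sum(s$in_b); n_a <- length(s$in_b) - n_b
  eps <- 1 / (2 * min(n_a, n_b))
  cnt_a <- as.integer(table(s$type[!s$in_b]))
  cnt_b <- as.integer(table(s$type[s$in_b]))
  data.frame(
    cell_type = s$types, n_a = cnt_a, n_b = cnt_b,
    prop_a = cnt_a / n_a, prop_b = cnt_b / n_b,
    obs_log2FD = prop_log2fd(cnt_a, cnt_b, n_a, n_b, eps),
    stringsAsFactors = FALSE)
}

#' Permutation p-values for per-type proportion shifts
#'
#' Condition labels are shuffled over cells `n_perm` times holding the two
#' condition totals fixed; the two-sided p-value per type is
#' `(1 + #(|perm log2FD| >= |obs|)) / (1 + n_perm)`.
#'
#' @inheritParams proportion_estimates
#' @param n_perm number of permutations (default 1000; < 100 warns)
#' @param seed RNG seed
#' @return data.frame: cell_type, obs_log2FD, p_perm
#' @export
permutation_test <- function(cells, cond_a, cond_b, cluster_field,
                             n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("n_perm < 100 gives poor p-value resolution")
  s <- prop_setup(cells, cond_a, cond_b, cluster_field)
  n <- length(s$in_b); n_b <- sum(s$in_b); n_a <- n - n_b
  k <- length(s$types)
  eps <- 1 / (2 * min(n_a, n_b))
  ti <- as.integer(s$type)
  tot <- tabulate(ti, k)
  obs_b <- tabulate(ti[s$in_b], k)
  obs <- prop_log2fd(tot - obs_b, obs_b, n_a, n_b, eps)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  exceed <- integer(k)
  for (i in seq_len(n_perm)) {
    idx_b <- sample.int(n, n_b)
    cb <- tabulate(ti[idx_b], k)
    perm <- prop_log2fd(tot - cb, cb, n_a, n_b, eps)
    exceed <- exceed + (abs(perm) >= abs(obs) - 1e-12)
  }
  data.frame(cell_type = s$types, obs_log2FD = obs,
             p_perm = (1 + exceed) / (1 + n_perm), stringsAsFactors = FALSE)
}

#' Percentile-bootstrap confidence interval for the proportion log2FD
#'
#' Cells are resampled with replacement within each condition; the interval
#' is the percentile interval of the resampled log2FD at `level`.
#'
#' @inheritParams proportion_estimates
#' @param n_boot bootstrap replicates (default 1000)
#' @param level interval coverage (default 0.95)
#' @param seed RNG seed
#' @return data.frame: cell_type, ci_low, ci_high
#' @export
bootstrap_ci <- function(cells, cond_a, cond_b, cluster_field,
                         n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(level > 0, level < 1)
  s <- prop_setup(cells, cond_a, cond_b, cluster_field)
  k <- length(s$types)
  ti <- as.integer(s$type)
  ti_a <- ti[!s$in_b]; ti_b <- ti[s$in_b]
  n_a <- length(ti_a); n_b <- length(ti_b)
  eps <- 1 / (2 * min(n_a, n_b))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, k)
  for (i in seq_len(n_boot)) {
    ca <- tabulate(ti_a[sample.int(n_a, n_a, replace = TRUE)], k)
    cb <- tabulate(ti_b[sample.int(n_b, n_b, replace = TRUE)], k)
    boots[i, ] <- prop_log2fd(ca, cb, n_a, n_b, eps)
  }
  lo <- (1 - level) / 2
  ci <- apply(boots, 2L, stats::quantile, probs = c(lo, 1 - lo), names = FALSE)
  data.frame(cell_type = s$types, ci_low = ci[1L, ], ci_high = ci[2L, ],
             stringsAsFactors = FALSE)
}

#' Adjust and classify proportion-shift results
#'
#' BH adjustment over the per-type permutation p-values of one run;
#' `significant` requires both `p_adj < fdr` and `|obs_log2FD| >
#' lfc_threshold`. The default magnitude threshold is 0.585 (log2 of 1.5); a
#' laxer 0.42 variant is used for major-class comparisons.
#'
#' @param results data.frame with `p_perm` and `obs_log2FD`
#' @param fdr FDR level (default 0.05)
#' @param lfc_threshold |log2FD| threshold (default 0.585)
#' @return `results` with `p_adj` and `significant` columns
#' @export
classify_shift <- function(results, fdr = 0.05, lfc_threshold = 0.585) {
  stopifnot(nrow(results) >= 1, all(c("p_perm", "obs_log2FD") %in% names(results)))
  results$p_adj <- benjamini_hochberg(results$p_perm)
  results$significant <- results$p_adj < fdr &
    abs(results$obs_log2FD) > lfc_threshold
  results
}

#' Full proportion comparison between two conditions
#'
#' Runs [proportion_estimates()], [permutation_test()], [bootstrap_ci()] and
#' [classify_shift()] in one call.
#'
#' @inheritParams proportion_estimates
#' @inheritParams permutation_test
#' @inheritParams bootstrap_ci
#' @inheritParams classify_shift
#' @return data.frame (class `prop_test`) with one row per cell type
#' @export
proportion_test <- function(cells, cond_a, cond_b, cluster_field,
                            n_perm = 1000, n_boot = 1000, level = 0.95,
                            fdr = 0.05, lfc_threshold = 0.585, seed = 1L) {
  est <- proportion_estimates(cells, cond_a, cond_b, cluster_field)
  perm <- permutation_test(cells, cond_a, cond_b, cluster_field,
                           n_perm = n_perm, seed = seed)
  ci <- bootstrap_ci(cells, cond_a, cond_b, cluster_field,
                     n_boot = n_boot, level = level, seed = seed + 1L)
  out <- merge(merge(est, perm[c("cell_type", "p_perm")], by = "cell_type"),
               ci, by = "cell_type")
  out <- classify_shift(out, fdr = fdr, lfc_threshold = lfc_threshold)
  attr(out, "comparison") <- paste(cond_a, "vs", cond_b)
  class(out) <- c("prop_test", "data.frame")
  out
}

#' @export
print.prop_test <- function(x, ...) {
  cat("Proportion test", attr(x, "comparison"), "-",
      sum(x$significant), "of", nrow(x), "types significant\n")
  NextMethod()
}

#' Nodule-adjacency proportion fold changes
#'
#' For neurons grouped as control / DPN nodule-adjacent / DPN non-adjacent,
#' computes each neuron type's mean within-sample proportion per group (or
#' the pooled proportion when no `sample_id` column exists) and the fold
#' change of the two DPN groups versus control, with the same epsilon guard
#' as the proportion tests (`eps = 1 / (2 * min group size)`).
#'
#' @param neurons data.frame with columns `group` (control, dpn_adjacent,
#'   dpn_nonadjacent), `neuron_type`, and optionally `sample_id`
#' @return data.frame: neuron_type, the three group proportions,
#'   fc_adjacent, fc_nonadjacent
#' @export
nodule_adjacency_fold_change <- function(neurons) {
  need <- c("control", "dpn_adjacent", "dpn_nonadjacent")
  stopifnot(all(c("group", "neuron_type") %in% names(neurons)))
  if (!all(need %in% neurons$group)) {
    stop("all three groups must be non-empty: ", paste(need, collapse = ", "))
  }
  types <- sort(unique(neurons$neuron_type))
  group_prop <- function(df) {
    if (!is.null(df$sample_id)) {
      per <- lapply(split(df, df$sample_id), function(s) {
        as.numeric(table(factor(s$neuron_type, levels = types))) / nrow(s)
      })
      rowMeans(do.call(cbind, per))
    } else {
      as.numeric(table(factor(df$neuron_type, levels = types))) / nrow(df)
    }
  }
  props <- sapply(need, function(g) group_prop(neurons[neurons$group == g, , drop = FALSE]))
  eps <- 1 / (2 * min(table(neurons$group)))
  absent <- rowSums(props) == 0
  if (any(absent)) {
    warning("neuron type(s) absent everywhere dropped: ",
            paste(types[absent], collapse = ", "))
    props <- props[!absent, , drop = FALSE]
    types <- types[!absent]
  }
  data.frame(
    neuron_type = types,
    prop_control = props[, "control"],
    prop_adjacent = props[, "dpn_adjacent"],
    prop_nonadjacent = props[, "dpn_nonadjacent"],
    fc_adjacent = (props[, "dpn_adjacent"] + eps) / (props[, "control"] + eps),
    fc_nonadjacent = (props[, "dpn_nonadjacent"] + eps) / (props[, "control"] + eps),
    row.names = NULL, stringsAsFactors = FALSE)
}
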