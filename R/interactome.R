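# Ligand -> receptor interactome: eligibility filtering on the three
# published criteria (differential expression of either gene, no opposite
# directions, expression floors for receptor and ligand), composite scoring
# and top-k ranking with a Sankey-ready export.

COMPARISONS <- c("control_vs_diabetic", "diabetic_vs_dpn", "control_vs_dpn")

#' Load a ligand-receptor pair table
#'
#' TSV with header columns `ligand` and `receptor` (a `source` column is
#' carried through if present). Symbols are upper-cased and duplicate pairs
#' dropped.
#'
#' @param path TSV file
#' @return data.frame: ligand, receptor, source
#' @export
load_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  for (col in c("ligand", "receptor")) {
    if (is.null(tab[[col]])) stop("ligand-receptor table lacks column: ", col)
  }
  tab$ligand <- toupper(trimws(tab$ligand))
  tab$receptor <- toupper(trimws(tab$receptor))
  if (is.null(tab$source)) tab$source <- rep(NA_character_, nrow(tab))
  tab <- tab[!duplicated(tab[c("ligand", "receptor")]),
             c("ligand", "receptor", "source"), drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Pseudobulk log-normalized expression per neuronal population
#'
#' Counts are summed over the cells of every population, then each
#' pseudobulk column is log-normalized (natural log, scale 1e4). These
#' values feed the receptor floor (>= 0.01 in at least one population).
#'
#' @param ds a `CellDataset`
#' @param subtype_field annotation column holding population labels
#'   (default `neuron_subtype`)
#' @return gene x population matrix of log-normalized pseudobulk values
#' @export
receptor_population_expression <- function(ds, subtype_field = "neuron_subtype") {
  stopifnot(inherits(ds, "CellDataset"))
  labels <- ds$cells[[subtype_field]]
  if (is.null(labels)) stop("annotation column missing: ", subtype_field)
  keep <- !is.na(labels)
  if (!any(keep)) stop("no cells carry a population label")
  sub <- subset_cells(ds, cells = keep)
  pb <- pseudobulk_aggregate(sub, subtype_field)
  m <- pb$counts
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("population(s) with zero counts dropped: ",
            paste(colnames(m)[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
  }
  log1p(sweep(m, 2L, colSums(m), "/") * 1e4)
}

#' Mean ligand expression per non-neuronal major type
#'
#' Used to name the best (argmax mean log-normalized expression) non-neuronal
#' source cell type of each ligand.
#'
#' @param ds a log-normalized `CellDataset`
#' @return gene x major-type matrix of mean lognorm over non-neuronal types
#' @export
ligand_source_expression <- function(ds) {
  stopifnot(inherits(ds, "CellDataset"))
  if (is.null(ds$lognorm)) stop("lognorm layer missing")
  mt <- ds$cells$major_type
  if (is.null(mt)) stop("major_type annotation missing")
  types <- setdiff(sort(unique(mt)), "Neurons")
  sapply(types, function(tt) {
    Matrix::rowMeans(ds$lognorm[, mt == tt, drop = FALSE])
  })
}

# per-gene percent-expressed within a mask, split by condition
pct_by_condition <- function(ds, cell_mask) {
  conds <- intersect(CONDITIONS, unique(ds$cells$condition[cell_mask]))
  sapply(conds, function(cc) {
    m <- cell_mask & ds$cells$condition == cc
    pct_expressed_rows(ds$counts, m)
  })
}

de_lookup <- function(de_tables, comparison, gene) {
  tab <- de_tables[[comparison]]
  i <- match(gene, tab$gene)
  if (is.na(i)) return(list(log2FC = 0, p_adj = 1, absent = TRUE))
  list(log2FC = tab$log2FC[i], p_adj = tab$p_adj[i], absent = FALSE)
}

#' Filter ligand-receptor pairs into per-comparison interaction records
#'
#' One record per (pair, comparison) with per-criterion flags:
#' \describe{
#'   \item{C1}{ligand differentially expressed among all DRG cells with
#'     `p_adj < alpha`, or receptor differentially expressed among neurons
#'     with `p_adj < alpha`, in that comparison.}
#'   \item{C2}{ligand and receptor are not both significant with opposite
#'     log2FC signs in that comparison.}
#'   \item{C3a}{receptor pseudobulk log-normalized expression >= 0.01 in at
#'     least one neuronal population.}
#'   \item{C3b}{receptor expressed in >= 5\% of all neurons in at least one
#'     condition.}
#'   \item{C3c}{ligand expressed in >= 0.1\% of all DRG cells in at least
#'     one condition.}
#' }
#' `eligible` is the conjunction. Genes absent from a DE table are treated
#' as not differentially expressed (`p_adj = 1`) and flagged.
#'
#' @param pairs data.frame with `ligand`, `receptor` columns
#' @param de_nonneuronal named list of DE tables (all-DRG-cell comparisons),
#'   names from `control_vs_diabetic`, `diabetic_vs_dpn`, `control_vs_dpn`
#' @param de_neuronal named list of DE tables over neurons, same names
#' @param pop_expr gene x population matrix from
#'   [receptor_population_expression()]
#' @param pct_ligand_by_condition gene x condition percent-expressed matrix
#'   over all DRG cells
#' @param pct_receptor_by_condition gene x condition matrix over neurons
#' @param alpha DE significance level for C1/C2 (default 0.05)
#' @param source_expr optional matrix from [ligand_source_expression()] used
#'   to annotate the best non-neuronal source type
#' @return data.frame of interaction records with per-criterion flags
#' @export
filter_interactions <- function(pairs, de_nonneuronal, de_neuronal, pop_expr,
                                pct_ligand_by_condition,
                                pct_receptor_by_condition,
                                alpha = 0.05, source_expr = NULL) {
  comparisons <- intersect(COMPARISONS, names(de_nonneuronal))
  if (!length(comparisons)) stop("no recognized comparison in de_nonneuronal")
  if (!all(comparisons %in% names(de_neuronal))) {
    stop("de_neuronal must cover the same comparisons as de_nonneuronal")
  }
  pair_idx <- rep(seq_len(nrow(pairs)), each = length(comparisons))
  comp <- rep(comparisons, times = nrow(pairs))

  row_of <- function(mat, gene) {
    i <- match(gene, rownames(mat))
    if (is.na(i)) rep(0, ncol(mat)) else mat[i, ]
  }
  recs <- vector("list", length(pair_idx))
  for (r in seq_along(pair_idx)) {
    lig <- pairs$ligand[pair_idx[r]]
    rec <- pairs$receptor[pair_idx[r]]
    cc <- comp[r]
    dl <- de_lookup(de_nonneuronal, cc, lig)
    dr <- de_lookup(de_neuronal, cc, rec)
    lig_sig <- dl$p_adj < alpha
    rec_sig <- dr$p_adj < alpha
    c1 <- lig_sig || rec_sig
    c2 <- !(lig_sig && rec_sig && sign(dl$log2FC) * sign(dr$log2FC) < 0)
    c3a <- max(row_of(pop_expr, rec)) >= 0.01
    rec_pct <- max(row_of(pct_receptor_by_condition, rec))
    lig_pct <- max(row_of(pct_ligand_by_condition, lig))
    c3b <- rec_pct >= 0.05
    c3c <- lig_pct >= 0.001
    src <- NA_character_
    if (!is.null(source_expr)) {
      v <- row_of(source_expr, lig)
      if (any(v > 0)) src <- colnames(source_expr)[which.max(v)]
    }
    recs[[r]] <- data.frame(
      ligand = lig, receptor = rec, comparison = cc,
      ligand_log2FC = dl$log2FC, ligand_p_adj = dl$p_adj,
      ligand_pct = lig_pct, ligand_absent = dl$absent,
      receptor_log2FC = dr$log2FC, receptor_p_adj = dr$p_adj,
      receptor_pct = rec_pct, receptor_absent = dr$absent,
      source_type = src,
      C1 = c1, C2 = c2, C3a = c3a, C3b = c3b, C3c = c3c,
      eligible = c1 && c2 && c3a && c3b && c3c,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# composite gene score: |log2FC| x (-log10 p_adj, floored) x percent expressed.
# the rank-score formula is a documented reconstruction from its three named
# ingredients; swap this function to try alternatives.
interaction_gene_score <- function(log2fc, p_adj, pct) {
  abs(log2fc) * (-log10(pmax(p_adj, 1e-300))) * pct
}

#' Score and rank eligible interactions
#'
#' Record score = ligand gene score + receptor gene score, where the gene
#' score is `|log2FC| * (-log10 max(p_adj, 1e-300)) * pct`. A pair's overall
#' score is the maximum over its per-comparison records; pairs are ranked by
#' descending overall score with ties broken lexicographically by
#' (ligand, receptor). The top-k export holds unique pairs only.
#'
#' @param records output of [filter_interactions()]
#' @param k number of top unique pairs to export (default 50)
#' @return list: `records` (with `score` and pair-level `rank`, `NA` for
#'   ineligible records) and `top` (top-k unique pairs, best record each)
#' @export
score_and_rank <- function(records, k = 50) {
  el <- records$eligible
  if (!any(el)) stop("no eligible interaction records to rank")
  records$score <- ifelse(
    el,
    interaction_gene_score(records$ligand_log2FC, records$ligand_p_adj,
                           records$ligand_pct) +
      interaction_gene_score(records$receptor_log2FC, records$receptor_p_adj,
                             records$receptor_pct),
    NA_real_)

  elig <- records[el, , drop = FALSE]
  key <- paste(elig$ligand, elig$receptor, sep = "\r")
  pair_score <- tapply(elig$score, key, max)
  pk <- names(pair_score)
  split_key <- do.call(rbind, strsplit(pk, "\r", fixed = TRUE))
  o <- order(-as.numeric(pair_score), split_key[, 1L], split_key[, 2L])
  pair_rank <- stats::setNames(seq_along(o), pk[o])

  records$rank <- NA_integer_
  rec_key <- paste(records$ligand, records$receptor, sep = "\r")
  records$rank[el] <- as.integer(pair_rank[rec_key[el]])

  if (k > length(pair_rank)) {
    warning("k = ", k, " exceeds the ", length(pair_rank),
            " eligible unique pairs; returning all")
    k <- length(pair_rank)
  }
  top_keys <- names(sort(pair_rank))[seq_len(k)]
  top <- do.call(rbind, lapply(top_keys, function(kk) {
    sub <- elig[key == kk, , drop = FALSE]
    sub[which.max(sub$score), , drop = FALSE]
  }))
  top$score <- as.numeric(pair_score[top_keys])
  top$rank <- as.integer(pair_rank[top_keys])
  rownames(top) <- NULL
  list(records = records, top = top)
}

#' Sankey-ready edge table from ranked interactions
#'
#' @param top the `top` table from [score_and_rank()]
#' @return data.frame: source_type, ligand, receptor, score
#' @export
sankey_edges <- function(top) {
  data.frame(source_type = ifelse(is.na(top$source_type), "DRG", top$source_type),
             ligand = top$ligand, receptor = top$receptor, score = top$score,
             stringsAsFactors = FALSE)
}

#' End-to-end interactome from a dataset and DE tables
#'
#' Computes the receptor population floor, the percent-expressed matrices
#' and the ligand source annotation from the dataset, then filters and ranks.
#'
#' @param ds a log-normalized `CellDataset` with `major_type` and
#'   `neuron_subtype` annotations
#' @param pairs ligand-receptor pair table
#' @param de_nonneuronal,de_neuronal named lists of DE tables per comparison
#' @param alpha DE significance level (default 0.05)
#' @param k top-k export size (default 50)
#' @return list: `records`, `top`, `sankey`
#' @export
build_interactome <- function(ds, pairs, de_nonneuronal, de_neuronal,
                              alpha = 0.05, k = 50) {
  neurons <- ds$cells$major_type == "Neurons"
  pop_expr <- receptor_population_expression(subset_cells(ds, cells = neurons))
  pct_lig <- pct_by_condition(ds, rep(TRUE, ncol(ds$counts)))
  pct_rec <- pct_by_condition(ds, neurons)
  src <- ligand_source_expression(ds)
  records <- filter_interactions(pairs, de_nonneuronal, de_neuronal, pop_expr,
                                 pct_lig, pct_rec, alpha = alpha,
                                 source_expr = src)
  ranked <- score_and_rank(records, k = k)
  c(ranked, list(sankey = sankey_edges(ranked$top)))
}
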