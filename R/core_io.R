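#' @importFrom Matrix readMM writeMM colSums rowSums rowMeans t sparseMatrix Diagonal
#' @importFrom methods as is
#' @importFrom stats quantile rnorm runif median var sd pchisq pnorm rbinom
#' @importFrom utils read.delim write.table combn head
NULL

# ---------------------------------------------------------------------------
# CellDataset: the universal carrier for counts + annotations
# ---------------------------------------------------------------------------

CONDITIONS <- c("Control", "Diabetic", "DPN")

#' Construct a CellDataset
#'
#' Bundles a sparse genes x cells count matrix with per-cell and per-gene
#' annotation tables, and optionally a log-normalized expression layer of the
#' same shape. This is the container every pipeline stage consumes.
#'
#' @param counts non-negative integer matrix (genes x cells); coerced to a
#'   sparse `dgCMatrix`. Row names are gene symbols, column names barcodes.
#' @param cells data.frame of per-cell annotations, one row per column of
#'   `counts`, in the same order. Recognised fields: `donor_id`, `condition`
#'   (one of Control/Diabetic/DPN), `major_type`, `neuron_subtype`,
#'   `nageotte_score` (in \[0, 5\]), `nodule_adjacent`.
#' @param genes data.frame of per-gene annotations, one row per row of
#'   `counts`. A logical `is_mito` column is added from the "MT-" symbol
#'   prefix if absent.
#' @param lognorm optional log-normalized layer, same shape as `counts`.
#' @return An object of class `CellDataset`.
#' @export
cell_dataset <- function(counts, cells = NULL, genes = NULL, lognorm = NULL) {
  counts <- methods::as(methods::as(as(counts, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("GENE%05d", seq_len(nrow(counts)))
  }
  rownames(counts) <- make_unique_symbols(rownames(counts))
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("CELL%06d", seq_len(ncol(counts)))
  }
  colnames(counts) <- make.unique(colnames(counts))
  if (is.null(cells)) cells <- data.frame(row.names = colnames(counts))
  if (is.null(genes)) genes <- data.frame(row.names = rownames(counts))
  if (nrow(cells) != ncol(counts)) {
    stop("cells table must have one row per matrix column (got ", nrow(cells),
         " rows for ", ncol(counts), " cells)")
  }
  if (nrow(genes) != nrow(counts)) {
    stop("genes table must have one row per matrix row")
  }
  rownames(cells) <- colnames(counts)
  rownames(genes) <- rownames(counts)
  if (!is.null(cells$condition)) {
    bad <- setdiff(unique(as.character(cells$condition)), CONDITIONS)
    if (length(bad)) {
      stop("unknown condition label(s): ", paste(bad, collapse = ", "),
           " (must be one of ", paste(CONDITIONS, collapse = "/"), ")")
    }
  }
  if (is.null(genes$is_mito)) {
    genes$is_mito <- startsWith(rownames(genes), "MT-")
  }
  if (!is.null(lognorm)) {
    lognorm <- methods::as(as(lognorm, "CsparseMatrix"), "generalMatrix")
    if (!identical(dim(lognorm), dim(counts))) {
      stop("lognorm layer must match the shape of counts")
    }
    dimnames(lognorm) <- dimnames(counts)
  }
  structure(list(counts = counts, lognorm = lognorm,
                 cells = cells, genes = genes),
            class = "CellDataset")
}

# duplicate symbols get ".1", ".2" suffixes (gene symbols are the primary key)
make_unique_symbols <- function(x) {
  if (!anyDuplicated(x)) return(x)
  warning("duplicate gene symbols found; suffixing with .1, .2, ...")
  stats::ave(x, x, FUN = function(v) {
    if (length(v) == 1L) v else c(v[1L], paste0(v[-1L], ".", seq_len(length(v) - 1L)))
  })
}

#' @export
dim.CellDataset <- function(x) dim(x$counts)

#' @export
print.CellDataset <- function(x, ...) {
  cat("CellDataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  layers: counts", if (!is.null(x$lognorm)) "+ lognorm" else "", "\n")
  if (ncol(x$cells)) {
    cat("  cell annotations:", paste(names(x$cells), collapse = ", "), "\n")
  }
  if (!is.null(x$cells$condition)) {
    tab <- table(x$cells$condition)
    cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a CellDataset by cells (and optionally genes)
#'
#' @param ds a `CellDataset`
#' @param cells logical/integer/character index over columns
#' @param genes logical/integer/character index over rows
#' @return the restricted `CellDataset`
#' @export
subset_cells <- function(ds, cells = NULL, genes = NULL) {
  stopifnot(inherits(ds, "CellDataset"))
  ci <- if (is.null(cells)) seq_len(ncol(ds$counts)) else cells
  gi <- if (is.null(genes)) seq_len(nrow(ds$counts)) else genes
  structure(list(
    counts  = ds$counts[gi, ci, drop = FALSE],
    lognorm = if (is.null(ds$lognorm)) NULL else ds$lognorm[gi, ci, drop = FALSE],
    cells   = ds$cells[ci, , drop = FALSE],
    genes   = ds$genes[gi, , drop = FALSE]
  ), class = "CellDataset")
}

# ---------------------------------------------------------------------------
# 10x triplet reader/writer
# ---------------------------------------------------------------------------

find_10x_file <- function(directory, base) {
  for (cand in c(file.path(directory, base), file.path(directory, paste0(base, ".gz")))) {
    if (file.exists(cand)) return(cand)
  }
  stop("10x input is missing required file '", base, "' (or '", base,
       ".gz') in ", directory)
}

#' Read a 10x-style triplet directory into a CellDataset
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (each optionally
#' gzipped). Features may carry one, two or three columns (id, symbol, type);
#' the symbol column (second if present, else first) becomes the gene key.
#' Mitochondrial genes are flagged by the case-sensitive "MT-" symbol prefix.
#'
#' @param directory path containing the three files
#' @param cells optional path to a cell annotation TSV (header row, first
#'   column barcode) to attach; row order is matched to the barcodes file.
#' @return a `CellDataset` with the counts layer populated
#' @export
read_counts_10x <- function(directory, cells = NULL) {
  mtx_path <- find_10x_file(directory, "matrix.mtx")
  feat_path <- find_10x_file(directory, "features.tsv")
  bc_path <- find_10x_file(directory, "barcodes.tsv")

  m <- Matrix::readMM(if (endsWith(mtx_path, ".gz")) gzfile(mtx_path) else mtx_path)
  feats <- utils::read.delim(feat_path, header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(bc_path, header = FALSE, stringsAsFactors = FALSE)[[1L]]

  if (nrow(feats) != nrow(m)) {
    stop("integrity error: features.tsv lists ", nrow(feats),
         " genes but matrix.mtx declares ", nrow(m), " rows")
  }
  if (length(bcs) != ncol(m)) {
    stop("integrity error: barcodes.tsv lists ", length(bcs),
         " cells but matrix.mtx declares ", ncol(m), " columns")
  }
  symbols <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
  rownames(m) <- symbols
  colnames(m) <- bcs

  ann <- NULL
  if (!is.null(cells)) {
    ann <- utils::read.delim(cells, header = TRUE, stringsAsFactors = FALSE)
    rownames(ann) <- ann[[1L]]
    ann <- ann[bcs, -1L, drop = FALSE]
  }
  cell_dataset(m, cells = ann)
}

#' Write a CellDataset as a 10x triplet directory
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and, when annotations
#' are present, `cells.tsv`. Plain text, UTF-8, LF line endings.
#'
#' @param ds a `CellDataset`
#' @param directory output directory (created if needed)
#' @return `directory`, invisibly
#' @export
write_counts_10x <- function(ds, directory) {
  stopifnot(inherits(ds, "CellDataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(directory, "matrix.mtx"))
  feats <- data.frame(id = rownames(ds$counts), symbol = rownames(ds$counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(directory, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE, eol = "\n")
  writeLines(colnames(ds$counts), file.path(directory, "barcodes.tsv"))
  if (ncol(ds$cells)) {
    out <- cbind(barcode = rownames(ds$cells), ds$cells)
    utils::write.table(out, file.path(directory, "cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, eol = "\n")
  }
  invisible(directory)
}

# ---------------------------------------------------------------------------
# GMT gene sets
# ---------------------------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' One set per line: name, description (discarded), then gene symbols,
#' tab-separated. Duplicate symbols within a set are dropped keeping the
#' first occurrence.
#'
#' @param path GMT file
#' @return a named list of character vectors (a `GeneSetCollection`)
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT format error at line ", i,
           ": expected at least name, description and one gene")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[fields[[1L]]]] <- unique(genes)
  }
  if (anyDuplicated(names(sets))) stop("GMT set names must be unique")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors
#' @param path output file
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# QC filter and log-normalization
# ---------------------------------------------------------------------------

#' Quality-control filter on detected genes and mitochondrial fraction
#'
#' Keeps cells with strictly more than `min_genes` detected genes (count > 0)
#' and strictly less than `max_mito_frac` of reads from mitochondrial genes.
#' Both inequalities are strict. Cells with zero total counts are removed and
#' tallied under the detected-genes criterion (their mito fraction is
#' undefined). The gene axis is unchanged.
#'
#' @param ds a `CellDataset`
#' @param min_genes detected-genes threshold (default 1000)
#' @param max_mito_frac mitochondrial read-fraction threshold (default 0.10)
#' @param verbose log how many cells each criterion removed
#' @return the filtered `CellDataset`
#' @export
qc_filter <- function(ds, min_genes = 1000, max_mito_frac = 0.10, verbose = TRUE) {
  stopifnot(inherits(ds, "CellDataset"), min_genes >= 0, max_mito_frac > 0)
  n_detected <- Matrix::colSums(ds$counts > 0)
  total <- Matrix::colSums(ds$counts)
  mito <- ds$genes$is_mito
  mito_counts <- if (any(mito)) Matrix::colSums(ds$counts[mito, , drop = FALSE]) else
    numeric(ncol(ds$counts))
  mito_frac <- ifelse(total > 0, mito_counts / total, NA_real_)

  pass_genes <- n_detected > min_genes & total > 0
  pass_mito <- !is.na(mito_frac) & mito_frac < max_mito_frac
  keep <- pass_genes & pass_mito
  if (verbose) {
    message(sprintf(
      "qc_filter: kept %d/%d cells (%d failed >%d detected genes, %d failed mito < %g)",
      sum(keep), length(keep), sum(!pass_genes), min_genes,
      sum(pass_genes & !pass_mito), max_mito_frac))
  }
  if (!any(keep)) warning("qc_filter removed every cell; returning an empty dataset")
  subset_cells(ds, cells = keep)
}

#' Log-normalize counts
#'
#' Per-cell depth normalization followed by a natural-log transform:
#' `lognorm[g, c] = ln(1 + counts[g, c] / total[c] * scale)`. The raw counts
#' layer is untouched.
#'
#' @param ds a `CellDataset` (every cell must have total count > 0)
#' @param scale depth scale factor (default 1e4)
#' @return the `CellDataset` with the `lognorm` layer populated
#' @export
log_normalize <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "CellDataset"))
  total <- Matrix::colSums(ds$counts)
  if (any(total == 0)) {
    stop("cells with zero total counts present; run qc_filter() first")
  }
  ln <- ds$counts
  # scale the x slot column-wise: entries of column j live at p[j]+1 .. p[j+1]
  percol <- diff(ln@p)
  ln@x <- log1p(ln@x / rep.int(total, percol) * scale)
  ds$lognorm <- ln
  ds
}

#' Fraction of cells expressing a gene
#'
#' @param ds a `CellDataset`
#' @param gene gene symbol
#' @param cell_mask logical or integer index over cells
#' @return fraction of masked cells with count > 0, in \[0, 1\]
#' @export
pct_expressed <- function(ds, gene, cell_mask = NULL) {
  stopifnot(inherits(ds, "CellDataset"))
  if (!gene %in% rownames(ds$counts)) stop("unknown gene: ", gene)
  if (is.null(cell_mask)) cell_mask <- seq_len(ncol(ds$counts))
  v <- ds$counts[gene, cell_mask]
  if (length(v) == 0L) stop("empty cell mask")
  mean(v > 0)
}

# row-wise fraction expressed for many genes at once (internal workhorse)
pct_expressed_rows <- function(counts, cell_mask) {
  sub <- counts[, cell_mask, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty cell mask")
  Matrix::rowSums(sub > 0) / ncol(sub)
}
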