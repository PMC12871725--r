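# Minimal in-repo differential-expression engines with a shared output
# schema: a per-cell rank-sum engine on log-normalized expression and a
# pseudobulk negative-binomial Wald engine with median-of-ratios size
# factors and method-of-moments shrunk dispersion. These are transparent
# stand-ins, not clones of published tools; downstream stages depend only on
# the schema (gene, log2FC, p, p_adj, pct_a, pct_b, class). Sign convention:
# positive log2FC means higher expression in the second-named condition.

#' Aggregate counts into pseudobulk profiles
#'
#' Sums counts over every combination of the annotation `keys`; group
#' metadata records the key values and cell counts. Total counts are
#' conserved exactly.
#'
#' @param ds a `CellDataset`
#' @param keys character vector of annotation columns to group by
#' @return list with `counts` (gene x group dense matrix) and `groups`
#'   (data.frame of key values + `n_cells`)
#' @export
pseudobulk_aggregate <- function(ds, keys) {
  stopifnot(inherits(ds, "CellDataset"), length(keys) >= 1)
  for (k in keys) {
    if (is.null(ds$cells[[k]])) stop("annotation key missing: ", k)
  }
  grp <- interaction(ds$cells[keys], drop = TRUE, sep = "\r", lex.order = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp),
                              x = 1, dims = c(length(grp), nlevels(grp)))
  pb <- as.matrix(ds$counts %*% ind)
  parts <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  groups <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(groups) <- keys
  groups$n_cells <- as.integer(table(grp))
  colnames(pb) <- apply(groups[keys], 1L, paste, collapse = ".")
  list(counts = pb, groups = groups)
}

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every group, the factor of a group is
#' the median of its counts divided by the gene-wise geometric mean;
#' factors are rescaled to geometric mean 1. With no all-nonzero gene,
#' library-size factors are used with a warning.
#'
#' @param pseudobulk gene x group count matrix (or a [pseudobulk_aggregate()]
#'   result)
#' @return named numeric vector of positive size factors
#' @export
size_factors_median_ratio <- function(pseudobulk) {
  m <- if (is.list(pseudobulk)) pseudobulk$counts else pseudobulk
  stopifnot(ncol(m) >= 2)
  use <- rowSums(m > 0) == ncol(m)
  if (!any(use)) {
    warning("no gene has nonzero counts in every group; ",
            "falling back to library-size factors")
    sf <- colSums(m)
  } else {
    lg <- log(m[use, , drop = FALSE])
    ref <- rowMeans(lg)                      # log geometric mean
    sf <- exp(apply(lg - ref, 2L, stats::median))
  }
  sf <- sf / exp(mean(log(sf)))              # geometric mean 1
  sf
}

#' Per-cell rank-sum differential expression
#'
#' For each gene, a two-sided Wilcoxon rank-sum p-value on log-normalized
#' expression between the two cell masks, `log2FC = log2((mean expm1 in b +
#' pc) / (mean expm1 in a + pc))`, percent-expressed per group, and BH
#' adjustment over the genes of this comparison.
#'
#' @param ds a log-normalized `CellDataset`
#' @param cell_mask_a,cell_mask_b logical or integer masks over cells
#' @param pseudocount stabilizer for the fold-change ratio (default 1e-9)
#' @param comparison label stored on the result
#' @return data.frame: gene, log2FC, p, p_adj, pct_a, pct_b
#' @export
de_rank_sum <- function(ds, cell_mask_a, cell_mask_b, pseudocount = 1e-9,
                        comparison = "a_vs_b") {
  stopifnot(inherits(ds, "CellDataset"))
  if (is.null(ds$lognorm)) stop("lognorm layer missing; run log_normalize() first")
  la <- ds$lognorm[, cell_mask_a, drop = FALSE]
  lb <- ds$lognorm[, cell_mask_b, drop = FALSE]
  if (!ncol(la) || !ncol(lb)) stop("both cell masks must select cells")

  mean_a <- Matrix::rowMeans(expm1_sparse(la))
  mean_b <- Matrix::rowMeans(expm1_sparse(lb))
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))

  n_genes <- nrow(la)
  p <- numeric(n_genes)
  da <- as.matrix(la)
  db <- as.matrix(lb)
  for (g in seq_len(n_genes)) {
    if (mean_a[g] == 0 && mean_b[g] == 0) {
      p[g] <- 1
    } else {
      p[g] <- wilcoxon_rank_sum(da[g, ], db[g, ])$p_value
    }
  }
  rm(da, db)
  lfc[mean_a == 0 & mean_b == 0] <- 0
  out <- data.frame(
    gene = rownames(la), log2FC = lfc, p = p,
    p_adj = benjamini_hochberg(p),
    pct_a = Matrix::rowSums(ds$counts[, cell_mask_a, drop = FALSE] > 0) / ncol(la),
    pct_b = Matrix::rowSums(ds$counts[, cell_mask_b, drop = FALSE] > 0) / ncol(lb),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  out
}

expm1_sparse <- function(m) {
  m@x <- expm1(m@x)
  m
}

# Newton/IRLS fit of log mu = offset + b0 + b1 x for one gene at fixed NB
# dispersion alpha; returns the Wald z-test on b1.
nb_wald_fit <- function(y, x, offset, alpha, max_iter = 25L, tol = 1e-8) {
  # Poisson-ish start
  b0 <- log(max(mean(y / exp(offset)), 1e-8))
  b1 <- 0
  for (it in seq_len(max_iter)) {
    eta <- offset + b0 + b1 * x
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)             # NB working weights
    z <- (y - mu) / mu                     # working residual on the link scale
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
    det <- sw * swxx - swx^2
    if (!is.finite(det) || det <= 1e-12) break
    u0 <- sum(w * z); u1 <- sum(w * z * x)
    d0 <- (swxx * u0 - swx * u1) / det
    d1 <- (sw * u1 - swx * u0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < tol) break
  }
  eta <- offset + b0 + b1 * x
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x * x)
  det <- sw * swxx - swx^2
  se <- if (is.finite(det) && det > 1e-12) sqrt(sw / det) else NA_real_
  zstat <- if (is.na(se) || se == 0) 0 else b1 / se
  list(beta = b1, se = se, z = zstat,
       p = if (is.na(se)) 1 else min(1, 2 * stats::pnorm(-abs(zstat))))
}

#' Pseudobulk negative-binomial Wald test
#'
#' Per gene, a log-linear NB model with size-factor offsets and a condition
#' coefficient is fit by IRLS at a fixed dispersion. The dispersion is
#' estimated per gene by the method of moments on normalized counts, then
#' shrunk toward the across-gene mean with weight `n / (n + 4)` (`n` =
#' number of replicates). Wald p-values on the condition coefficient are BH
#' adjusted. Needs at least two replicates per condition.
#'
#' @param pseudobulk gene x replicate count matrix (or a
#'   [pseudobulk_aggregate()] result)
#' @param condition character vector of condition labels per replicate
#' @param cond_a,cond_b conditions to compare (log2FC is b over a)
#' @param comparison label stored on the result
#' @return data.frame: gene, log2FC, p, p_adj, plus the per-gene dispersion
#' @export
de_pseudobulk_nb <- function(pseudobulk, condition, cond_a, cond_b,
                             comparison = "a_vs_b") {
  m <- if (is.list(pseudobulk)) pseudobulk$counts else pseudobulk
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(m))
  keep <- condition %in% c(cond_a, cond_b)
  m <- m[, keep, drop = FALSE]
  condition <- condition[keep]
  n_a <- sum(condition == cond_a); n_b <- sum(condition == cond_b)
  if (n_a < 2 || n_b < 2) {
    stop("need >= 2 pseudobulk replicates per condition; ",
         "use de_rank_sum() for per-cell testing instead")
  }
  sf <- size_factors_median_ratio(m)
  x <- as.numeric(condition == cond_b)
  offset <- log(sf)
  n <- ncol(m)

  # method-of-moments dispersion on normalized counts, per gene
  q <- sweep(m, 2L, sf, "/")
  alpha_raw <- vapply(seq_len(nrow(m)), function(g) {
    a_num <- 0; a_den <- 0
    for (grp in list(which(x == 0), which(x == 1))) {
      qq <- q[g, grp]
      mb <- mean(qq)
      if (mb <= 0) next
      v <- stats::var(qq)
      a_num <- a_num + (v - mb * mean(1 / sf[grp])) * (length(qq) - 1)
      a_den <- a_den + mb^2 * (length(qq) - 1)
    }
    if (a_den <= 0) return(NA_real_)
    max(a_num / a_den, 0)
  }, numeric(1))
  alpha_bar <- mean(alpha_raw, na.rm = TRUE)
  if (!is.finite(alpha_bar)) alpha_bar <- 0.1
  wgt <- n / (n + 4)
  alpha <- ifelse(is.na(alpha_raw), alpha_bar,
                  wgt * alpha_raw + (1 - wgt) * alpha_bar)
  alpha <- pmax(alpha, 1e-8)

  res <- lapply(seq_len(nrow(m)), function(g) {
    y <- m[g, ]
    if (all(y == 0)) return(list(beta = 0, p = 1))
    nb_wald_fit(y, x, offset, alpha[g])
  })
  beta <- vapply(res, `[[`, numeric(1), "beta")
  p <- vapply(res, `[[`, numeric(1), "p")
  out <- data.frame(
    gene = rownames(m), log2FC = beta / log(2), p = p,
    p_adj = benjamini_hochberg(p), dispersion = alpha,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "comparison") <- comparison
  out
}

#' Classify differential-expression results
#'
#' Three-way classification: `up` when `log2FC > lfc_threshold` and
#' `p_adj < fdr`, `down` symmetric, else `ns`. The default magnitude
#' threshold is `log2(1.33)` (~ 0.411); 0.585 is the stricter variant used
#' for some figure panels.
#'
#' @param rows DE table with `log2FC` and `p_adj`
#' @param fdr FDR level (default 0.05)
#' @param lfc_threshold |log2FC| threshold (default log2(1.33))
#' @return `rows` with a `class` column
#' @export
classify_deg <- function(rows, fdr = 0.05, lfc_threshold = log2(1.33)) {
  stopifnot(all(c("log2FC", "p_adj") %in% names(rows)))
  cls <- rep("ns", nrow(rows))
  sig <- !is.na(rows$p_adj) & rows$p_adj < fdr
  cls[sig & rows$log2FC > lfc_threshold] <- "up"
  cls[sig & rows$log2FC < -lfc_threshold] <- "down"
  rows$class <- cls
  rows
}
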