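# Shared fixtures and independent oracles. Oracles implement the stated
# algorithms from scratch (enumeration, brute force) and deliberately share
# no code with the package internals.

# small dense dataset with controllable annotations
make_toy_dataset <- function(counts, conditions = NULL, major = NULL,
                             subtype = NULL, donor = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("C%03d", seq_len(ncol(counts)))
  }
  cells <- data.frame(row.names = colnames(counts))
  if (!is.null(conditions)) cells$condition <- conditions
  if (!is.null(major)) cells$major_type <- major
  if (!is.null(subtype)) cells$neuron_subtype <- subtype
  if (!is.null(donor)) cells$donor_id <- donor
  cell_dataset(counts, cells = cells)
}

# a tiny cohort config that keeps unit tests fast
tiny_cohort <- function(seed = 1L, ...) {
  cohort_config(n_donors = c(Control = 2, Diabetic = 2, DPN = 2),
                cells_per_donor = 60, n_genes = 200, seed = seed, ...)
}

# --- oracle: naive module score -------------------------------------------
# recomputes expression bins and control means from scratch on a dense
# matrix, following only the documented algorithm
oracle_module_score <- function(lognorm, gene_set, n_bins, n_ctrl, seed) {
  lognorm <- as.matrix(lognorm)
  genes <- rownames(lognorm)
  avg <- apply(lognorm, 1, mean)
  ord <- order(avg, seq_along(avg))
  bin <- integer(length(avg))
  bin[ord] <- ceiling(seq_along(avg) * n_bins / length(avg))
  present <- intersect(gene_set, genes)
  set_idx <- match(present, genes)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ctrl <- integer(0)
  for (gi in set_idx) {
    pool <- setdiff(which(bin == bin[gi]), set_idx)
    draw <- if (length(pool) >= n_ctrl) sample(pool, n_ctrl) else
      sample(pool, n_ctrl, replace = TRUE)
    ctrl <- c(ctrl, draw)
  }
  set_mean <- colMeans(lognorm[set_idx, , drop = FALSE])
  ctrl_mean <- colMeans(lognorm[ctrl, , drop = FALSE])  # duplicates repeat rows
  set_mean - ctrl_mean
}

# --- oracle: brute-force BH step-up ---------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # smallest m*p_(j)/j over j at or after this rank
    js <- which(rank(p, ties.method = "first") >= rank(p, ties.method = "first")[i])
    q[i] <- min(1, min(m * p[js] / rank(p, ties.method = "first")[js]))
  }
  q
}

# --- oracle: exact permutation proportion test -----------------------------
# enumerates every assignment of condition labels (n_b cells to condition b)
# and computes P(|log2FD| >= |obs|) per cell type
oracle_exact_prop_p <- function(types, in_b) {
  n <- length(types); n_b <- sum(in_b); n_a <- n - n_b
  lv <- sort(unique(types))
  ti <- match(types, lv)
  eps <- 1 / (2 * min(n_a, n_b))
  k <- length(lv)
  stat <- function(idx_b) {
    cb <- tabulate(ti[idx_b], k)
    ca <- tabulate(ti, k) - cb
    log2((cb / n_b + eps) / (ca / n_a + eps))
  }
  obs <- abs(stat(which(in_b)))
  combos <- combn(n, n_b)
  hits <- numeric(k)
  for (j in seq_len(ncol(combos))) {
    hits <- hits + (abs(stat(combos[, j])) >= obs - 1e-12)
  }
  hits / ncol(combos)
}

# --- GMT + 10x scratch writers ---------------------------------------------
write_tmp_gmt <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}
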