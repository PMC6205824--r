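#' Remove genes below the expression floor on every day
#'
#' A gene is removed only when its mean RPKM is below `rpkm_min` in every
#' (condition, timepoint) group -- i.e. kept as expressed if it reaches the
#' floor on at least one day (ties at the floor are kept).
#'
#' @param expr An [expr_set] with an `rpkm` assay.
#' @param rpkm_min Expression floor (default 5).
#' @return The [expr_set] with sub-threshold genes dropped from all assays.
#' @export
filter_expressed <- function(expr, rpkm_min = 5) {
  tbl <- expr$rpkm
  if (is.null(tbl)) abort("filter_expressed needs an rpkm assay")
  groups <- split(expr$samples$sample,
                  paste(expr$samples$condition, expr$samples$timepoint))
  day_means <- vapply(groups, function(cols) {
    rowMeans(as.matrix(tbl[, cols, drop = FALSE]))
  }, numeric(nrow(tbl)))
  keep <- apply(day_means >= rpkm_min, 1, any)
  out <- expr
  out$rpkm <- tbl[keep, , drop = FALSE]
  if (!is.null(out$counts)) out$counts <- out$counts[keep, , drop = FALSE]
  out
}

# ---- signed weighted topological overlap ----------------------------------
#
# For nodes i, j against the full expressed background:
#   omega_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#              (min(k_i, k_j) + 1 - |a_ij|),   k_i = sum_{u != i} |a_iu|
# with a = signed Pearson correlation. Correlations of zero-variance genes
# are set to 0 (so an all-zero correlation structure yields omega = 0).

# A: N x G correlation block (rows nodes, columns all genes incl. the nodes);
# node_cols: column indices of the nodes within A.
wto_from_cor <- function(A, node_cols) {
  N <- nrow(A)
  self <- A[cbind(seq_len(N), node_cols)]
  k <- rowSums(abs(A)) - abs(self)
  Ann <- A[, node_cols, drop = FALSE]
  S <- A %*% t(A)
  num <- S - self * Ann - Ann * rep(self, each = N) + Ann
  den <- outer(k, k, pmin) + 1 - abs(Ann)
  W <- num / den
  diag(W) <- 0
  W
}

# m: samples x genes matrix -> node x node omega matrix
wto_omega <- function(m, nodes, warn_zero_var = FALSE) {
  node_cols <- match(nodes, colnames(m))
  A <- suppressWarnings(cor(m[, node_cols, drop = FALSE], m))
  if (anyNA(A)) {
    if (warn_zero_var) {
      bad <- colnames(m)[apply(is.na(A), 2, any)]
      warn(paste("zero-variance genes, correlations set to 0:",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) "..." else ""))
    }
    A[is.na(A)] <- 0
  }
  W <- wto_from_cor(A, node_cols)
  dimnames(W) <- list(nodes, nodes)
  W
}

omega_edges <- function(W) {
  nodes <- rownames(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  tibble(node_i = nodes[ut[, 1]], node_j = nodes[ut[, 2]],
         omega = W[ut])
}

#' Signed weighted topological overlap network over a node set
#'
#' Computes the signed wTO weight for every pair of nodes (typically TFs),
#' correcting each pairwise Pearson correlation by the agreement of the two
#' nodes' correlations with *all* expressed genes in the input -- the full
#' background reduces noise and false-positive links relative to a plain
#' correlation network, and the signed form keeps repressive (negative)
#' relationships visible.
#'
#' @param x Gene x sample tibble (`gene_id` + one numeric column per sample)
#'   holding the expressed background for one condition and day, e.g.
#'   `expr_slice()` of a filtered [expr_set].
#' @param nodes Character vector of node gene ids (subset of `x$gene_id`).
#' @param correlation Correlation method; only "pearson" is supported.
#' @return A `wto_network` tibble: `node_i`, `node_j`, `omega` in \[-1, 1\],
#'   one row per unordered node pair, with attributes `nodes` and
#'   `n_samples`.
#' @export
wto <- function(x, nodes, correlation = "pearson") {
  arg_match(correlation, "pearson")
  if (!all(nodes %in% x$gene_id)) abort("all nodes must be rows of x")
  m <- as_sample_matrix(x)
  if (nrow(m) < 3) abort("need >= 3 samples to estimate correlations")
  W <- wto_omega(m, nodes, warn_zero_var = TRUE)
  structure(omega_edges(W), class = c("wto_network", class(tibble())),
            nodes = nodes, n_samples = nrow(m))
}

#' Bootstrap link probabilities for a wTO network
#'
#' Resamples the samples (columns of one condition-day slice) with
#' replacement `n_bootstrap` times, recomputes every omega, and scores each
#' link by the empirical two-sided sign-crossing probability
#' `2 * min(#\{omega* <= 0\}, #\{omega* >= 0\}) / B` -- the probability that
#' the link's sign is random. Links with probability above `p_cut` are
#' flagged as not kept.
#'
#' @inheritParams wto
#' @param n_bootstrap Number of bootstrap resamples (default 1000).
#' @param p_cut Retention threshold: links with `pval <= p_cut` are kept.
#' @param seed Integer seed for the resampling.
#' @return A `wto_network` tibble with columns `node_i`, `node_j`, `omega`,
#'   `pval`, `kept`.
#' @export
wto_bootstrap <- function(x, nodes, n_bootstrap = 1000, p_cut = 0.10,
                          seed = 1, correlation = "pearson") {
  arg_match(correlation, "pearson")
  stopifnot(n_bootstrap >= 1, p_cut > 0, p_cut < 1)
  m <- as_sample_matrix(x)
  if (nrow(m) < 4) abort("need >= 4 samples to bootstrap")
  W <- wto_omega(m, nodes, warn_zero_var = TRUE)
  set.seed(as.integer(seed))
  N <- length(nodes)
  cnt_le <- matrix(0L, N, N)
  cnt_ge <- matrix(0L, N, N)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    Wb <- wto_omega(m[idx, , drop = FALSE], nodes)
    cnt_le <- cnt_le + (Wb <= 0)
    cnt_ge <- cnt_ge + (Wb >= 0)
  }
  pval <- 2 * pmin(cnt_le, cnt_ge) / n_bootstrap
  pval <- pmin(pval, 1)
  edges <- omega_edges(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  edges$pval <- pval[ut]
  edges$kept <- edges$pval <= p_cut
  structure(edges, class = c("wto_network", class(tibble())),
            nodes = nodes, n_samples = nrow(m), n_bootstrap = n_bootstrap,
            p_cut = p_cut)
}
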