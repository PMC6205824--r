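#' Top differentially expressed genes versus a reference timepoint
#'
#' Ranks genes by the significance of their change between `timepoint` and
#' `reference_timepoint` within one cell line (condition), using the built-in
#' Welch DE stage, and returns the `n_top` highest-ranked gene ids. Ties on
#' adjusted p are broken by |log2fc| (larger first), then gene id, so the
#' ranking is deterministic even when nothing changes.
#'
#' @param expr An [expr_set].
#' @param condition Cell line to rank within.
#' @param timepoint Later timepoint to contrast.
#' @param reference_timepoint Baseline timepoint (default 0).
#' @param n_top Number of genes to return (default 1000; capped at the gene
#'   count).
#' @param de Optional externally computed DE table (`gene_id`, `log2fc`,
#'   `padj`) replacing the built-in contrast.
#' @param assay Assay for the built-in contrast.
#' @return Character vector of gene ids, highest-ranked first.
#' @export
top_de_genes <- function(expr, condition = "WT", timepoint,
                         reference_timepoint = 0, n_top = 1000, de = NULL,
                         assay = c("counts", "rpkm")) {
  assay <- arg_match(assay)
  if (is.null(de)) {
    a <- as_sample_matrix(expr_slice(expr, condition, timepoint, assay))
    b <- as_sample_matrix(expr_slice(expr, condition, reference_timepoint,
                                     assay))
    de <- welch_de(a, b)
  }
  ranked <- de |>
    arrange(.data$padj, desc(abs(.data$log2fc)), .data$gene_id)
  head(ranked$gene_id, n_top)
}

#' Correlate an expression profile against every atlas column
#'
#' Computes the Pearson correlation between a query profile and each
#' (region, age) column of a developmental atlas over a chosen gene set.
#' Both sides are log2(x + 1) transformed before correlating. Genes absent
#' from either namespace are dropped (the intersection size is reported per
#' call).
#'
#' @param profile Tibble `gene_id`, `value` (linear scale, e.g. FPKM/RPKM),
#'   or a named numeric vector.
#' @param atlas An [atlas_matrix].
#' @param gene_set Optional character vector restricting the correlated
#'   genes (e.g. [top_de_genes()] output); default all shared genes.
#' @return Tibble `region`, `age`, `age_order`, `n_genes`, `r`.
#' @export
correlate_to_atlas <- function(profile, atlas, gene_set = NULL) {
  if (!is.data.frame(profile)) {
    profile <- tibble(gene_id = names(profile), value = unname(profile))
  }
  shared <- intersect(profile$gene_id, atlas$expr$gene_id)
  if (!is.null(gene_set)) shared <- intersect(shared, gene_set)
  if (length(shared) < 3) abort("fewer than 3 shared genes to correlate")
  inform(sprintf("correlating over %d shared genes", length(shared)))
  q <- log2(profile$value[match(shared, profile$gene_id)] + 1)
  amat <- log2(as.matrix(
    atlas$expr[match(shared, atlas$expr$gene_id), atlas$meta$column]) + 1)
  r <- suppressWarnings(as.numeric(cor(q, amat)))
  atlas$meta |>
    transmute(.data$region, .data$age, .data$age_order,
              n_genes = length(shared), r = r)
}

#' Call significant region-age matches by the two-SD rule
#'
#' A (region, age) correlation is called significant when it exceeds the
#' mean correlation of the *other* regions at the same age by more than
#' twice the standard deviation of correlations among samples of similar
#' age -- similar meaning the age itself plus its immediate ordered
#' neighbors (window controlled by `age_window`), excluding the focal
#' column.
#'
#' @param calls Tibble from [correlate_to_atlas()].
#' @param age_window Number of ordered age neighbors on each side counted
#'   as "similar" (default 1).
#' @return `calls` with `mean_other`, `sd_similar`, `significant` added.
#' @export
call_region_age <- function(calls, age_window = 1) {
  stopifnot(all(c("region", "age", "age_order", "r") %in% names(calls)))
  n <- nrow(calls)
  mean_other <- numeric(n)
  sd_similar <- numeric(n)
  for (i in seq_len(n)) {
    same_age <- calls$age_order == calls$age_order[i] &
      calls$region != calls$region[i]
    windowed <- abs(calls$age_order - calls$age_order[i]) <= age_window
    pool <- windowed & !(calls$region == calls$region[i] &
                           calls$age_order == calls$age_order[i])
    mean_other[i] <- if (any(same_age)) mean(calls$r[same_age]) else calls$r[i]
    sd_similar[i] <- if (sum(pool) >= 2) sd(calls$r[pool]) else 0
  }
  calls |>
    mutate(mean_other = mean_other, sd_similar = sd_similar,
           significant = (.data$r - mean_other) > 2 * sd_similar)
}

#' Merge atlas regions by averaging their columns
#'
#' Averages the named regions' expression columns at shared ages and keeps
#' single-region columns where only one of them has data -- the treatment
#' applied to regions whose sampled ages do not overlap.
#'
#' @param atlas An [atlas_matrix].
#' @param regions_to_merge Character vector of region names to combine.
#' @param new_region Name of the merged region (default the names joined
#'   with "+").
#' @return A new [atlas_matrix].
#' @export
merge_regions <- function(atlas, regions_to_merge,
                          new_region = paste(regions_to_merge, collapse = "+")) {
  regions_to_merge <- unique(regions_to_merge)
  stopifnot(all(regions_to_merge %in% atlas$meta$region))
  if (length(regions_to_merge) == 1 &&
      identical(new_region, regions_to_merge)) {
    return(atlas)
  }
  meta <- atlas$meta
  in_merge <- meta$region %in% regions_to_merge
  merged_cols <- meta[in_merge, ] |>
    group_by(.data$age, .data$age_order) |>
    group_map(function(df, key) {
      col <- paste(new_region, key$age, sep = "|")
      vals <- rowMeans(as.matrix(atlas$expr[, df$column, drop = FALSE]))
      list(meta = tibble(column = col, region = new_region, age = key$age,
                         age_order = key$age_order),
           vals = setNames(list(vals), col))
    })
  new_meta <- bind_rows(meta[!in_merge, ], map(merged_cols, "meta")) |>
    arrange(.data$region, .data$age_order)
  new_vals <- unlist(map(merged_cols, "vals"), recursive = FALSE)
  expr <- bind_cols(atlas$expr[, c("gene_id", meta$column[!in_merge])],
                    as_tibble(new_vals))
  atlas_matrix(expr, new_meta, truth = atlas$truth)
}
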