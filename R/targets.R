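#' Differential expression between two sample groups
#'
#' The built-in, intentionally simple DE stage: a Welch two-sample test on
#' log2(count + 1) per gene, Benjamini-Hochberg adjusted across genes. The
#' published analysis used a negative-binomial model; this stage is pluggable
#' -- any externally computed table with columns `gene_id`, `log2fc`,
#' `pvalue`, `padj` can be used wherever a DE result is consumed.
#'
#' The log2 fold change is `log2(mean_A / mean_B)` of raw values, with a 0.5
#' pseudocount added to both means only when one of them is zero.
#'
#' @param expr An [expr_set].
#' @param condition_pair Length-2 character: c(test, reference), e.g.
#'   `c("KO", "WT")` for knockout-versus-WT.
#' @param timepoint Optional timepoint restriction (recommended: test within
#'   one day).
#' @param assay Assay to test ("counts" or "rpkm").
#' @return Tibble `gene_id`, `base_mean`, `log2fc`, `pvalue`, `padj`.
#' @export
de_test <- function(expr, condition_pair = c("KO", "WT"), timepoint = NULL,
                    assay = c("counts", "rpkm")) {
  assay <- arg_match(assay)
  stopifnot(length(condition_pair) == 2)
  a <- as_sample_matrix(expr_slice(expr, condition_pair[1], timepoint, assay))
  b <- as_sample_matrix(expr_slice(expr, condition_pair[2], timepoint, assay))
  welch_de(a, b)
}

# a, b: samples x genes matrices (same genes); Welch test on log2(x + 1)
welch_de <- function(a, b) {
  if (nrow(a) < 2 || nrow(b) < 2) {
    abort("need >= 2 replicates per group: variance is undefined otherwise")
  }
  stopifnot(identical(colnames(a), colnames(b)))
  la <- log2(a + 1)
  lb <- log2(b + 1)
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(la); m2 <- colMeans(lb)
  v1 <- apply(la, 2, stats::var); v2 <- apply(lb, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  pvalue <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df),
                   ifelse(m1 == m2, 1, 0))
  ma <- colMeans(a); mb <- colMeans(b)
  pseudo <- ifelse(pmin(ma, mb) == 0, 0.5, 0)
  tibble(gene_id = colnames(a),
         base_mean = unname((ma + mb) / 2),
         log2fc = unname(log2((ma + pseudo) / (mb + pseudo))),
         pvalue = unname(pvalue),
         padj = unname(p.adjust(pvalue, method = "BH")))
}

#' Three-way intersection defining high-confidence miRNA targets
#'
#' Flags each gene for (i) loss of AGO2 3'UTR signal in the knockout,
#' operationalized as carrying a WT-specific consensus binding site, (ii)
#' significant upregulation in knockout whole-cell RNA (`log2fc > 0` and
#' `padj < alpha`; significance only, no fold-change floor), and (iii)
#' presence on the annotated-target list. The high-confidence set is the
#' conjunction of all three.
#'
#' @param signals Gene-signal tibble from [annotate_and_normalize()] run on
#'   WT-specific sites (column `gene_id`; other columns carried through the
#'   flag only).
#' @param de DE table with `gene_id`, `log2fc`, `padj` (gene ids unique).
#' @param annotation Annotated-target gene ids: character vector, or a
#'   data frame whose first column holds the ids.
#' @param alpha Adjusted-p cutoff for upregulation (default 0.05).
#' @return Tibble of all genes with at least one flag set: `gene_id`,
#'   `has_wt_specific_utr_site`, `upregulated_in_ko`, `annotated_target`,
#'   `high_confidence`.
#' @export
intersect_targets <- function(signals, de, annotation, alpha = 0.05) {
  if (anyDuplicated(de$gene_id)) abort("duplicate gene ids in DE table")
  if (is.data.frame(annotation)) annotation <- annotation[[1]]
  site_genes <- unique(signals$gene_id)
  up_genes <- de$gene_id[de$log2fc > 0 & !is.na(de$padj) & de$padj < alpha]
  ann_genes <- unique(annotation)
  universe <- sort(unique(c(site_genes, up_genes, ann_genes)))
  tibble(gene_id = universe,
         has_wt_specific_utr_site = universe %in% site_genes,
         upregulated_in_ko = universe %in% up_genes,
         annotated_target = universe %in% ann_genes) |>
    mutate(high_confidence = .data$has_wt_specific_utr_site &
             .data$upregulated_in_ko & .data$annotated_target)
}

#' Venn counts of the target-intersection sets
#'
#' @param calls Output of [intersect_targets()].
#' @return Named list of the three set sizes and all intersection
#'   cardinalities, ready for JSON serialization.
#' @export
target_venn <- function(calls) {
  s <- calls$has_wt_specific_utr_site
  u <- calls$upregulated_in_ko
  a <- calls$annotated_target
  list(n_wt_specific_site = sum(s),
       n_upregulated = sum(u),
       n_annotated = sum(a),
       n_site_and_up = sum(s & u),
       n_site_and_annotated = sum(s & a),
       n_up_and_annotated = sum(u & a),
       n_high_confidence = sum(s & u & a))
}
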