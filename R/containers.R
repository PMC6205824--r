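#' Expression set: gene x sample assays plus sample metadata
#'
#' A light container pairing one or more gene x sample tables (`counts`,
#' `rpkm`) with a sample-metadata tibble. Assay tables have a `gene_id`
#' column followed by one numeric column per sample; `samples` has columns
#' `sample`, `condition`, `timepoint`, `replicate`.
#'
#' @param counts Tibble of raw counts (`gene_id` + sample columns), or NULL.
#' @param rpkm Tibble of RPKM values in the same layout, or NULL.
#' @param samples Sample metadata tibble.
#' @param truth Optional ground-truth record attached by the generators.
#'
#' @return An `expr_set` object.
#' @export
expr_set <- function(counts = NULL, rpkm = NULL, samples, truth = NULL) {
  stopifnot(is.data.frame(samples))
  req <- c("sample", "condition", "timepoint", "replicate")
  if (!all(req %in% names(samples))) {
    abort(paste("samples metadata needs columns:", paste(req, collapse = ", ")))
  }
  for (assay in list(counts, rpkm)) {
    if (!is.null(assay)) {
      if (names(assay)[1] != "gene_id") abort("assay tables start with gene_id")
      missing <- setdiff(samples$sample, names(assay))
      if (length(missing)) {
        abort(paste("assay lacks sample columns:", paste(missing, collapse = ", ")))
      }
    }
  }
  structure(list(counts = counts, rpkm = rpkm,
                 samples = as_tibble(samples), truth = truth),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  assay <- x$counts %||% x$rpkm
  cat(sprintf("<expr_set> %d genes x %d samples (%s)\n",
              nrow(assay), nrow(x$samples),
              paste(c("counts", "rpkm")[!vapply(x[1:2], is.null, logical(1))],
                    collapse = " + ")))
  cat(sprintf("  conditions: %s | timepoints: %s | replicates per group: %s\n",
              paste(unique(x$samples$condition), collapse = ", "),
              paste(sort(unique(x$samples$timepoint)), collapse = ", "),
              paste(unique(table(x$samples$condition, x$samples$timepoint)),
                    collapse = "/")))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Slice an assay by condition and timepoint
#'
#' Returns one assay restricted to matching samples as a gene x sample
#' tibble -- the input layout of the correlation-based stages.
#'
#' @param expr An [expr_set].
#' @param condition,timepoint Optional filters (NULL keeps everything).
#' @param assay Which assay to slice.
#' @param log2 If TRUE, values are log2(x + 1) transformed -- the scale on
#'   which expression correlations are computed.
#' @return Tibble `gene_id` + one column per matching sample.
#' @export
expr_slice <- function(expr, condition = NULL, timepoint = NULL,
                       assay = c("rpkm", "counts"), log2 = FALSE) {
  assay <- arg_match(assay)
  tbl <- expr[[assay]]
  if (is.null(tbl)) abort(sprintf("expr_set has no '%s' assay", assay))
  keep <- expr$samples
  if (!is.null(condition)) keep <- filter(keep, .data$condition %in% !!condition)
  if (!is.null(timepoint)) keep <- filter(keep, .data$timepoint %in% !!timepoint)
  if (nrow(keep) == 0) abort("no samples match the requested slice")
  out <- select(tbl, "gene_id", all_of(keep$sample))
  if (log2) out <- mutate(out, across(-"gene_id", ~log2(.x + 1)))
  out
}

# gene x sample tibble -> samples x genes numeric matrix
as_sample_matrix <- function(tbl) {
  m <- t(as.matrix(tbl[, -1, drop = FALSE]))
  colnames(m) <- tbl$gene_id
  m
}

#' miRNA count set: miRNA x sample counts with housekeeping rows
#'
#' @param counts Tibble with `mirna_id` + one numeric column per sample.
#' @param samples Sample metadata (`sample`, `condition`, `timepoint`,
#'   `replicate`).
#' @param housekeeping Character vector of housekeeping row ids (non-empty,
#'   all present in `counts$mirna_id`).
#' @param normalized Optional tibble of housekeeping-normalized counts.
#' @param truth Optional ground-truth record.
#'
#' @return A `mirna_set` object.
#' @export
mirna_set <- function(counts, samples, housekeeping, normalized = NULL,
                      truth = NULL) {
  if (length(housekeeping) == 0) abort("housekeeping set must be non-empty")
  if (names(counts)[1] != "mirna_id") abort("counts must start with mirna_id")
  if (!all(housekeeping %in% counts$mirna_id)) {
    abort("all housekeeping ids must be rows of the count table")
  }
  if (any(as.matrix(counts[, -1]) < 0)) abort("counts must be non-negative")
  structure(list(counts = as_tibble(counts), samples = as_tibble(samples),
                 housekeeping = housekeeping, normalized = normalized,
                 truth = truth),
            class = "mirna_set")
}

#' @export
print.mirna_set <- function(x, ...) {
  cat(sprintf("<mirna_set> %d miRNAs x %d samples, %d housekeeping rows%s\n",
              nrow(x$counts), nrow(x$samples), length(x$housekeeping),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' Developmental atlas: genes x (region, age) expression
#'
#' @param expr Tibble with `gene_id` + one numeric column per atlas column.
#' @param meta Tibble with `column`, `region`, `age`, `age_order` describing
#'   each expression column; `age_order` gives the ordering of ages.
#' @param truth Optional ground-truth record.
#'
#' @return An `atlas_matrix` object.
#' @export
atlas_matrix <- function(expr, meta, truth = NULL) {
  req <- c("column", "region", "age", "age_order")
  if (!all(req %in% names(meta))) {
    abort(paste("atlas meta needs columns:", paste(req, collapse = ", ")))
  }
  if (names(expr)[1] != "gene_id") abort("atlas expr must start with gene_id")
  missing <- setdiff(meta$column, names(expr))
  if (length(missing)) {
    abort(paste("atlas expr lacks columns:", paste(missing, collapse = ", ")))
  }
  structure(list(expr = as_tibble(expr), meta = as_tibble(meta), truth = truth),
            class = "atlas_matrix")
}

#' @export
print.atlas_matrix <- function(x, ...) {
  cat(sprintf("<atlas_matrix> %d genes x %d columns (%d regions x %d ages)\n",
              nrow(x$expr), nrow(x$meta),
              dplyr::n_distinct(x$meta$region), dplyr::n_distinct(x$meta$age)))
  invisible(x)
}
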