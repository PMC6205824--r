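#' Housekeeping-normalize an miRNA count table
#'
#' Divides each sample's counts by that sample's mean housekeeping count
#' (per-replicate normalization), making values invariant to lane depth.
#' Replicate means per condition and timepoint are attached for profile
#' reporting.
#'
#' @param x A [mirna_set].
#' @return The [mirna_set] with a `normalized` table and a `profile`
#'   element (mean normalized counts per miRNA, condition and timepoint).
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "mirna_set"))
  hk <- filter(x$counts, .data$mirna_id %in% x$housekeeping)
  norm <- x$counts
  for (s in x$samples$sample) {
    hk_mean <- mean(hk[[s]])
    if (hk_mean <= 0) abort(sprintf("housekeeping mean is zero in %s", s))
    norm[[s]] <- x$counts[[s]] / hk_mean
  }
  profile <- norm |>
    pivot_longer(-"mirna_id", names_to = "sample", values_to = "value") |>
    left_join(x$samples, by = "sample") |>
    group_by(.data$mirna_id, .data$condition, .data$timepoint) |>
    summarise(mean_normalized = mean(.data$value), .groups = "drop")
  x$normalized <- norm
  x$profile <- profile
  x
}

#' miRNAs passing the raw-abundance threshold
#'
#' Keeps miRNAs whose raw count strictly exceeds `min_counts` in at least
#' one sample (housekeeping rows are not returned).
#'
#' @param x A [mirna_set].
#' @param min_counts Raw-count threshold (default 200, strict >).
#' @return Character vector of abundant miRNA ids.
#' @export
filter_abundant <- function(x, min_counts = 200) {
  stopifnot(inherits(x, "mirna_set"))
  m <- as.matrix(x$counts[, x$samples$sample])
  ok <- apply(m > min_counts, 1, any)
  setdiff(x$counts$mirna_id[ok], x$housekeeping)
}

#' miRNAs taking over regulatory load in the knockout
#'
#' Three-way intersection of: upregulated in the knockout within the
#' AGO2-IP compartment, upregulated in knockout whole-cell small RNA, and
#' abundant -- the species with both more molecules and more RISC
#' association once the dominant miRNA is gone.
#'
#' @param ip_de,wholecell_de DE tables over miRNAs (`gene_id` or
#'   `mirna_id`, `log2fc`, `padj`), knockout versus WT.
#' @param abundant_ids Abundant miRNA ids ([filter_abundant()]).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Character vector of candidate miRNA ids.
#' @export
takeover_candidates <- function(ip_de, wholecell_de, abundant_ids,
                                alpha = 0.05) {
  up <- function(de) {
    id_col <- if ("mirna_id" %in% names(de)) "mirna_id" else "gene_id"
    de[[id_col]][de$log2fc > 0 & !is.na(de$padj) & de$padj < alpha]
  }
  Reduce(intersect, list(up(ip_de), up(wholecell_de), abundant_ids))
}

#' Rank miRNAs by AGO2 activity within each condition
#'
#' Activity is the ratio of AGO2-IP signal to whole-cell signal per miRNA:
#' how strongly a species is engaged in the silencing complex relative to
#' its abundance. Ranks (1 = most active, dense over the scored set) are
#' assigned within each condition; miRNAs with zero whole-cell signal have
#' undefined activity and are excluded with a warning.
#'
#' @param ip_signal,wholecell_signal Tibbles `mirna_id`, `condition`,
#'   `signal` (e.g. mean normalized counts per condition from
#'   [normalize_counts()]'s profile).
#' @return Tibble `mirna_id`, `condition`, `ip_signal`,
#'   `wholecell_signal`, `activity`, `rank`.
#' @export
activity_rank <- function(ip_signal, wholecell_signal) {
  joined <- inner_join(rename(ip_signal, ip_signal = "signal"),
                       rename(wholecell_signal, wholecell_signal = "signal"),
                       by = c("mirna_id", "condition"))
  bad <- joined$wholecell_signal <= 0
  if (any(bad)) {
    warn(sprintf("%d miRNA/condition entries with zero whole-cell signal excluded",
                 sum(bad)))
    joined <- joined[!bad, , drop = FALSE]
  }
  joined |>
    mutate(activity = .data$ip_signal / .data$wholecell_signal) |>
    group_by(.data$condition) |>
    mutate(rank = dplyr::dense_rank(desc(.data$activity))) |>
    ungroup() |>
    arrange(.data$condition, .data$rank)
}

#' Rank shifts between two conditions
#'
#' @param ranks Output of [activity_rank()].
#' @param conditions Length-2 character, c(reference, other); shift is
#'   rank(reference) - rank(other), positive when the miRNA moved up (is
#'   more active) in the other condition.
#' @return Tibble `mirna_id`, `rank_<ref>`, `rank_<other>`, `shift`.
#' @export
rank_shifts <- function(ranks, conditions = c("WT", "KO")) {
  wide <- ranks |>
    select("mirna_id", "condition", "rank") |>
    pivot_wider(names_from = "condition", values_from = "rank",
                names_prefix = "rank_")
  ref <- paste0("rank_", conditions[1])
  oth <- paste0("rank_", conditions[2])
  wide$shift <- wide[[ref]] - wide[[oth]]
  wide
}
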