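#' Call binding sites by recursive summit splitting of a pileup track
#'
#' Implements the threshold-based binding-site definition used for AGO2-RIP
#' coverage. Candidate regions are maximal runs of non-zero depth at
#' consecutive positions. Within a candidate with global summit S:
#'
#' 1. if S is below `tau_background` reads the whole candidate is background
#'    and discarded;
#' 2. every base with depth strictly below `f_primary * S` is cut (cut bases
#'    belong to no site; ties with the threshold stay inside sites);
#' 3. each emerging sub-region whose own summit reaches both
#'    `f_primary * S` and `tau_background` is recursively split at `f_sub`
#'    times its own summit, which preserves sub-regions with only weak
#'    signal relative to the primary summit;
#' 4. maximal uncut stretches are emitted as binding sites, disjoint and
#'    ordered by start.
#'
#' @param pileup Tibble with columns `region_id`, `pos` (0-based), `depth`
#'   (non-negative), one row per base, e.g. one replicate's track from
#'   [gen_pileups()] or [read_bedgraph()].
#' @param tau_background Background summit threshold in reads (default 10).
#' @param f_primary Primary split fraction of the candidate summit (0.20).
#' @param f_sub Recursive split fraction of a sub-site's own summit (0.05).
#' @return Tibble of binding sites: `region_id`, `start`, `end` (0-based
#'   half-open), `summit_pos`, `summit_height`, `parent_id` (candidate-region
#'   id), `depth_sum`. Empty input or all-background tracks give zero rows.
#' @export
#' @examples
#' track <- tibble::tibble(region_id = "r", pos = 0:9,
#'                         depth = c(0, 2, 8, 20, 40, 25, 9, 3, 1, 0))
#' split_sites(track)
split_sites <- function(pileup, tau_background = 10, f_primary = 0.20,
                        f_sub = 0.05) {
  check_site_params(tau_background, f_primary, f_sub)
  req <- c("region_id", "pos", "depth")
  if (!all(req %in% names(pileup))) {
    abort("pileup needs columns region_id, pos, depth")
  }
  if (nrow(pileup) == 0) return(empty_sites())
  if (any(pileup$depth < 0)) abort("depth must be non-negative")

  pileup |>
    group_by(.data$region_id) |>
    group_map(function(df, key) {
      df <- arrange(df, .data$pos)
      split_track(key$region_id, df$pos, df$depth,
                  tau_background, f_primary, f_sub)
    }) |>
    list_rbind() |>
    arrange(.data$region_id, .data$start)
}

check_site_params <- function(tau_background, f_primary, f_sub) {
  if (!(f_sub > 0 && f_sub < f_primary && f_primary < 1)) {
    abort("need 0 < f_sub < f_primary < 1")
  }
  if (tau_background < 1) abort("tau_background must be >= 1")
  invisible(TRUE)
}

empty_sites <- function() {
  tibble(region_id = character(), start = integer(), end = integer(),
         summit_pos = integer(), summit_height = numeric(),
         parent_id = character(), depth_sum = numeric())
}

# indices of maximal TRUE runs as a list of ranges
true_runs <- function(keep) {
  if (!any(keep)) return(list())
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  map2(starts[r$values], ends[r$values], seq.int)
}

split_track <- function(region_id, pos, depth, tau, fp, fs) {
  # candidate regions: maximal runs of depth > 0 at consecutive positions
  nonzero <- depth > 0
  breaks <- c(TRUE, diff(pos) != 1L)          # position gaps also split
  cand_id <- cumsum(breaks | c(FALSE, diff(nonzero) != 0L))
  sites <- list()
  cand_n <- 0L
  for (idx in split(seq_along(pos), cand_id)) {
    if (!nonzero[idx[1]]) next
    cand_n <- cand_n + 1L
    s <- max(depth[idx])
    if (s < tau) next
    keep <- depth[idx] >= fp * s
    for (run in true_runs(keep)) {
      sub <- idx[run]
      if (max(depth[sub]) >= max(fp * s, tau)) {
        sites <- c(sites, recurse_split(pos[sub], depth[sub], tau, fs,
                                        parent = cand_n))
      }
    }
  }
  if (length(sites) == 0) return(empty_sites())
  map(sites, function(x) {
    w <- which.max(x$depth)
    tibble(region_id = region_id,
           start = x$pos[1], end = x$pos[length(x$pos)] + 1L,
           summit_pos = x$pos[w], summit_height = x$depth[w],
           parent_id = sprintf("%s:c%d", region_id, x$parent),
           depth_sum = sum(x$depth))
  }) |> list_rbind()
}

recurse_split <- function(pos, depth, tau, fs, parent) {
  s <- max(depth)
  keep <- depth >= fs * s
  if (all(keep)) {
    return(list(list(pos = pos, depth = depth, parent = parent)))
  }
  out <- list()
  for (run in true_runs(keep)) {
    if (max(depth[run]) >= max(fs * s, tau)) {
      out <- c(out, recurse_split(pos[run], depth[run], tau, fs, parent))
    }
  }
  out
}

# row pairs (i in a, j in b) of sites sharing >= 1 base within a region
overlap_pairs <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(i = integer(), j = integer()))
  lv <- union(a$region_id, b$region_id)
  gra <- GenomicRanges::GRanges(factor(a$region_id, lv),
                                IRanges::IRanges(a$start + 1L, a$end))
  grb <- GenomicRanges::GRanges(factor(b$region_id, lv),
                                IRanges::IRanges(b$start + 1L, b$end))
  h <- GenomicRanges::findOverlaps(gra, grb)
  tibble(i = S4Vectors::queryHits(h), j = S4Vectors::subjectHits(h))
}

#' Keep binding sites supported by every replicate
#'
#' A site (taken from the first replicate, by convention) is retained when
#' its interval shares at least one base with a site in each of the other
#' replicates. `depth_sum` of a consensus site is the mean, over replicates,
#' of the summed `depth_sum` of the overlapping sites in that replicate.
#'
#' @param per_replicate_sites List of site tibbles (one per replicate) as
#'   returned by [split_sites()].
#' @return Consensus site tibble in the [split_sites()] layout.
#' @export
consensus_sites <- function(per_replicate_sites) {
  stopifnot(is.list(per_replicate_sites), length(per_replicate_sites) >= 1)
  ref <- per_replicate_sites[[1]]
  if (length(per_replicate_sites) == 1 || nrow(ref) == 0) return(ref)
  support <- map(per_replicate_sites, function(rep_sites) {
    hits <- overlap_pairs(ref, rep_sites)
    list(ok = seq_len(nrow(ref)) %in% hits$i,
         ds = hits |> mutate(depth_sum = rep_sites$depth_sum[.data$j]) |>
           group_by(.data$i) |> summarise(ds = sum(.data$depth_sum)))
  })
  ok <- Reduce(`&`, map(support, "ok"))
  ds <- map(support, function(x) {
    v <- rep(NA_real_, nrow(ref))
    v[x$ds$i] <- x$ds$ds
    v
  })
  ref$depth_sum <- rowMeans(do.call(cbind, ds))
  ref[ok, , drop = FALSE]
}

#' Sites specific to the WT condition
#'
#' Returns WT consensus sites with no overlapping KO consensus site -- the
#' binding events lost upon knockout of the miRNA, the signature of direct
#' targets.
#'
#' @param wt_sites,ko_sites Consensus site tibbles ([consensus_sites()]).
#' @return Tibble of WT-specific sites.
#' @export
condition_specific_sites <- function(wt_sites, ko_sites) {
  if (nrow(wt_sites) == 0) return(wt_sites)
  hits <- overlap_pairs(wt_sites, ko_sites)
  wt_sites[!seq_len(nrow(wt_sites)) %in% hits$i, , drop = FALSE]
}

#' Sum 3'UTR binding signal per gene and normalize by whole-cell expression
#'
#' Sums `depth_sum` of binding sites intersecting each gene's annotated
#' 3'UTR, then divides by the gene's mean whole-cell expression in the
#' matching condition, so that IP signal is interpretable relative to
#' transcript abundance. Genes with zero whole-cell expression get an
#' undefined (`NA`) normalized signal and should be excluded downstream.
#'
#' @param sites Site tibble (e.g. WT-specific consensus sites).
#' @param annotation Interval table: `region_id`, `gene_id`, `start`, `end`
#'   (0-based half-open), `feature`; only rows with
#'   `feature == "three_prime_UTR"` are used.
#' @param expr An [expr_set] providing whole-cell expression.
#' @param condition Condition whose samples provide the normalizer.
#' @param timepoint Optional timepoint restriction; default all.
#' @param assay Which assay normalizes the signal ("rpkm" or "counts").
#' @return Tibble `gene_id`, `utr3_ip_signal`, `wholecell_expr`,
#'   `normalized_signal`, one row per gene with at least one 3'UTR site.
#' @export
annotate_and_normalize <- function(sites, annotation, expr, condition = "WT",
                                   timepoint = NULL,
                                   assay = c("rpkm", "counts")) {
  assay <- arg_match(assay)
  req <- c("region_id", "gene_id", "start", "end")
  if (!all(req %in% names(annotation))) {
    abort("annotation needs columns region_id, gene_id, start, end")
  }
  if (any(annotation$start < 0 | annotation$end <= annotation$start)) {
    abort("annotation intervals out of range: expected 0-based half-open")
  }
  utr <- annotation
  if ("feature" %in% names(utr)) {
    utr <- filter(utr, .data$feature == "three_prime_UTR")
  }
  hits <- overlap_pairs(sites, utr)
  signal <- hits |>
    mutate(gene_id = utr$gene_id[.data$j],
           depth_sum = sites$depth_sum[.data$i]) |>
    distinct(.data$gene_id, .data$i, .data$depth_sum) |>
    group_by(.data$gene_id) |>
    summarise(utr3_ip_signal = sum(.data$depth_sum))

  slice <- expr_slice(expr, condition = condition, timepoint = timepoint,
                      assay = assay)
  mean_expr <- tibble(gene_id = slice$gene_id,
                      wholecell_expr = rowMeans(as.matrix(slice[, -1])))
  signal |>
    left_join(mean_expr, by = "gene_id") |>
    mutate(normalized_signal = ifelse(
      !is.na(.data$wholecell_expr) & .data$wholecell_expr > 0,
      .data$utr3_ip_signal / .data$wholecell_expr, NA_real_))
}
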