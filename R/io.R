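#' Read and write per-base pileup tracks as bedGraph
#'
#' Tracks are stored 0-based half-open, one bedGraph per replicate. On
#' write, consecutive bases with equal depth are collapsed into intervals;
#' on read, intervals are expanded back to per-base rows.
#'
#' @param pileup Tibble `region_id`, `pos`, `depth` (one track).
#' @param path File path.
#' @return `read_bedgraph()` returns a pileup tibble.
#' @export
write_bedgraph <- function(pileup, path) {
  runs <- pileup |>
    arrange(.data$region_id, .data$pos) |>
    group_by(.data$region_id) |>
    mutate(run = cumsum(c(TRUE, diff(.data$pos) != 1L) |
                          c(TRUE, diff(.data$depth) != 0))) |>
    group_by(.data$region_id, .data$run) |>
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              depth = .data$depth[1], .groups = "drop")
  gr <- GenomicRanges::GRanges(runs$region_id,
                               IRanges::IRanges(runs$start + 1L, runs$end),
                               score = runs$depth)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- tibble(region_id = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               depth = as.numeric(S4Vectors::mcols(gr)$score))
  len <- df$end - df$start
  tibble(region_id = rep(df$region_id, len),
         pos = unlist(map2(df$start, df$end - 1L, seq.int)),
         depth = rep(df$depth, len)) |>
    arrange(.data$region_id, .data$pos)
}

#' Read and write binding sites as BED6
#'
#' Score carries the summit height; the name field carries
#' `parent_id:summit_pos:depth_sum` so sites round-trip without loss.
#'
#' @param sites Site tibble ([split_sites()] layout).
#' @param path File path.
#' @return `read_sites_bed()` returns a site tibble.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   sites$region_id, sites$start, sites$end,
                   paste(sites$parent_id, sites$summit_pos, sites$depth_sum,
                         sep = ";"),
                   format(sites$summit_height, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("region_id", "start", "end",
                                             "name", "score", "strand"),
                         col_types = "ciicdc", progress = FALSE)
  parts <- stringr::str_split_fixed(raw$name, ";", 3)
  tibble(region_id = raw$region_id, start = raw$start, end = raw$end,
         summit_pos = as.integer(parts[, 2]), summit_height = raw$score,
         parent_id = parts[, 1], depth_sum = as.numeric(parts[, 3]))
}

#' Read and write an assay table with a sample-metadata header
#'
#' The TSV carries three comment lines (`#condition`, `#timepoint`,
#' `#replicate`) above the header row, aligning metadata with the sample
#' columns.
#'
#' @param tbl Assay tibble (`gene_id` or `mirna_id` + sample columns).
#' @param samples Sample metadata tibble.
#' @param path File path.
#' @return `read_assay_tsv()` returns `list(tbl, samples)`.
#' @export
write_assay_tsv <- function(tbl, samples, path) {
  meta <- samples[match(names(tbl)[-1], samples$sample), ]
  hdr <- c(paste(c("#condition", meta$condition), collapse = "\t"),
           paste(c("#timepoint", meta$timepoint), collapse = "\t"),
           paste(c("#replicate", meta$replicate), collapse = "\t"))
  writeLines(hdr, path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_assay_tsv
#' @export
read_assay_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  stopifnot(startsWith(hdr[1], "#condition"))
  tbl <- readr::read_tsv(path, skip = 3, col_types = readr::cols(),
                         progress = FALSE)
  fields <- map(hdr, function(h) strsplit(h, "\t", fixed = TRUE)[[1]][-1])
  samples <- tibble(sample = names(tbl)[-1],
                    condition = fields[[1]],
                    timepoint = as.integer(fields[[2]]),
                    replicate = as.integer(fields[[3]]))
  list(tbl = tbl, samples = samples)
}

#' Serialize a ground-truth record to JSON and back
#'
#' @param truth Ground-truth list from a generator.
#' @param path File path.
#' @return `read_truth_json()` returns the truth list (tibbles restored).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  map(out, function(x) if (is.list(x) && !is.data.frame(x) &&
                             length(x) && all(lengths(x) == length(x[[1]]))) {
    tryCatch(as_tibble(x), error = function(e) x)
  } else if (is.data.frame(x)) as_tibble(x) else x)
}
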