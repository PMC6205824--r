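#' Pipeline configuration with the published stage defaults
#'
#' Collects every stage parameter in one validated list. Defaults are the
#' analysis-chain operating points: background summit threshold 10 reads,
#' 20 %/5 % summit-split fractions, DE and node-test alpha 0.05, 1000
#' bootstraps filtered at probability 0.10, RPKM floor 5, correlated-gene
#' threshold |r| > 0.9, link-distance cut 0.5, SOM distortion cut 10, top
#' 1000 DE genes for atlas profiling, and the > 200 raw-count miRNA
#' abundance floor.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param synth Named list of [synth_config()] overrides.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param tau_background,f_primary,f_sub Site-splitting parameters.
#' @param alpha Significance level for DE, node chi-squared and takeover.
#' @param n_bootstrap,p_cut wTO bootstrap parameters.
#' @param rpkm_min Expression floor for network genes.
#' @param distance_cut Normalized link-distance filter.
#' @param r_min Correlated-gene |r| threshold.
#' @param distortion_cut SOM grid-growth stopping rule.
#' @param n_top Genes used for atlas correlation.
#' @param min_counts miRNA raw-abundance threshold (strict >).
#' @param network_day Day whose networks are compared (default
#'   `min(3, n_timepoints - 1)`).
#' @param outdir Optional output directory; when set, stage outputs are
#'   written as TSV/BED/JSON next to the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, synth = list(),
                            stages = c("peaks", "targets", "wto", "codina",
                                       "som", "atlas", "mirna"),
                            tau_background = 10, f_primary = 0.20,
                            f_sub = 0.05, alpha = 0.05, n_bootstrap = 1000,
                            p_cut = 0.10, rpkm_min = 5, distance_cut = 0.5,
                            r_min = 0.9, distortion_cut = 10, n_top = 1000,
                            min_counts = 200, network_day = NULL,
                            outdir = NULL) {
  check_site_params(tau_background, f_primary, f_sub)
  stopifnot(alpha > 0, alpha < 1, n_bootstrap >= 1, p_cut > 0, p_cut < 1,
            rpkm_min >= 0, distance_cut >= 0, r_min > 0, distortion_cut > 0,
            n_top >= 1, min_counts >= 0)
  structure(list(seed = as.integer(seed), synth = synth, stages = stages,
                 tau_background = tau_background, f_primary = f_primary,
                 f_sub = f_sub, alpha = alpha, n_bootstrap = n_bootstrap,
                 p_cut = p_cut, rpkm_min = rpkm_min,
                 distance_cut = distance_cut, r_min = r_min,
                 distortion_cut = distortion_cut, n_top = n_top,
                 min_counts = min_counts, network_day = network_day,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full synthetic analysis chain
#'
#' Generates all inputs with the planted ground truth, then executes the
#' stages in order: site calling (per-replicate summit splitting,
#' all-replicate consensus, WT-specific filtering), target intersection,
#' expression filtering + per-condition wTO networks with bootstrap
#' probabilities, differential link/node classification, SOM trajectory
#' clustering, atlas correlation profiling, and miRNA normalization /
#' takeover analysis. Each stage's recovery against the planted truth is
#' measured and reported in the manifest; a rerun with the same
#' configuration reproduces the manifest except for its timestamp.
#'
#' @param config A [pipeline_config()].
#' @return A `ripnet_manifest` list: `params`, `parameter_hash`, `seeds`,
#'   `metrics` (per stage), `outputs` (paths, when `outdir` is set),
#'   `versions`, `timestamp`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  cfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
  final_day <- cfg$n_timepoints - 1L
  network_day <- config$network_day %||% min(3L, final_day)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  metrics <- list()
  outputs <- list()
  emit <- function(name, writer) {
    if (!is.null(outdir)) {
      path <- file.path(outdir, name)
      writer(path)
      outputs[[name]] <<- path
    }
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  # ---- synthetic inputs ----------------------------------------------------
  pile <- gen_pileups(cfg)
  expr <- gen_expression(cfg)
  truth <- expr$truth
  non_tf <- setdiff(expr$counts$gene_id, truth$tf_ids)
  region_genes <- c(truth$planted_targets,
                    setdiff(non_tf, truth$planted_targets))
  annotation <- gen_annotation(cfg, region_genes)

  wt_specific <- NULL
  signals <- NULL
  calls <- NULL
  networks <- NULL
  links <- NULL

  # ---- peaks ---------------------------------------------------------------
  if ("peaks" %in% config$stages) run_stage("peaks", function() {
    consensus <- map(c(WT = "WT", KO = "KO"), function(cond) {
      reps <- filter(pile$pileups, .data$condition == cond)
      per_rep <- map(sort(unique(reps$replicate)), function(r) {
        split_sites(filter(reps, .data$replicate == r),
                    tau_background = config$tau_background,
                    f_primary = config$f_primary, f_sub = config$f_sub)
      })
      consensus_sites(per_rep)
    })
    wt_specific <<- condition_specific_sites(consensus$WT, consensus$KO)
    planted <- filter(pile$truth$planted_sites,
                      .data$specificity == "WT", !.data$below_background)
    hits <- overlap_pairs(planted, wt_specific)
    metrics$peaks <<- list(
      n_wt_consensus = nrow(consensus$WT),
      n_ko_consensus = nrow(consensus$KO),
      n_wt_specific = nrow(wt_specific),
      site_recall = if (nrow(planted)) {
        length(unique(hits$i)) / nrow(planted)
      } else NA,
      site_precision = if (nrow(wt_specific)) {
        length(unique(hits$j)) / nrow(wt_specific)
      } else NA)
    emit("wt_specific_sites.bed", function(p) write_sites_bed(wt_specific, p))
  })

  # ---- targets -------------------------------------------------------------
  if ("targets" %in% config$stages) run_stage("targets", function() {
    stopifnot(!is.null(wt_specific))
    signals <<- annotate_and_normalize(wt_specific, annotation, expr,
                                       condition = "WT",
                                       timepoint = final_day)
    de <- de_test(expr, c("KO", "WT"), timepoint = final_day)
    annotated <- gen_target_list(expr)
    calls <<- intersect_targets(signals, de, annotated, alpha = config$alpha)
    high <- calls$gene_id[calls$high_confidence]
    metrics$targets <<- list(
      n_high_confidence = length(high),
      venn = target_venn(calls),
      target_precision = if (length(high)) {
        mean(high %in% truth$planted_targets)
      } else NA,
      target_recall = mean(truth$planted_targets %in% high))
    emit("target_calls.tsv", function(p) readr::write_tsv(calls, p))
  })

  # ---- wto -----------------------------------------------------------------
  if ("wto" %in% config$stages) run_stage("wto", function() {
    expr_f <- filter_expressed(expr, rpkm_min = config$rpkm_min)
    nodes <- intersect(truth$tf_ids, expr_f$rpkm$gene_id)
    networks <<- imap(c(WT = "WT", KO = "KO"), function(cond, i) {
      wto_bootstrap(expr_slice(expr_f, cond, network_day, "rpkm",
                               log2 = TRUE), nodes,
                    n_bootstrap = config$n_bootstrap, p_cut = config$p_cut,
                    seed = stage_seed(config$seed, "wto") +
                      match(cond, c("WT", "KO")))
    })
    metrics$wto <<- list(
      n_nodes = length(nodes),
      n_kept_wt = sum(networks$WT$kept),
      n_kept_ko = sum(networks$KO$kept))
    emit("wto_wt.tsv", function(p) readr::write_tsv(tidy(networks$WT), p))
    emit("wto_ko.tsv", function(p) readr::write_tsv(tidy(networks$KO), p))
  })

  # ---- codina --------------------------------------------------------------
  if ("codina" %in% config$stages) run_stage("codina", function() {
    stopifnot(!is.null(networks))
    links <<- classify_links(networks, distance_cut = config$distance_cut)
    kept <- filter(links, .data$kept)
    nodes <- classify_nodes(links, alpha = config$alpha)
    planted <- truth$planted_diff_links
    recovered <- pmap(planted, function(node_i, node_j, expected) {
      row <- filter(kept, .data$node_i == !!node_i, .data$node_j == !!node_j)
      nrow(row) == 1 &&
        ((expected == "beta" && row$category == "beta") ||
           (expected == "gamma" && row$category == "gamma" &&
              row$specific_to == "WT"))
    })
    metrics$codina <<- list(
      n_kept = nrow(kept),
      category_counts = as.list(table(kept$category)),
      diff_link_recall = if (nrow(planted)) {
        mean(unlist(recovered))
      } else NA)
    emit("codina_links.tsv", function(p) readr::write_tsv(tidy(links), p))
    emit("codina_nodes.tsv", function(p) readr::write_tsv(nodes, p))
  })

  # ---- som -----------------------------------------------------------------
  if ("som" %in% config$stages) run_stage("som", function() {
    des <- map(setNames(1:final_day, paste0("d", 1:final_day)),
               function(d) de_test(expr, c("KO", "WT"), timepoint = d))
    nfc <- persistent_de_tfs(des, truth$tf_ids, alpha = config$alpha)
    planted <- truth$planted_clusters
    fit <- fit_som(nfc, seed = stage_seed(config$seed, "som"),
                   distortion_cut = config$distortion_cut)
    common <- intersect(nfc$gene_id, planted$gene_id)
    ari <- mclust::adjustedRandIndex(
      fit$membership$unit[match(common, fit$membership$gene_id)],
      planted$shape[match(common, planted$gene_id)])
    metrics$som <<- list(
      n_persistent = nrow(nfc),
      persistent_recall = mean(planted$gene_id %in% nfc$gene_id),
      grid = unname(fit$grid), avg_distortion = fit$avg_distortion,
      som_ari = ari)
    emit("som_membership.tsv", function(p) readr::write_tsv(tidy(fit), p))
    emit("som_summaries.tsv",
         function(p) readr::write_tsv(cluster_summaries(fit, nfc), p))
  })

  # ---- atlas ---------------------------------------------------------------
  if ("atlas" %in% config$stages) run_stage("atlas", function() {
    wt_final <- expr_slice(expr, "WT", final_day, "rpkm")
    profile_lin <- rowMeans(as.matrix(wt_final[, -1]))
    template <- setNames(log2(profile_lin + 1), wt_final$gene_id)
    atlas <- gen_atlas(cfg, template = template)
    gene_set <- top_de_genes(expr, "WT", timepoint = final_day,
                             n_top = min(config$n_top, nrow(wt_final)))
    acalls <- suppressMessages(correlate_to_atlas(
      tibble(gene_id = wt_final$gene_id, value = profile_lin),
      atlas, gene_set = gene_set)) |>
      call_region_age()
    best <- acalls[which.max(acalls$r), ]
    sig <- filter(acalls, .data$significant)
    is_template <- function(df) {
      nrow(df) == 1 && df$region == atlas$truth$template_region &&
        df$age == atlas$truth$template_age
    }
    metrics$atlas <<- list(
      best_r = best$r,
      top_block_correct = is_template(best),
      n_significant = nrow(sig),
      unique_significant_is_template = is_template(sig))
    emit("atlas_calls.tsv", function(p) readr::write_tsv(acalls, p))
  })

  # ---- mirna ---------------------------------------------------------------
  if ("mirna" %in% config$stages) run_stage("mirna", function() {
    mir <- gen_mirna_counts(cfg)
    wc <- normalize_counts(mir$wholecell)
    ip <- normalize_counts(mir$ip)
    abundant <- filter_abundant(mir$wholecell, min_counts = config$min_counts)
    mir_de <- function(x) {
      keep <- intersect(x$counts$mirna_id, abundant)
      # rescale normalized counts to count scale (grand housekeeping mean, a
      # constant) so the log transform in the Welch stage stabilizes variance
      hk_scale <- mean(as.matrix(
        filter(x$counts, .data$mirna_id %in% x$housekeeping)[,
                                                             x$samples$sample]))
      mat <- function(cond) {
        cols <- filter(x$samples, .data$condition == cond,
                       .data$timepoint == final_day)$sample
        m <- t(as.matrix(x$normalized[match(keep, x$counts$mirna_id), cols]))
        colnames(m) <- keep
        m * hk_scale
      }
      welch_de(mat("KO"), mat("WT"))
    }
    takeover <- takeover_candidates(mir_de(ip), mir_de(wc), abundant,
                                    alpha = config$alpha)
    sig_of <- function(x) {
      filter(x$profile, .data$timepoint == final_day,
             !.data$mirna_id %in% x$housekeeping) |>
        select("mirna_id", "condition", signal = "mean_normalized")
    }
    ranks <- suppressWarnings(activity_rank(sig_of(ip), sig_of(wc)))
    shifts <- rank_shifts(ranks)
    others <- setdiff(shifts$mirna_id, mir$truth$dominant_mirna)
    metrics$mirna <<- list(
      n_abundant = length(abundant),
      takeover = takeover,
      n_takeover = length(takeover),
      takeover_exact = setequal(takeover, mir$truth$takeover),
      frac_rank_not_worse = mean(
        shifts$shift[shifts$mirna_id %in% others] >= 0, na.rm = TRUE))
    emit("mirna_ranks.tsv", function(p) readr::write_tsv(ranks, p))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ripnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = config[setdiff(names(config), "outdir")],
    parameter_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    seeds = list(master = config$seed,
                 stages = map(setNames(nm = c("pileups", "expression",
                                              "mirna", "atlas", "wto",
                                              "som")),
                              ~stage_seed(config$seed, .x))),
    metrics = metrics,
    outputs = outputs,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest[setdiff(names(manifest), "timestamp")],
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(manifest, class = "ripnet_manifest")
}

#' @export
print.ripnet_manifest <- function(x, ...) {
  cat("<ripnet_manifest>", x$timestamp, "\n")
  cat("  stages run:", paste(names(x$metrics), collapse = ", "), "\n")
  for (st in names(x$metrics)) {
    m <- x$metrics[[st]]
    scalars <- m[vapply(m, function(v) is.numeric(v) || is.logical(v),
                        logical(1)) & lengths(m) == 1]
    cat(sprintf("  %-8s %s\n", st,
                paste(names(scalars), vapply(scalars, format, ""),
                      sep = "=", collapse = "  ")))
  }
  invisible(x)
}

#' Validate pipeline input files
#'
#' Checks bedGraph coordinate sanity and sortedness, assay-TSV headers,
#' annotation interval sanity, and gene-namespace overlap between
#' expression and atlas tables. Issues are reported as rows with level
#' "warning" or "fatal"; the presence of any fatal row means the inputs
#' cannot be run.
#'
#' @param paths Named list; recognized names: `bedgraph`, `expr_tsv`,
#'   `annotation_tsv`, `atlas_tsv` (any subset; each a file path).
#' @return Tibble `check`, `level`, `message` (zero rows when everything
#'   passes), with attribute `ok` = no fatal rows.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(check, level, message) {
    report[[length(report) + 1]] <<- tibble(check = check, level = level,
                                            message = message)
  }
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) note(nm, "fatal", "file does not exist")
  }
  expr_genes <- NULL
  if (!is.null(paths$bedgraph) && file.exists(paths$bedgraph)) {
    bg <- tryCatch(read_bedgraph(paths$bedgraph), error = function(e) NULL)
    if (is.null(bg)) {
      note("bedgraph", "fatal", "cannot be parsed as bedGraph")
    } else {
      if (any(bg$depth < 0)) note("bedgraph", "fatal", "negative depth")
      sorted <- bg |> group_by(.data$region_id) |>
        summarise(ok = !is.unsorted(.data$pos))
      if (!all(sorted$ok)) note("bedgraph", "warning",
                                "positions not sorted within region")
    }
  }
  if (!is.null(paths$expr_tsv) && file.exists(paths$expr_tsv)) {
    parsed <- tryCatch(read_assay_tsv(paths$expr_tsv),
                       error = function(e) NULL)
    if (is.null(parsed)) {
      note("expr_tsv", "fatal", "missing 3-row sample-metadata header")
    } else {
      expr_genes <- parsed$tbl[[1]]
      if (anyNA(parsed$samples$timepoint)) {
        note("expr_tsv", "warning", "non-integer timepoints in header")
      }
    }
  }
  if (!is.null(paths$annotation_tsv) && file.exists(paths$annotation_tsv)) {
    ann <- tryCatch(readr::read_tsv(paths$annotation_tsv,
                                    col_types = readr::cols(),
                                    progress = FALSE),
                    error = function(e) NULL)
    req <- c("region_id", "gene_id", "start", "end")
    if (is.null(ann) || !all(req %in% names(ann))) {
      note("annotation_tsv", "fatal",
           "needs columns region_id, gene_id, start, end")
    } else {
      if (any(ann$start < 0 | ann$end <= ann$start)) {
        note("annotation_tsv", "fatal",
             "intervals out of range for 0-based half-open coordinates")
      }
      extra <- setdiff(names(ann), c(req, "feature"))
      if (length(extra)) {
        note("annotation_tsv", "warning",
             paste("unknown extra columns:", paste(extra, collapse = ", ")))
      }
    }
  }
  if (!is.null(paths$atlas_tsv) && file.exists(paths$atlas_tsv)) {
    hdr <- readLines(paths$atlas_tsv, n = 2)
    if (!startsWith(hdr[1], "#region") || !startsWith(hdr[2], "#age")) {
      note("atlas_tsv", "fatal", "missing 2-row region/age column header")
    } else {
      atl <- readr::read_tsv(paths$atlas_tsv, skip = 2,
                             col_types = readr::cols(), progress = FALSE)
      if (!is.null(expr_genes) &&
          length(intersect(expr_genes, atl[[1]])) == 0) {
        note("atlas_tsv", "fatal",
             "no gene overlap between expression and atlas")
      }
    }
  }
  out <- if (length(report)) list_rbind(report) else
    tibble(check = character(), level = character(), message = character())
  attr(out, "ok") <- !any(out$level == "fatal")
  out
}

#' Read and write an atlas table with a two-row column header
#'
#' @param atlas An [atlas_matrix].
#' @param path File path.
#' @return `read_atlas_tsv()` returns an [atlas_matrix].
#' @export
write_atlas_tsv <- function(atlas, path) {
  meta <- atlas$meta[match(names(atlas$expr)[-1], atlas$meta$column), ]
  writeLines(c(paste(c("#region", meta$region), collapse = "\t"),
               paste(c("#age", meta$age), collapse = "\t")), path)
  readr::write_tsv(atlas$expr, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  hdr <- readLines(path, n = 2)
  stopifnot(startsWith(hdr[1], "#region"), startsWith(hdr[2], "#age"))
  expr <- readr::read_tsv(path, skip = 2, col_types = readr::cols(),
                          progress = FALSE)
  fields <- map(hdr, function(h) strsplit(h, "\t", fixed = TRUE)[[1]][-1])
  ages <- fields[[2]]
  meta <- tibble(column = names(expr)[-1], region = fields[[1]], age = ages,
                 age_order = match(ages, unique(ages)))
  atlas_matrix(expr, meta)
}
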