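#' Simulate a two-condition expression time course with planted structure
#'
#' Emulates a WT vs knockout neuronal-differentiation time course: `n_genes`
#' genes measured over `n_timepoints` days with `n_expr_replicates`
#' biological replicates per condition and day. Planted structure:
#'
#' * **TF modules** -- two co-regulation modules, each of five TFs plus ten
#'   member genes sharing a per-replicate latent factor. At the default
#'   `noise_dispersion`, within-module pairs have |Pearson r| above 0.9 across
#'   the replicates of one day; some loadings are negative so both correlation
#'   signs occur.
#' * **Differential links** -- in the knockout, from day 1 onward, one module-1
#'   TF has its loading sign flipped (expected "different"/beta links) and one
#'   module-2 TF is decoupled entirely (expected WT-specific/gamma links).
#' * **Targets** -- `planted_targets` (non-TF genes) gain `effect_size` log2
#'   units in the knockout from day 1 onward, as de-repressed miRNA targets
#'   do.
#' * **Trajectory shapes** -- two groups of five non-module TFs are
#'   differentially expressed on every day 1..4 with distinct fold-change
#'   trajectories (rising vs fading), the planted truth for trajectory
#'   clustering.
#' * **Developmental program** -- a block of genes drifts linearly with time
#'   identically in both conditions, mimicking the differentiation program
#'   that dominates expression change relative to day 0.
#'
#' Both conditions are statistically identical at day 0.
#'
#' @param cfg A [synth_config()].
#' @param rewire If FALSE, the knockout rewiring (sign flip / decoupling) is
#'   not applied and `planted_diff_links` is empty; with `effect_size = 0`
#'   the two conditions are then exchangeable draws from one model.
#' @return An [expr_set] carrying `counts`, `rpkm`, `samples` and a `truth`
#'   list (`planted_modules`, `planted_targets`, `planted_diff_links`,
#'   `planted_clusters`, `dev_genes`, `tf_ids`).
#' @export
#' @examples
#' expr <- gen_expression(synth_config(seed = 7, n_genes = 120))
gen_expression <- function(cfg, rewire = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_tfs > cfg$n_genes) abort("n_tfs cannot exceed n_genes")
  set.seed(stage_seed(cfg$seed, "expression"))

  G <- cfg$n_genes
  Tn <- cfg$n_timepoints
  R <- cfg$n_expr_replicates
  sigma <- cfg$noise_dispersion
  nb_size <- if (sigma > 0) 1 / sigma^2 else Inf

  n_tfs <- cfg$n_tfs
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  other_ids <- sprintf("G%04d", seq_len(G - n_tfs))
  gene_ids <- c(tf_ids, other_ids)

  # --- module layout: 2 modules x (5 TFs + 10 member genes) where room allows
  n_mod <- 2L
  tf_per_mod <- min(5L, n_tfs %/% (n_mod + 2L))
  mem_per_mod <- min(10L, max(0L, (G - n_tfs) %/% (4L * n_mod)))
  module_of <- setNames(rep(NA_integer_, G), gene_ids)
  loading <- setNames(rep(0, G), gene_ids)
  mod_rows <- list()
  for (m in seq_len(n_mod)) {
    tfs <- tf_ids[((m - 1) * tf_per_mod + 1):(m * tf_per_mod)]
    mems <- if (mem_per_mod > 0) {
      other_ids[((m - 1) * mem_per_mod + 1):(m * mem_per_mod)]
    } else character()
    ids <- c(tfs, mems)
    module_of[ids] <- m
    # alternate loading signs; lead TF is +1 so planted link signs are known
    loading[ids] <- rep_len(c(1, 1, 1, -1), length(ids))
    loading[tfs[1]] <- 1
    mod_rows[[m]] <- tibble(module = m, gene_id = ids,
                            role = rep(c("TF", "member"),
                                       c(length(tfs), length(mems))),
                            loading = loading[ids])
  }
  planted_modules <- list_rbind(mod_rows)
  mod_tfs <- function(m) {
    filter(planted_modules, .data$module == m, .data$role == "TF")$gene_id
  }

  # --- knockout rewiring (from day 1 onward)
  flip_tf <- if (rewire && tf_per_mod >= 2) mod_tfs(1)[2] else character()
  drop_tf <- if (rewire && tf_per_mod >= 2) mod_tfs(2)[2] else character()
  planted_diff_links <- if (length(c(flip_tf, drop_tf))) {
    bind_rows(
      tibble(node_i = flip_tf,
             node_j = setdiff(mod_tfs(1), flip_tf), expected = "beta"),
      tibble(node_i = drop_tf,
             node_j = setdiff(mod_tfs(2), drop_tf), expected = "gamma")
    ) |>
      mutate(a = pmin(.data$node_i, .data$node_j),
             b = pmax(.data$node_i, .data$node_j)) |>
      select(node_i = "a", node_j = "b", "expected")
  } else {
    tibble(node_i = character(), node_j = character(), expected = character())
  }

  # --- planted trajectory shapes on TFs outside the modules
  n_shape <- min(5L, max(0L, (n_tfs - n_mod * tf_per_mod) %/% 2L))
  free_tfs <- setdiff(tf_ids, planted_modules$gene_id)
  shape_tfs <- list(rising = head(free_tfs, n_shape),
                    fading = head(setdiff(free_tfs, head(free_tfs, n_shape)),
                                  n_shape))
  # nonzero from day 1 on both shapes, so shape TFs are DE on every day 1..4
  up <- c(0, seq(0.8, 2, length.out = Tn - 1))
  shape_profiles <- list(rising = cfg$effect_size * up,
                         fading = cfg$effect_size * c(0, rev(up[-1])))
  planted_clusters <- tibble(
    gene_id = unlist(shape_tfs, use.names = FALSE),
    shape = rep(names(shape_tfs), lengths(shape_tfs))
  )

  # --- planted knockout-upregulated targets and shared developmental genes
  pool <- setdiff(other_ids, planted_modules$gene_id)
  n_targets <- min(30L, length(pool) %/% 3L)
  planted_targets <- head(pool, n_targets)
  pool <- setdiff(pool, planted_targets)
  n_dev <- min(60L, length(pool))
  dev_genes <- head(pool, n_dev)
  dev_slope <- setNames(rnorm(n_dev, sd = 2), dev_genes)

  # --- sample sheet
  samples <- crossing(condition = c("WT", "KO"), timepoint = 0:(Tn - 1),
                      replicate = seq_len(R)) |>
    mutate(sample = sprintf("%s_d%d_r%d", .data$condition, .data$timepoint,
                            .data$replicate)) |>
    select("sample", "condition", "timepoint", "replicate")

  base_mu <- setNames(runif(G, 4, 8), gene_ids)      # log2 RPKM baseline

  log2_rpkm <- matrix(NA_real_, G, nrow(samples),
                      dimnames = list(gene_ids, samples$sample))
  for (s in seq_len(nrow(samples))) {
    cond <- samples$condition[s]
    day <- samples$timepoint[s]
    f <- rnorm(n_mod, mean = 0, sd = 1)              # per-replicate latents
    lo <- loading
    if (cond == "KO" && day >= 1) {
      if (length(flip_tf)) lo[flip_tf] <- -lo[flip_tf]
      if (length(drop_tf)) lo[drop_tf] <- 0
    }
    mu <- base_mu
    in_mod <- !is.na(module_of)
    mu[in_mod] <- mu[in_mod] + lo[in_mod] * f[module_of[in_mod]]
    if (n_dev > 0 && Tn > 1) {
      mu[dev_genes] <- mu[dev_genes] + dev_slope * day / (Tn - 1)
    }
    if (cond == "KO" && day >= 1 && length(planted_targets)) {
      mu[planted_targets] <- mu[planted_targets] + cfg$effect_size
    }
    if (cond == "KO") {
      for (sh in names(shape_tfs)) {
        ids <- shape_tfs[[sh]]
        if (length(ids)) mu[ids] <- mu[ids] + shape_profiles[[sh]][day + 1]
      }
    }
    log2_rpkm[, s] <- mu + rnorm(G, sd = sigma)
  }

  rpkm <- 2^log2_rpkm
  depth_factor <- 40
  counts <- matrix(
    if (is.finite(nb_size)) {
      rnbinom(length(rpkm), mu = rpkm * depth_factor, size = nb_size)
    } else {
      rpois(length(rpkm), lambda = rpkm * depth_factor)
    },
    nrow = G, dimnames = dimnames(rpkm)
  )

  to_tbl <- function(m) bind_cols(tibble(gene_id = gene_ids), as_tibble(m))
  truth <- list(planted_modules = planted_modules,
                planted_targets = planted_targets,
                planted_diff_links = planted_diff_links,
                planted_clusters = planted_clusters,
                shape_profiles = shape_profiles,
                dev_genes = dev_genes,
                dev_slopes = dev_slope,
                tf_ids = tf_ids)
  expr_set(counts = to_tbl(counts), rpkm = to_tbl(rpkm),
           samples = samples, truth = truth)
}

#' Synthetic annotated miRNA-target list
#'
#' Emulates the union of validated and predicted target databases: all
#' planted targets plus a margin of annotated-but-unaffected genes, since
#' seed-match predictions are deliberately over-inclusive.
#'
#' @param expr An [expr_set] from [gen_expression()].
#' @param n_extra Number of annotated non-target genes appended.
#' @return Character vector of annotated target gene ids.
#' @export
gen_target_list <- function(expr, n_extra = 15) {
  truth <- expr$truth
  if (is.null(truth)) abort("expr has no ground truth attached")
  extras <- head(truth$dev_genes, n_extra)
  sort(unique(c(truth$planted_targets, extras)))
}
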