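#' Simulate a block-structured region x age developmental atlas
#'
#' Builds an FPKM-like genes x (region, age) matrix in which each
#' (region, age) cell has its own expression signature around a shared gene
#' baseline. One designated cell (the "template block") is planted to match a
#' supplied query profile -- by default a synthetic profile drawn alongside
#' the atlas -- so that correlation profiling can be tested against a known
#' source block. Real developmental atlases drift smoothly with age; this
#' generator deliberately keeps cells close to independent so the planted
#' match is unambiguous.
#'
#' @param cfg A [synth_config()].
#' @param template Optional named numeric vector (log2 expression by gene id)
#'   to plant as the template block, e.g. a final-day mean profile from
#'   [gen_expression()]. When NULL a self-contained profile over
#'   `cfg$n_genes` synthetic gene ids is drawn and returned in the truth.
#' @param n_regions Number of atlas regions.
#' @param n_ages Number of ordered ages.
#' @return An [atlas_matrix] whose `truth` holds `template_region`,
#'   `template_age` and `template_profile` (log2 scale, named by gene).
#' @export
gen_atlas <- function(cfg, template = NULL, n_regions = 4, n_ages = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "atlas"))

  if (is.null(template)) {
    gene_ids <- c(sprintf("TF%02d", seq_len(cfg$n_tfs)),
                  sprintf("G%04d", seq_len(cfg$n_genes - cfg$n_tfs)))
    template <- setNames(runif(length(gene_ids), 4, 8) + rnorm(length(gene_ids)),
                         gene_ids)
  }
  gene_ids <- names(template)
  G <- length(gene_ids)

  regions <- sprintf("region%d", seq_len(n_regions))
  ages <- sprintf("age%02d", seq_len(n_ages))
  meta <- crossing(region = regions, age = ages) |>
    mutate(column = paste(.data$region, .data$age, sep = "|"),
           age_order = match(.data$age, ages)) |>
    select("column", "region", "age", "age_order")

  template_region <- regions[1]
  template_age <- ages[ceiling(n_ages / 2)]
  baseline <- runif(G, 4, 8)

  cols <- map(seq_len(nrow(meta)), function(i) {
    if (meta$region[i] == template_region && meta$age[i] == template_age) {
      mu <- template + rnorm(G, sd = 0.1)
    } else {
      mu <- baseline + rnorm(G, sd = 1.5)    # cell-specific signature
    }
    2^mu                                      # FPKM-like scale
  })
  expr <- bind_cols(tibble(gene_id = gene_ids),
                    setNames(as_tibble(cols, .name_repair = "minimal"),
                             meta$column))

  atlas_matrix(expr, meta,
               truth = list(template_region = template_region,
                            template_age = template_age,
                            template_profile = template))
}
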