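#' Configuration for the synthetic-data generators
#'
#' Bundles every knob the seeded generators share. Defaults describe a
#' two-condition (WT vs KO, a miR-124-like knockout) neuronal-differentiation
#' time course: five timepoints (0--4 days post induction), seven biological
#' replicates per condition and timepoint for expression, three replicates for
#' AGO2-RIP pileups, and 24 transcription factors among the simulated genes.
#'
#' @param seed Integer seed; a fixed seed makes every generator byte-identical.
#' @param n_regions Number of simulated transcript regions carrying pileups.
#' @param region_length Length of each region in bases.
#' @param n_pileup_replicates Pileup replicates per condition.
#' @param n_expr_replicates Expression replicates per condition per timepoint.
#' @param background_rate Mean Poisson background read depth per base (> 0).
#' @param site_height Summit read depth of planted binding sites.
#' @param site_width Width in bases of planted (triangular) binding sites.
#' @param n_genes Total number of simulated genes (TFs included).
#' @param n_tfs Number of transcription factors (must be <= `n_genes`).
#' @param n_timepoints Number of timepoints (days 0 .. n_timepoints - 1).
#' @param effect_size Planted knockout effect in log2 fold-change units.
#' @param noise_dispersion Log-normal sigma (log2 scale) for expression noise;
#'   also sets the negative-binomial dispersion of simulated counts.
#'
#' @return A `synth_config` list.
#' @export
#' @examples
#' cfg <- synth_config(seed = 7)
synth_config <- function(seed = 1,
                         n_regions = 40,
                         region_length = 500,
                         n_pileup_replicates = 3,
                         n_expr_replicates = 7,
                         background_rate = 2,
                         site_height = 40,
                         site_width = 60,
                         n_genes = 260,
                         n_tfs = 24,
                         n_timepoints = 5,
                         effect_size = 1.5,
                         noise_dispersion = 0.25) {
  cfg <- list(
    seed = as.integer(seed),
    n_regions = as.integer(n_regions),
    region_length = as.integer(region_length),
    n_pileup_replicates = as.integer(n_pileup_replicates),
    n_expr_replicates = as.integer(n_expr_replicates),
    background_rate = as.numeric(background_rate),
    site_height = as.numeric(site_height),
    site_width = as.integer(site_width),
    n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs),
    n_timepoints = as.integer(n_timepoints),
    effect_size = as.numeric(effect_size),
    noise_dispersion = as.numeric(noise_dispersion)
  )
  counts <- cfg[c("n_regions", "region_length", "n_pileup_replicates",
                  "n_expr_replicates", "n_genes", "n_tfs", "n_timepoints")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, logical(1)))) {
    abort("all counts in a synth_config must be >= 1")
  }
  if (cfg$background_rate < 0) {
    abort("background_rate must be non-negative")
  }
  if (cfg$site_width >= cfg$region_length) {
    abort("site_width must be smaller than region_length")
  }
  if (cfg$n_tfs > cfg$n_genes) {
    abort("n_tfs cannot exceed n_genes")
  }
  if (cfg$n_timepoints < 2) {
    abort("n_timepoints must be >= 2")
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Derive a stage seed from the master seed, staying inside 32-bit range.
stage_seed <- function(seed, stage) {
  offsets <- c(pileups = 101L, expression = 211L, mirna = 307L, atlas = 401L,
               wto = 503L, som = 601L, pipeline = 701L)
  (as.integer(seed) * 1000L + offsets[[stage]]) %% .Machine$integer.max
}
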