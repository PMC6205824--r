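#' Simulate AGO2-RIP read pileups with planted binding sites
#'
#' Generates per-base read-depth tracks for two conditions (WT, KO) over
#' `cfg$n_regions` transcript regions. Each track is Poisson background plus
#' planted isoceles-triangular binding sites. WT-specific sites appear in all
#' WT replicates and are absent from KO; some regions additionally carry a
#' shared site (both conditions) and a weak sub-background decoy site whose
#' summit sits below the 10-read background rule, so site callers are
#' exercised on both sides of that threshold.
#'
#' @param cfg A [synth_config()].
#' @return A list with `pileups` (tibble: `region_id`, `pos` 0-based, `depth`,
#'   `condition`, `replicate`) and `truth` (list with `planted_sites`: tibble
#'   of `region_id`, `start`, `end` (0-based half-open), `summit_pos`,
#'   `height`, `specificity` ("WT" or "shared"), `below_background`).
#' @export
#' @examples
#' sim <- gen_pileups(synth_config(seed = 1, n_regions = 4))
#' head(sim$pileups)
gen_pileups <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "pileups"))
  L <- cfg$region_length
  w <- cfg$site_width
  half <- w %/% 2

  regions <- sprintf("region_%02d", seq_len(cfg$n_regions))
  plant <- list()
  if (cfg$site_height > 0) {
    for (i in seq_along(regions)) {
      # deterministic slots with jitter; slots are far enough apart to stay
      # disjoint for any width < region_length / 4
      jit <- sample(-5:5, 3, replace = TRUE)
      centers <- pmin(pmax(round(L * c(0.25, 0.75, 0.5)) + jit, half + 1),
                      L - half - 1)
      plant[[i]] <- tibble(
        region_id = regions[i],
        center = centers,
        height = c(cfg$site_height, cfg$site_height, 8),
        specificity = c("WT", "shared", "shared"),
        below_background = c(FALSE, FALSE, TRUE),
        keep = c(TRUE, i %% 2 == 0, i %% 5 == 0)
      ) |> filter(.data$keep) |> select(-"keep")
    }
    plant <- list_rbind(plant)
  } else {
    plant <- tibble(region_id = character(), center = integer(),
                    height = numeric(), specificity = character(),
                    below_background = logical())
  }

  triangle <- function(center, height) {
    pos <- (center - half):(center + half)
    dep <- round(height * (1 - abs(pos - center) / (half + 1)))
    tibble(pos = pos, add = pmax(dep, 0))
  }

  grid <- crossing(condition = c("WT", "KO"),
                   replicate = seq_len(cfg$n_pileup_replicates),
                   region_id = regions)
  tracks <- pmap(grid, function(condition, replicate, region_id) {
    depth <- rpois(L, cfg$background_rate)
    here <- filter(plant, .data$region_id == !!region_id,
                   condition == "WT" | .data$specificity == "shared")
    if (nrow(here)) {
      for (k in seq_len(nrow(here))) {
        tri <- triangle(here$center[k], here$height[k])
        depth[tri$pos + 1L] <- depth[tri$pos + 1L] + tri$add
      }
    }
    tibble(region_id = region_id, pos = 0:(L - 1L), depth = depth,
           condition = condition, replicate = replicate)
  }) |> list_rbind()

  planted_sites <- plant |>
    mutate(start = .data$center - half, end = .data$center + half + 1L,
           summit_pos = .data$center) |>
    select("region_id", "start", "end", summit_pos = "summit_pos",
           height = "height", "specificity", "below_background")

  list(pileups = tracks,
       truth = list(planted_sites = planted_sites))
}

#' Synthetic 3'UTR annotation linking pileup regions to genes
#'
#' Maps each simulated pileup region to one gene and marks a 3'UTR interval
#' inside it. The interval is placed so that the planted WT-specific site
#' (near 1/4 of the region) falls inside the 3'UTR while the planted shared
#' site (near 3/4) falls outside -- mirroring the fact that miRNA-guided AGO2
#' binding is scored only within annotated 3'UTRs.
#'
#' @param cfg A [synth_config()].
#' @param gene_ids Character vector of gene ids, one per region (recycled
#'   against `cfg$n_regions`; must have at least that many).
#' @return Annotation tibble: `region_id`, `gene_id`, `start`, `end`
#'   (0-based half-open), `feature` = "three_prime_UTR".
#' @export
gen_annotation <- function(cfg, gene_ids) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(gene_ids) < cfg$n_regions) {
    abort("need at least one gene id per region")
  }
  L <- cfg$region_length
  tibble(
    region_id = sprintf("region_%02d", seq_len(cfg$n_regions)),
    gene_id = gene_ids[seq_len(cfg$n_regions)],
    start = round(L * 0.1),
    end = round(L * 0.6),
    feature = "three_prime_UTR"
  )
}
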