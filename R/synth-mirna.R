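#' Simulate nCounter-style miRNA count tables (whole cell and AGO2-IP)
#'
#' Generates raw miRNA x sample count tables for two conditions (WT, KO) at
#' day 0 and the final day, three replicates each (12 samples, the published
#' assay layout). Planted structure:
#'
#' * a **dominant miRNA** that grows to roughly 80 % of the WT count mass by
#'   the final day and has zero counts in the knockout at every timepoint
#'   (the ablated species);
#' * three **takeover miRNAs** upregulated in the knockout at the final day in
#'   both the whole-cell and the AGO2-IP table -- the species absorbing the
#'   freed RISC capacity;
#' * **housekeeping rows** with condition- and time-independent means, used
#'   for per-replicate normalization;
#' * per-sample depth factors, so raw totals differ by lane depth.
#'
#' @param cfg A [synth_config()].
#' @param n_mirna Number of (non-housekeeping) miRNA species.
#' @param n_housekeeping Number of housekeeping rows.
#' @param dispersion Negative-binomial dispersion of the counts. Default
#'   0.15: digital hybridization counting replicates more tightly than
#'   sequencing, so this is deliberately below the expression generator's
#'   noise.
#' @return List with `wholecell` and `ip` ([mirna_set] objects sharing sample
#'   metadata) and `truth` (list: `dominant_mirna`, `takeover`,
#'   `housekeeping`).
#' @export
gen_mirna_counts <- function(cfg, n_mirna = 50, n_housekeeping = 5,
                             dispersion = 0.15) {
  stopifnot(inherits(cfg, "synth_config"))
  if (n_housekeeping < 1) abort("housekeeping set must be non-empty")
  set.seed(stage_seed(cfg$seed, "mirna"))

  final_day <- cfg$n_timepoints - 1L
  samples <- crossing(condition = c("WT", "KO"),
                      timepoint = c(0L, final_day),
                      replicate = 1:3) |>
    mutate(sample = sprintf("%s_d%d_r%d", .data$condition, .data$timepoint,
                            .data$replicate)) |>
    select("sample", "condition", "timepoint", "replicate")

  mirna_ids <- sprintf("miR%03d", seq_len(n_mirna))
  hk_ids <- sprintf("HK%02d", seq_len(n_housekeeping))
  dominant <- mirna_ids[1]
  takeover <- mirna_ids[2:4]

  base <- setNames(2^runif(n_mirna, 4, 9), mirna_ids)   # abundance scale
  # takeover species are drawn from the abundant end of the panel
  base[takeover] <- 2^runif(length(takeover), 8.5, 9)
  hk_base <- setNames(rep(5000, n_housekeeping), hk_ids)
  nb_size <- if (dispersion > 0) 1 / dispersion^2 else Inf
  # per-species RISC-loading efficiency: spread so activity ranks are stable
  act <- setNames(2^seq(-2, 2, length.out = n_mirna), mirna_ids)
  act[dominant] <- 4
  act[takeover] <- 1

  one_table <- function(ip) {
    cols <- map(seq_len(nrow(samples)), function(s) {
      cond <- samples$condition[s]
      day <- samples$timepoint[s]
      mu <- base
      if (ip) mu <- mu * 0.5 * act                       # IP capture x loading
      if (cond == "KO") {
        mu[dominant] <- 0
        # takeover species absorb the freed RISC capacity: a large jump
        if (day == final_day) {
          mu[takeover] <- mu[takeover] * 2^(2 * cfg$effect_size)
        }
      } else if (day == final_day) {
        # dominant species ~80% of the WT profile at the final day
        mu[dominant] <- 4 * sum(mu[setdiff(mirna_ids, dominant)])
      }
      depth <- 2^rnorm(1, sd = 0.3)
      lam <- c(mu, hk_base) * depth
      counts <- if (is.finite(nb_size)) {
        rnbinom(length(lam), mu = lam, size = nb_size)
      } else {
        rpois(length(lam), lam)
      }
      as.integer(counts)
    })
    tbl <- bind_cols(tibble(mirna_id = c(mirna_ids, hk_ids)),
                     setNames(as_tibble(cols, .name_repair = "minimal"),
                              samples$sample))
    mirna_set(tbl, samples, hk_ids)
  }

  wholecell <- one_table(ip = FALSE)
  ip <- one_table(ip = TRUE)
  truth <- list(dominant_mirna = dominant, takeover = takeover,
                housekeeping = hk_ids)
  wholecell$truth <- truth
  ip$truth <- truth
  list(wholecell = wholecell, ip = ip, truth = truth)
}
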