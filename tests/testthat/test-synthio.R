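test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 1)
  expect_identical(gen_pileups(cfg), gen_pileups(cfg))
  expect_identical(gen_expression(cfg), gen_expression(cfg))
  expect_identical(gen_mirna_counts(cfg), gen_mirna_counts(cfg))
  a1 <- gen_atlas(cfg)
  a2 <- gen_atlas(cfg)
  expect_identical(a1$expr, a2$expr)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(site_width = 500, region_length = 500), "site_width")
  expect_error(synth_config(n_tfs = 50, n_genes = 40), "n_tfs")
  expect_error(synth_config(n_timepoints = 1), "n_timepoints")
  expect_error(synth_config(background_rate = -1), "background_rate")
  expect_error(gen_mirna_counts(small_cfg(), n_housekeeping = 0),
               "housekeeping")
})

test_that("degenerate pileup configurations behave as stated", {
  # no planted sites: pure Poisson noise
  cfg0 <- small_cfg(seed = 2, site_height = 0)
  sim0 <- gen_pileups(cfg0)
  expect_equal(nrow(sim0$truth$planted_sites), 0)
  # noise-free: depth only inside planted sites
  cfg1 <- small_cfg(seed = 3, background_rate = 0)
  sim1 <- gen_pileups(cfg1)
  tr <- dplyr::filter(sim1$pileups, condition == "WT", replicate == 1)
  outside <- dplyr::anti_join(
    tr,
    tidyr::crossing(dplyr::select(sim1$truth$planted_sites,
                                  region_id, start, end),
                    pos = 0:(cfg1$region_length - 1)) |>
      dplyr::filter(pos >= start, pos < end) |>
      dplyr::select(region_id, pos),
    by = c("region_id", "pos"))
  expect_true(all(outside$depth == 0))
  # WT-specific sites are absent from every KO replicate
  ko <- dplyr::filter(sim1$pileups, condition == "KO")
  wt_only <- dplyr::filter(sim1$truth$planted_sites, specificity == "WT")
  in_wt_sites <- dplyr::inner_join(ko, wt_only, by = "region_id",
                                   relationship = "many-to-many") |>
    dplyr::filter(pos >= start, pos < end)
  expect_true(all(in_wt_sites$depth == 0))
})

test_that("expression generator realizes the planted structure", {
  cfg <- small_cfg(seed = 7)
  expr <- gen_expression(cfg)
  truth <- expr$truth
  # all planted ids exist in the emitted data
  ids <- expr$counts$gene_id
  expect_true(all(truth$planted_targets %in% ids))
  expect_true(all(truth$planted_modules$gene_id %in% ids))
  expect_true(all(c(truth$planted_diff_links$node_i,
                    truth$planted_diff_links$node_j) %in% truth$tf_ids))
  # within-module correlation exceeds 0.9 in absolute value; measured with
  # many replicates so the sample estimate reflects the generative model
  big <- gen_expression(small_cfg(seed = 7, n_expr_replicates = 60))
  x <- expr_slice(big, "WT", 2, "rpkm", log2 = TRUE)
  m <- t(as.matrix(x[, -1]))
  colnames(m) <- x$gene_id
  mod1 <- dplyr::filter(big$truth$planted_modules, module == 1)$gene_id
  cors <- cor(m[, mod1])
  expect_true(all(abs(cors[upper.tri(cors)]) > 0.9))
  # both conditions identical in distribution at day 0: no DE calls
  de0 <- de_test(expr, c("KO", "WT"), timepoint = 0)
  expect_equal(sum(de0$padj < 0.05), 0)
})

test_that("noise-free expression gives exactly unit within-module correlation", {
  cfg <- small_cfg(seed = 4, noise_dispersion = 0)
  expr <- gen_expression(cfg)
  x <- expr_slice(expr, "WT", 1, "rpkm")
  m <- log2(t(as.matrix(x[, -1])))
  colnames(m) <- x$gene_id
  mod <- dplyr::filter(expr$truth$planted_modules, module == 1)
  cors <- cor(m[, mod$gene_id])
  expect_equal(abs(cors[upper.tri(cors)]), rep(1, sum(upper.tri(cors))),
               tolerance = 1e-12)
  # signs follow the planted loadings
  expect_equal(sign(cors), outer(sign(mod$loading), sign(mod$loading)),
               ignore_attr = TRUE)
})

test_that("exchangeable conditions carry no planted differences", {
  cfg <- small_cfg(seed = 5, effect_size = 0)
  expr <- gen_expression(cfg, rewire = FALSE)
  expect_equal(nrow(expr$truth$planted_diff_links), 0)
  de <- de_test(expr, c("KO", "WT"), timepoint = cfg$n_timepoints - 1)
  expect_equal(sum(de$padj < 0.05), 0)
})

test_that("the built-in DE stage recovers planted targets at default settings", {
  expr <- gen_expression(synth_config(seed = 7))
  de <- de_test(expr, c("KO", "WT"), timepoint = 4)
  hits <- de$gene_id[de$padj < 0.05 & de$log2fc > 0]
  recall <- mean(expr$truth$planted_targets %in% hits)
  expect_gte(recall, 0.9)
})

test_that("miRNA tables carry the ablated dominant species and stable background", {
  cfg <- small_cfg(seed = 6)
  mir <- gen_mirna_counts(cfg)
  wc <- mir$wholecell
  ko_cols <- dplyr::filter(wc$samples, condition == "KO")$sample
  dom_row <- wc$counts[wc$counts$mirna_id == mir$truth$dominant_mirna, ]
  expect_true(all(dom_row[, ko_cols] == 0))
  # dominant species ~80% of the WT profile at the final day
  final <- cfg$n_timepoints - 1
  wt_final <- dplyr::filter(wc$samples, condition == "WT",
                            timepoint == final)$sample
  m <- as.matrix(wc$counts[!wc$counts$mirna_id %in% wc$housekeeping,
                           wt_final])
  frac <- as.numeric(dom_row[, wt_final]) / colSums(m)
  expect_true(all(abs(frac - 0.8) < 0.05))
  # day-0 normalized profiles overlap between conditions (dominant aside)
  norm <- normalize_counts(wc)
  p0 <- dplyr::filter(norm$profile, timepoint == 0,
                      mirna_id != mir$truth$dominant_mirna,
                      !mirna_id %in% wc$housekeeping)
  ks <- suppressWarnings(ks.test(
    p0$mean_normalized[p0$condition == "WT"],
    p0$mean_normalized[p0$condition == "KO"]))
  expect_gt(ks$p.value, 0.05)
})

test_that("the atlas template block is its own best correlate", {
  cfg <- small_cfg(seed = 8)
  atlas <- gen_atlas(cfg)
  truth <- atlas$truth
  prof <- tibble::tibble(gene_id = names(truth$template_profile),
                         value = 2^truth$template_profile)
  calls <- suppressMessages(correlate_to_atlas(prof, atlas))
  best <- calls[which.max(calls$r), ]
  expect_equal(best$region, truth$template_region)
  expect_equal(best$age, truth$template_age)
})
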