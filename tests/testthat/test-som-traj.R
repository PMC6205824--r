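fake_de <- function(sig_genes, lfc, all_genes) {
  tibble::tibble(gene_id = all_genes,
                 log2fc = lfc[all_genes],
                 pvalue = ifelse(all_genes %in% sig_genes, 1e-6, 0.8),
                 padj = ifelse(all_genes %in% sig_genes, 1e-4, 0.9))
}

test_that("persistence requires significance on every day", {
  genes <- c("TF1", "TF2", "TF3", "G1")
  lfc <- stats::setNames(c(1, 2, 3, 4), genes)
  des <- list(d1 = fake_de(c("TF1", "TF2", "G1"), lfc, genes),
              d2 = fake_de(c("TF1", "TF2", "G1"), lfc, genes),
              d3 = fake_de(c("TF1", "TF2", "G1"), lfc, genes),
              d4 = fake_de(c("TF1", "G1"), lfc, genes))
  out <- persistent_de_tfs(des, tf_list = c("TF1", "TF2", "TF3"))
  # TF2 misses one day, G1 is not a TF
  expect_equal(out$gene_id, "TF1")
  # empty DE tables give an empty result
  empty <- dplyr::mutate(des$d1, padj = 1)
  expect_equal(nrow(persistent_de_tfs(list(empty), c("TF1"))), 0)
})

test_that("nFC trajectories are standardized within each day", {
  genes <- paste0("TF", 1:4)
  lfc1 <- stats::setNames(c(1, 2, 3, 4), genes)
  lfc2 <- stats::setNames(c(10, 20, 30, 40), genes)
  des <- list(d1 = fake_de(genes, lfc1, genes),
              d2 = fake_de(genes, lfc2, genes))
  out <- persistent_de_tfs(des, genes)
  expect_equal(mean(out$nfc_d1), 0, tolerance = 1e-12)
  expect_equal(sd(out$nfc_d1), 1, tolerance = 1e-12)
  # same z-scores despite the 10x larger raw fold changes on day 2
  expect_equal(out$nfc_d1, out$nfc_d2, tolerance = 1e-12)
})

test_that("a 2-unit SOM separates two well-separated shapes exactly", {
  withr::local_seed(41)
  up <- c(-1.5, -0.5, 0.5, 1.5)
  traj <- rbind(t(replicate(8, up + rnorm(4, sd = 0.1))),
                t(replicate(8, rev(up) + rnorm(4, sd = 0.1))))
  nfc <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("TF%02d", 1:16)),
    tibble::as_tibble(traj, .name_repair = ~paste0("nfc_d", 1:4)))
  fit <- fit_som(nfc, seed = 9)
  labels <- rep(c("up", "down"), each = 8)
  expect_equal(mclust::adjustedRandIndex(fit$membership$unit, labels), 1)
  # deterministic under the seed
  fit2 <- fit_som(nfc, seed = 9)
  expect_identical(fit$membership, fit2$membership)
})

test_that("identical trajectories collapse onto one unit with zero distortion", {
  nfc <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("TF", 1:6)),
    tibble::as_tibble(matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6),
                      .name_repair = ~paste0("nfc_d", 1:4)))
  fit <- fit_som(nfc, seed = 1)
  expect_equal(dplyr::n_distinct(fit$membership$unit), 1)
  expect_equal(fit$avg_distortion, 0)
})

test_that("distortion does not increase along the grid growth path", {
  withr::local_seed(42)
  # six well-separated trajectory shapes force growth through several grids
  # before the stopping rule is satisfied
  shapes <- rbind(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2),
                  c(0, 2, 0, -2, 0), c(0, -2, 0, 2, 0),
                  c(2, 2, -2, -2, 0), c(-2, -2, 2, 2, 0))
  traj <- do.call(rbind, lapply(1:6, function(k) {
    t(replicate(10, shapes[k, ] + rnorm(5, sd = 0.15)))
  }))
  nfc <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("TF%02d", 1:60)),
    tibble::as_tibble(traj, .name_repair = ~paste0("nfc_d", 1:5)))
  fit <- fit_som(nfc, seed = 2, distortion_cut = 0.3)
  expect_gte(nrow(fit$growth), 3)
  expect_true(all(diff(fit$growth$avg_distortion) <= 1e-8))
  expect_lt(fit$avg_distortion, 0.3)
})

test_that("cluster summaries smooth faithfully", {
  # single-member cluster with a quadratic trajectory: smooth interpolates it
  quad <- (1:5 - 3)^2
  lin <- 2 * (1:5) - 3
  nfc <- dplyr::bind_cols(
    tibble::tibble(gene_id = c("TFq", "TFl")),
    tibble::as_tibble(rbind(quad, lin), .name_repair = ~paste0("nfc_d", 1:5)))
  fit <- fit_som(nfc, seed = 3, distortion_cut = 0.5)
  sm <- cluster_summaries(fit, nfc)
  unit_q <- fit$membership$unit[fit$membership$gene_id == "TFq"]
  unit_l <- fit$membership$unit[fit$membership$gene_id == "TFl"]
  expect_equal(sm$smooth_nfc[sm$unit == unit_q], quad, tolerance = 1e-6)
  expect_equal(sm$smooth_nfc[sm$unit == unit_l], lin, tolerance = 1e-6)
  # a rising cluster keeps a strictly increasing smooth
  withr::local_seed(43)
  rising <- t(replicate(6, seq(-2, 2, length.out = 5) + rnorm(5, sd = 0.05)))
  nfc2 <- dplyr::bind_cols(
    tibble::tibble(gene_id = paste0("TF", 1:6)),
    tibble::as_tibble(rising, .name_repair = ~paste0("nfc_d", 1:5)))
  fit2 <- fit_som(nfc2, seed = 4)
  sm2 <- cluster_summaries(fit2, nfc2)
  for (u in unique(sm2$unit)) {
    expect_true(all(diff(sm2$smooth_nfc[sm2$unit == u]) > 0))
  }
})

test_that("SOM recovers planted trajectory shapes from the full chain", {
  expr <- gen_expression(synth_config(seed = 7))
  final <- 4
  des <- lapply(stats::setNames(1:final, paste0("d", 1:final)),
                function(d) de_test(expr, c("KO", "WT"), timepoint = d))
  nfc <- persistent_de_tfs(des, expr$truth$tf_ids)
  planted <- expr$truth$planted_clusters
  expect_setequal(nfc$gene_id, planted$gene_id)
  fit <- fit_som(nfc, seed = 11)
  ari <- mclust::adjustedRandIndex(
    fit$membership$unit,
    planted$shape[match(fit$membership$gene_id, planted$gene_id)])
  expect_gte(ari, 0.9)
})
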