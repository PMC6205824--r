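track <- function(depth, region = "r") {
  tibble::tibble(region_id = region, pos = seq_along(depth) - 1L,
                 depth = depth)
}

test_that("background-level and empty tracks give no sites", {
  expect_equal(nrow(split_sites(track(integer(0)))), 0)
  expect_equal(nrow(split_sites(track(rep(0L, 50)))), 0)
  # a plateau just under the 10-read background rule is discarded
  expect_equal(nrow(split_sites(track(c(0, rep(9, 20), 0)))), 0)
  # and at exactly 10 it is kept
  expect_equal(nrow(split_sites(track(c(0, rep(10, 20), 0)))), 1)
})

test_that("a valley below 20% of the summit splits two bumps", {
  depth <- rep(0, 40)
  # triangular bump, summit 40 at pos 10 (depth[i] sits at pos i - 1)
  depth[7:16] <- c(8, 16, 24, 32, 40, 32, 24, 16, 10, 9)
  depth[17:21] <- 3                       # valley below 0.2 * 40 = 8
  depth[22:31] <- c(9, 15, 22, 30, 22, 15, 9, 9, 9, 9)  # second bump, summit 30
  s <- split_sites(track(depth))
  expect_equal(nrow(s), 2)
  expect_equal(s$summit_height, c(40, 30))
  expect_equal(s$summit_pos, c(10, 24))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))  # disjoint, ordered
})

test_that("split_sites agrees exactly with the brute-force oracle", {
  withr::local_seed(401)
  for (i in 1:250) {
    tr <- random_track()
    got <- split_sites(tibble::as_tibble(tr))
    want <- oracle_split_track(tr)
    expect_equal(nrow(got), nrow(want), info = paste("case", i))
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = paste("case", i))
      expect_equal(got$end, want$end, info = paste("case", i))
      expect_equal(got$summit_pos, want$summit_pos, info = paste("case", i))
      expect_equal(got$summit_height, want$summit_height,
                   info = paste("case", i))
      expect_equal(got$depth_sum, want$depth_sum, info = paste("case", i))
    }
  }
})

test_that("summits respect the background threshold and are monotone in it", {
  withr::local_seed(402)
  for (i in 1:30) {
    tr <- tibble::as_tibble(random_track())
    n_sites <- sapply(c(5, 10, 20, 40), function(tau) {
      s <- split_sites(tr, tau_background = tau)
      expect_true(all(s$summit_height >= tau))
      nrow(s)
    })
    expect_true(all(diff(n_sites) <= 0))
  }
})

test_that("re-splitting an emitted site returns it unchanged", {
  withr::local_seed(403)
  for (i in 1:30) {
    tr <- tibble::as_tibble(random_track())
    sites <- split_sites(tr)
    for (k in seq_len(nrow(sites))) {
      sub <- dplyr::filter(tr, region_id == sites$region_id[k],
                           pos >= sites$start[k], pos < sites$end[k])
      again <- split_sites(sub)
      expect_equal(nrow(again), 1)
      expect_equal(again$start, sites$start[k])
      expect_equal(again$end, sites$end[k])
      expect_equal(again$summit_height, sites$summit_height[k])
    }
  }
})

test_that("consensus requires support in every replicate", {
  s1 <- split_sites(track(c(0, 20, 30, 20, 0, 0, 0, 15, 20, 15, 0)))
  expect_equal(nrow(s1), 2)
  # one replicate: identity
  expect_identical(consensus_sites(list(s1)), s1)
  # second replicate only supports the first site
  s2 <- split_sites(track(c(0, 25, 35, 25, 0, 0, 0, 0, 0, 0, 0)))
  s3 <- split_sites(track(c(0, 18, 28, 18, 0, 0, 0, 12, 18, 12, 0)))
  cons <- consensus_sites(list(s1, s2, s3))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$summit_pos, 2)
  # present in 2 of 3 replicates: dropped
  expect_false(8 %in% cons$summit_pos)
  # depth_sum is the replicate mean of overlapping-site sums
  expect_equal(cons$depth_sum,
               mean(c(s1$depth_sum[1], s2$depth_sum[1], s3$depth_sum[1])))
})

test_that("condition-specific filtering removes any KO-overlapping site", {
  a <- split_sites(track(c(0, 20, 30, 20, 0, 0, 15, 20, 15, 0)))
  expect_equal(nrow(condition_specific_sites(a, a)), 0)
  b <- a |> dplyr::mutate(start = start + 100, end = end + 100,
                          summit_pos = summit_pos + 100)
  expect_equal(nrow(condition_specific_sites(a, b)), nrow(a))
})

test_that("planted sites are recovered through consensus at default settings", {
  cfg <- synth_config(seed = 7, n_regions = 20)
  sim <- gen_pileups(cfg)
  consensus <- lapply(c(WT = "WT", KO = "KO"), function(cond) {
    reps <- dplyr::filter(sim$pileups, condition == cond)
    consensus_sites(lapply(sort(unique(reps$replicate)), function(r) {
      split_sites(dplyr::filter(reps, replicate == r))
    }))
  })
  planted_wt <- dplyr::filter(sim$truth$planted_sites,
                              specificity == "WT", !below_background)
  hits <- ripnet:::overlap_pairs(planted_wt, consensus$WT)
  expect_gte(length(unique(hits$i)) / nrow(planted_wt), 0.95)
  # WT-specific filtering keeps planted WT sites, drops shared ones
  specific <- condition_specific_sites(consensus$WT, consensus$KO)
  hits2 <- ripnet:::overlap_pairs(planted_wt, specific)
  expect_gte(length(unique(hits2$i)) / nrow(planted_wt), 0.95)
  shared <- dplyr::filter(sim$truth$planted_sites, specificity == "shared",
                          !below_background)
  expect_equal(nrow(ripnet:::overlap_pairs(shared, specific)), 0)
})

test_that("3'UTR signal is summed and normalized by whole-cell expression", {
  sites <- tibble::tibble(region_id = "r1", start = 10L, end = 30L,
                          summit_pos = 20L, summit_height = 50,
                          parent_id = "r1:c1", depth_sum = 200)
  ann <- tibble::tibble(region_id = "r1", gene_id = "G1", start = 0L,
                        end = 100L, feature = "three_prime_UTR")
  samples <- tibble::tibble(sample = c("s1", "s2"), condition = "WT",
                            timepoint = 0L, replicate = 1:2)
  expr <- expr_set(rpkm = tibble::tibble(gene_id = c("G1", "G2"),
                                         s1 = c(10, 0), s2 = c(10, 0)),
                   samples = samples)
  out <- annotate_and_normalize(sites, ann, expr)
  expect_equal(out$gene_id, "G1")
  expect_equal(out$normalized_signal, 20)
  # a site outside every 3'UTR yields no rows
  ann2 <- dplyr::mutate(ann, start = 50L, end = 60L)
  expect_equal(nrow(annotate_and_normalize(sites, ann2, expr)), 0)
  # zero whole-cell expression: undefined normalized signal
  ann3 <- dplyr::mutate(ann, gene_id = "G2")
  out3 <- annotate_and_normalize(sites, ann3, expr)
  expect_true(is.na(out3$normalized_signal))
  # coordinate mismatch is an error
  bad <- dplyr::mutate(ann, end = -5L)
  expect_error(annotate_and_normalize(sites, bad, expr), "out of range")
})
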