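toy_atlas <- function(r_mat, genes = 30, seed = 51) {
  # build an atlas whose columns are noisy copies/negations of a template
  set.seed(seed)
  template <- rnorm(genes, 6, 1)
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(r_mat))) {
    col <- paste(r_mat$region[i], r_mat$age[i], sep = "|")
    cols[[col]] <- 2^(r_mat$mix[i] * template +
                        (1 - abs(r_mat$mix[i])) * rnorm(genes, 6, 1))
    meta[[i]] <- tibble::tibble(column = col, region = r_mat$region[i],
                                age = r_mat$age[i],
                                age_order = as.integer(factor(r_mat$age[i])))
  }
  atlas_matrix(dplyr::bind_cols(tibble::tibble(
    gene_id = paste0("g", seq_len(genes))), tibble::as_tibble(cols)),
    dplyr::bind_rows(meta))
}

test_that("top-ranked DE genes are deterministic and complete", {
  expr <- gen_expression(small_cfg(seed = 1))
  all_genes <- expr$counts$gene_id
  top_all <- top_de_genes(expr, "WT", timepoint = 4, n_top = 10 * length(all_genes))
  expect_setequal(top_all, all_genes)
  # planted developmental responders with a clear slope occupy the top ranks
  dev <- expr$truth$dev_genes
  strong <- dev[abs(expr$truth$dev_slopes) > 1]
  top_dev <- top_de_genes(expr, "WT", timepoint = 4, n_top = length(dev))
  expect_true(all(strong %in% top_dev))
  # deterministic under the tie rule even with no expression change
  flat <- expr
  flat$counts <- dplyr::mutate(flat$counts,
                               dplyr::across(-gene_id, ~1000))
  t1 <- top_de_genes(flat, "WT", timepoint = 4, n_top = 20)
  t2 <- top_de_genes(flat, "WT", timepoint = 4, n_top = 20)
  expect_identical(t1, t2)
})

test_that("atlas correlation is exact for copies, negations and affine maps", {
  expr <- 2^matrix(rnorm(40 * 3, 6), nrow = 40)
  atlas <- atlas_matrix(
    dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:40)),
                     tibble::as_tibble(expr,
                                       .name_repair = ~c("A|a1", "A|a2",
                                                         "B|a1"))),
    tibble::tibble(column = c("A|a1", "A|a2", "B|a1"),
                   region = c("A", "A", "B"), age = c("a1", "a2", "a1"),
                   age_order = c(1L, 2L, 1L)))
  prof <- tibble::tibble(gene_id = paste0("g", 1:40),
                         value = expr[, 1])
  calls <- suppressMessages(correlate_to_atlas(prof, atlas))
  expect_equal(calls$r[calls$region == "A" & calls$age == "a1"], 1)
  # negated profile in log space: r = -1
  neg <- tibble::tibble(gene_id = prof$gene_id,
                        value = 2^(-log2(prof$value + 1)) - 1)
  calls_neg <- suppressMessages(correlate_to_atlas(neg, atlas))
  expect_equal(calls_neg$r[1], -1, tolerance = 1e-12)
  # affine transformation of the log profile leaves r unchanged
  aff <- tibble::tibble(gene_id = prof$gene_id,
                        value = 2^(3 * log2(prof$value + 1) + 2) - 1)
  calls_aff <- suppressMessages(correlate_to_atlas(aff, atlas))
  expect_equal(calls_aff$r, calls$r, tolerance = 1e-12)
  # gene order never matters
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(suppressMessages(correlate_to_atlas(shuffled, atlas))$r,
               calls$r, tolerance = 1e-12)
})

test_that("the two-SD rule calls only clear region-age matches", {
  grid <- tidyr::crossing(region = c("R1", "R2", "R3", "R4"),
                          age = c("a1", "a2", "a3"))
  # R1 at a2 is a faithful copy; everything else is noise
  grid$mix <- ifelse(grid$region == "R1" & grid$age == "a2", 0.995, 0)
  atlas <- toy_atlas(grid, genes = 200)
  prof <- tibble::tibble(gene_id = atlas$expr$gene_id,
                         value = atlas$expr[["R1|a2"]])
  calls <- call_region_age(suppressMessages(correlate_to_atlas(prof, atlas)))
  sig <- calls[calls$significant, ]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$region, "R1")
  expect_equal(sig$age, "a2")
  # identical regions at an age: difference 0, SD 0, no call
  same <- tibble::tibble(
    region = rep(c("X", "Y", "Z"), each = 1), age = "a1", mix = 0.9)
  atlas2 <- toy_atlas(same, genes = 50, seed = 52)
  # make the three columns exactly identical
  atlas2$expr[["Y|a1"]] <- atlas2$expr[["X|a1"]]
  atlas2$expr[["Z|a1"]] <- atlas2$expr[["X|a1"]]
  prof2 <- tibble::tibble(gene_id = atlas2$expr$gene_id,
                          value = atlas2$expr[["X|a1"]])
  calls2 <- call_region_age(
    suppressMessages(correlate_to_atlas(prof2, atlas2)))
  expect_equal(sum(calls2$significant), 0)
})

test_that("region merging averages shared ages and concatenates disjoint ones", {
  grid <- tidyr::crossing(region = c("cb", "cbc", "ctx"),
                          age = c("a1", "a2"))
  grid$mix <- 0
  atlas <- toy_atlas(grid, genes = 20, seed = 53)
  # merging a region with itself is the identity
  expect_identical(merge_regions(atlas, "ctx", new_region = "ctx"), atlas)
  # identical regions merge to their common column
  atlas$expr[["cbc|a1"]] <- atlas$expr[["cb|a1"]]
  merged <- merge_regions(atlas, c("cb", "cbc"))
  expect_equal(merged$expr[["cb+cbc|a1"]], atlas$expr[["cb|a1"]])
  # shared ages average
  expect_equal(merged$expr[["cb+cbc|a2"]],
               (atlas$expr[["cb|a2"]] + atlas$expr[["cbc|a2"]]) / 2)
  # disjoint age coverage: the union of ages is kept
  atlas3 <- toy_atlas(tibble::tibble(region = c("cb", "cbc"),
                                     age = c("a1", "a2"), mix = 0),
                      genes = 20, seed = 54)
  merged3 <- merge_regions(atlas3, c("cb", "cbc"))
  expect_setequal(merged3$meta$age[merged3$meta$region == "cb+cbc"],
                  c("a1", "a2"))
  expect_equal(merged3$expr[["cb+cbc|a1"]], atlas3$expr[["cb|a1"]])
})

test_that("a noisy copy of an atlas column is matched to it reliably", {
  cfg <- small_cfg(seed = 55)
  atlas <- gen_atlas(cfg)
  tmpl <- atlas$truth$template_profile
  set.seed(56)
  hits <- 0
  for (i in 1:40) {
    noisy <- tmpl + rnorm(length(tmpl), sd = sd(tmpl) / 5)   # SNR 5
    prof <- tibble::tibble(gene_id = names(tmpl), value = 2^noisy)
    calls <- suppressMessages(correlate_to_atlas(prof, atlas))
    best <- calls[which.max(calls$r), ]
    hits <- hits + (best$region == atlas$truth$template_region &&
                      best$age == atlas$truth$template_age)
  }
  expect_gte(hits / 40, 0.95)
})
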