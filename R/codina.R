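#' Classify links across co-expression networks as common, different or
#' specific
#'
#' Compares two or more significance-filtered wTO edge lists over a shared
#' node namespace. Each network's weights are first scaled by its own
#' maximum absolute weight (`w~ = w / max|w|`), so the distance filter is
#' scale-free across networks of different density. A link is:
#'
#' * **alpha** (common) -- present in all networks with the same sign;
#' * **beta** (different) -- present in at least two networks with differing
#'   signs;
#' * **gamma** (specific) -- present in a single network (with more than two
#'   networks, a same-sign link confined to a proper subset is likewise
#'   treated as specific to that subset).
#'
#' Each link is scored by the normalized distance of its scaled weight
#' vector from the origin, `||w~|| / sqrt(n_networks)`, and only links with
#' distance above `distance_cut` are flagged as kept.
#'
#' @param networks Named list (>= 2) of edge tibbles with columns `node_i`,
#'   `node_j` and a weight column `omega`; links flagged `kept = FALSE`
#'   (e.g. by [wto_bootstrap()]) are dropped on input.
#' @param distance_cut Keep links with normalized distance above this value
#'   (default 0.5).
#' @return A `codina_links` tibble: `node_i`, `node_j`, one `w_<network>`
#'   column per input network (0 when absent), `category`
#'   ("alpha"/"beta"/"gamma"), `specific_to` (owning network for gamma
#'   links, NA otherwise), `distance`, `kept`.
#' @export
classify_links <- function(networks, distance_cut = 0.5) {
  if (length(networks) < 2) abort("need at least 2 networks to compare")
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    names(networks) <- paste0("net", seq_along(networks))
  }
  nets <- imap(networks, function(net, nm) {
    if ("kept" %in% names(net)) net <- filter(net, .data$kept)
    net <- net |>
      transmute(node_i = pmin(.data$node_i, .data$node_j),
                node_j = pmax(.data$node_i, .data$node_j),
                w = .data$omega)
    scale <- max(abs(net$w), 0)
    if (scale > 0) net$w <- net$w / scale
    rename(net, !!paste0("w_", nm) := "w")
  })
  merged <- Reduce(function(a, b) full_join(a, b, by = c("node_i", "node_j")),
                   nets)
  wcols <- paste0("w_", names(networks))
  wmat <- as.matrix(merged[, wcols])
  wmat[is.na(wmat)] <- 0
  merged[wcols] <- as_tibble(wmat)

  present <- wmat != 0
  n_present <- rowSums(present)
  signs <- sign(wmat)
  has_pos <- rowSums(signs > 0) > 0
  has_neg <- rowSums(signs < 0) > 0
  category <- case_when(
    n_present >= 2 & has_pos & has_neg ~ "beta",
    n_present == ncol(wmat) ~ "alpha",
    TRUE ~ "gamma"
  )
  owner <- ifelse(category == "gamma",
                  apply(present, 1, function(p) {
                    paste(names(networks)[p], collapse = "+")
                  }),
                  NA_character_)
  merged |>
    mutate(category = category,
           specific_to = owner,
           distance = sqrt(rowSums(wmat^2)) / sqrt(ncol(wmat)),
           kept = .data$distance > distance_cut) |>
    arrange(.data$node_i, .data$node_j) |>
    structure(class = c("codina_links", class(tibble())),
              networks = names(networks), distance_cut = distance_cut)
}

#' Categorize nodes by the link categories around them
#'
#' For each node, counts its kept links per category and tests the counts
#' against a uniform 1/3 split with a chi-squared goodness-of-fit test
#' (df = 2). Nodes with p below `alpha` are assigned their modal category;
#' others -- and modal ties -- are "undefined". Counts below 5 expected per
#' cell are still tested but flagged.
#'
#' @param links A `codina_links` tibble; only rows with `kept = TRUE` are
#'   scored (all rows if there is no `kept` column).
#' @param alpha Significance level for the chi-squared test (default 0.05).
#' @return Tibble `node`, `n_alpha`, `n_beta`, `n_gamma`, `chi2`, `pvalue`,
#'   `assigned`, `low_expected`.
#' @export
classify_nodes <- function(links, alpha = 0.05) {
  if ("kept" %in% names(links)) links <- filter(links, .data$kept)
  long <- bind_rows(select(links, node = "node_i", "category"),
                    select(links, node = "node_j", "category"))
  counts <- long |>
    count(.data$node, .data$category) |>
    pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  for (cat in c("alpha", "beta", "gamma")) {
    if (!cat %in% names(counts)) counts[[cat]] <- 0L
  }
  counts |>
    rowwise() |>
    mutate(chi2 = {
      obs <- c(.data$alpha, .data$beta, .data$gamma)
      expd <- sum(obs) / 3
      sum((obs - expd)^2 / expd)
    },
    pvalue = pchisq(.data$chi2, df = 2, lower.tail = FALSE),
    assigned = {
      obs <- c(alpha = .data$alpha, beta = .data$beta, gamma = .data$gamma)
      modal <- names(obs)[obs == max(obs)]
      if (.data$pvalue < !!alpha && length(modal) == 1) modal else "undefined"
    },
    low_expected = sum(.data$alpha, .data$beta, .data$gamma) / 3 < 5) |>
    ungroup() |>
    select(node = "node", n_alpha = "alpha", n_beta = "beta",
           n_gamma = "gamma", "chi2", "pvalue", "assigned", "low_expected")
}

#' Genes strongly correlated with each categorized node
#'
#' For each scored node (TF), returns the genes whose absolute Pearson
#' correlation with that node exceeds `r_min` in the supplied expression
#' slice -- the node's putative regulatory program in that condition.
#'
#' @param x Gene x sample tibble (`gene_id` + numeric sample columns) for
#'   the relevant condition and day.
#' @param node_calls Tibble with a `node` column ([classify_nodes()]
#'   output), or a character vector of node ids.
#' @param r_min Absolute-correlation threshold (default 0.9, exclusive).
#' @return Tibble `node`, `gene_id`, `r` for all pairs with |r| > `r_min`.
#' @export
correlated_gene_sets <- function(x, node_calls, r_min = 0.9) {
  nodes <- if (is.character(node_calls)) node_calls else node_calls$node
  nodes <- intersect(nodes, x$gene_id)
  m <- as_sample_matrix(x)
  A <- suppressWarnings(cor(m[, nodes, drop = FALSE], m))
  A[is.na(A)] <- 0
  hits <- which(abs(A) > r_min, arr.ind = TRUE)
  out <- tibble(node = nodes[hits[, 1]], gene_id = colnames(m)[hits[, 2]],
                r = A[hits]) |>
    filter(.data$node != .data$gene_id) |>
    arrange(.data$node, desc(abs(.data$r)))
  out
}
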