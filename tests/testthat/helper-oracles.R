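# Independent reference implementations used as oracles. These deliberately
# share no code with the package: explicit index scans and nested loops.

# ---- brute-force recursive summit splitter --------------------------------

oracle_pieces <- function(depth, thr) {
  # index ranges of maximal stretches with depth >= thr, by linear scan
  out <- list()
  i <- 1
  n <- length(depth)
  while (i <= n) {
    if (depth[i] >= thr) {
      j <- i
      while (j < n && depth[j + 1] >= thr) j <- j + 1
      out[[length(out) + 1]] <- i:j
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

oracle_recurse <- function(pos, depth, tau, fs) {
  s <- max(depth)
  thr <- fs * s
  if (all(depth >= thr)) return(list(list(pos = pos, depth = depth)))
  out <- list()
  for (piece in oracle_pieces(depth, thr)) {
    if (max(depth[piece]) >= max(thr, tau)) {
      out <- c(out, oracle_recurse(pos[piece], depth[piece], tau, fs))
    }
  }
  out
}

oracle_split_track <- function(track, tau = 10, fp = 0.20, fs = 0.05) {
  rows <- list()
  for (rid in unique(track$region_id)) {
    df <- track[track$region_id == rid, ]
    df <- df[order(df$pos), ]
    pos <- df$pos
    depth <- df$depth
    # candidate regions: maximal runs of depth > 0 at consecutive positions
    i <- 1
    n <- length(pos)
    while (i <= n) {
      if (depth[i] > 0) {
        j <- i
        while (j < n && depth[j + 1] > 0 && pos[j + 1] == pos[j] + 1L) {
          j <- j + 1
        }
        cand <- i:j
        s <- max(depth[cand])
        if (s >= tau) {
          for (piece in oracle_pieces(depth[cand], fp * s)) {
            sub <- cand[piece]
            if (max(depth[sub]) >= max(fp * s, tau)) {
              for (site in oracle_recurse(pos[sub], depth[sub], tau, fs)) {
                w <- which.max(site$depth)
                rows[[length(rows) + 1]] <- data.frame(
                  region_id = rid,
                  start = site$pos[1],
                  end = site$pos[length(site$pos)] + 1L,
                  summit_pos = site$pos[w],
                  summit_height = site$depth[w],
                  depth_sum = sum(site$depth))
              }
            }
          }
        }
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(region_id = character(), start = integer(),
                      end = integer(), summit_pos = integer(),
                      summit_height = numeric(), depth_sum = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$region_id, out$start), , drop = FALSE]
}

random_track <- function(len = sample(20:500, 1), region = "r") {
  # spiky random tracks: background noise plus a few planted bumps
  depth <- rpois(len, sample(c(0.2, 1, 3), 1))
  for (k in seq_len(sample(0:4, 1))) {
    c0 <- sample(len, 1)
    h <- sample(1:100, 1)
    w <- sample(2:30, 1)
    idx <- max(1, c0 - w):min(len, c0 + w)
    depth[idx] <- depth[idx] + pmax(0, round(h * (1 - abs(idx - c0) / w)))
  }
  data.frame(region_id = region, pos = seq_len(len) - 1L, depth = depth)
}

# ---- triple-loop signed wTO ------------------------------------------------

oracle_wto <- function(m, nodes) {
  genes <- colnames(m)
  pcor <- function(a, b) {
    r <- suppressWarnings(stats::cor(m[, a], m[, b]))
    if (is.na(r)) 0 else r
  }
  k <- sapply(nodes, function(i) {
    tot <- 0
    for (u in genes) if (u != i) tot <- tot + abs(pcor(i, u))
    tot
  })
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in nodes) {
    for (j in nodes) {
      if (i == j) next
      aij <- pcor(i, j)
      num <- aij
      for (u in genes) {
        if (u != i && u != j) num <- num + pcor(i, u) * pcor(u, j)
      }
      W[i, j] <- num / (min(k[[i]], k[[j]]) + 1 - abs(aij))
    }
  }
  W
}

# ---- step-up false-discovery-rate adjustment ------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, sorted[j] * n / j)
    adj[o[i]] <- min(1, best)
  }
  adj
}

# ---- small helpers ---------------------------------------------------------

small_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(list(seed = seed, n_regions = 10, n_genes = 120,
                                 n_tfs = 24), list(...))
  do.call(synth_config, args)
}
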