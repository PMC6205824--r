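#' TFs differentially expressed on every day, with their trajectory matrix
#'
#' Intersects per-day DE results over days 1..k and restricts to a TF list:
#' only TFs significant (`padj < alpha`) on *every* day qualify. Their
#' normalized fold-change (nFC) trajectory is the per-day log2 fold change,
#' standardized across the qualifying TFs within each day (z-score), so days
#' with large global shifts do not dominate the trajectory shape.
#'
#' @param de_per_day Named list of DE tibbles (`gene_id`, `log2fc`, `padj`),
#'   one per day, in day order (names used as day labels).
#' @param tf_list Character vector of TF gene ids.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Tibble `gene_id` + one standardized `nfc_<day>` column per day;
#'   zero rows when no TF is persistently significant.
#' @export
persistent_de_tfs <- function(de_per_day, tf_list, alpha = 0.05) {
  stopifnot(length(de_per_day) >= 1)
  if (is.null(names(de_per_day))) {
    names(de_per_day) <- paste0("d", seq_along(de_per_day))
  }
  sig_sets <- map(de_per_day, function(de) {
    de$gene_id[!is.na(de$padj) & de$padj < alpha]
  })
  persistent <- sort(intersect(Reduce(intersect, sig_sets), tf_list))
  if (length(persistent) == 0) {
    return(tibble(gene_id = character()))
  }
  nfc <- imap(de_per_day, function(de, day) {
    lfc <- de$log2fc[match(persistent, de$gene_id)]
    z <- if (length(lfc) > 1 && sd(lfc) > 0) (lfc - mean(lfc)) / sd(lfc) else lfc * 0
    tibble(!!paste0("nfc_", day) := z)
  })
  bind_cols(c(list(tibble(gene_id = persistent)), unname(nfc)))
}

# grid layouts in growth order: 1x2, 1x3, 2x2, 2x3, ... Strongly elongated
# strips quantize poorly, so unit counts whose only factorization is a long
# strip are skipped (keeps distortion non-increasing along the growth path).
som_grids <- function(max_units) {
  grids <- map(2:max_units, function(k) {
    rows <- max(which(k %% seq_len(floor(sqrt(k))) == 0))
    c(rows = rows, cols = k %/% rows)
  })
  keep(grids, function(g) g[["cols"]] <= 3 * g[["rows"]] + 1)
}

# best-of-3 restarts guard against poor codebook initializations
som_train <- function(x, rows, cols, seed, epochs_factor = 100,
                      alpha_range = c(0.5, 0.01), n_restarts = 3) {
  fits <- map(seq_len(n_restarts), function(r) {
    som_train_once(x, rows, cols, seed = seed * 13L + r,
                   epochs_factor = epochs_factor, alpha_range = alpha_range)
  })
  fits[[which.min(map_dbl(fits, "avg_distortion"))]]
}

# online SOM with Gaussian neighborhood and linear decay; deterministic
som_train_once <- function(x, rows, cols, seed, epochs_factor = 100,
                           alpha_range = c(0.5, 0.01)) {
  n <- nrow(x)
  units <- rows * cols
  grid_xy <- as.matrix(expand.grid(gx = seq_len(cols), gy = seq_len(rows)))
  set.seed(as.integer(seed))
  codebook <- x[sample.int(n, units, replace = units > n), , drop = FALSE]
  total <- epochs_factor * n
  radius0 <- max(rows, cols) / 2
  order_idx <- unlist(map(seq_len(epochs_factor), function(e) sample.int(n)))
  for (t in seq_len(total)) {
    frac <- (t - 1) / max(total - 1, 1)
    lr <- alpha_range[1] + frac * (alpha_range[2] - alpha_range[1])
    radius <- max(radius0 * (1 - frac), 0.5)
    v <- x[order_idx[t], ]
    d2 <- rowSums((codebook - rep(v, each = units))^2)
    bmu <- which.min(d2)
    gd2 <- (grid_xy[, 1] - grid_xy[bmu, 1])^2 + (grid_xy[, 2] - grid_xy[bmu, 2])^2
    h <- exp(-gd2 / (2 * radius^2))
    codebook <- codebook + lr * h * (rep(v, each = units) - codebook) *
      (h > 0.01)
  }
  # quantization fine-tuning: radius-zero (Lloyd) iterations to convergence
  for (it in 1:100) {
    bmu_of <- apply(x, 1, function(v) {
      which.min(rowSums((codebook - rep(v, each = units))^2))
    })
    new_cb <- codebook
    for (u in unique(bmu_of)) {
      new_cb[u, ] <- colMeans(x[bmu_of == u, , drop = FALSE])
    }
    if (max(abs(new_cb - codebook)) < 1e-10) break
    codebook <- new_cb
  }
  bmu_of <- apply(x, 1, function(v) {
    which.min(rowSums((codebook - rep(v, each = units))^2))
  })
  qerr <- vapply(seq_len(n), function(i) {
    sum((x[i, ] - codebook[bmu_of[i], ])^2)
  }, numeric(1))
  list(codebook = codebook, membership = bmu_of, qerror = qerr,
       avg_distortion = mean(qerr), rows = rows, cols = cols)
}

#' Fit a self-organizing map to trajectories, growing the grid
#'
#' Fits a standard online SOM (rectangular grid, Gaussian neighborhood,
#' linearly decaying learning rate and radius, fixed epoch count) to the
#' nFC trajectory matrix, followed by a radius-zero quantization
#' fine-tuning pass run to convergence. The grid grows through layouts of increasing unit
#' count (1x2, 1x3, 2x2, ...) until the average distortion -- the mean
#' squared distance of trajectories to their best-matching unit -- falls
#' below `distortion_cut`. Per-unit quantization errors are reported but not
#' individually thresholded. Deterministic under a fixed seed.
#'
#' @param nfc Tibble from [persistent_de_tfs()] (`gene_id` + numeric
#'   trajectory columns), or any tibble in that layout.
#' @param seed Integer seed for codebook initialization and sample order.
#' @param distortion_cut Stop growing when average distortion drops below
#'   this value (default 10; the scale is that of the standardized nFC).
#' @param epochs_factor Training updates per trajectory (default 100).
#' @return A `som_fit` object: `grid` (rows, cols), `codebook` (unit x day
#'   matrix), `membership` tibble (`gene_id`, `unit`, `qerror`),
#'   `qerror_per_unit`, `avg_distortion`, `growth` (distortion per tried
#'   grid).
#' @export
fit_som <- function(nfc, seed = 1, distortion_cut = 10, epochs_factor = 100) {
  x <- as.matrix(nfc[, -1, drop = FALSE])
  if (nrow(x) < 2) abort("need >= 2 trajectories to cluster")
  grids <- som_grids(max_units = nrow(x))
  growth <- list()
  fit <- NULL
  for (g in grids) {
    fit <- som_train(x, g[["rows"]], g[["cols"]], seed = seed,
                     epochs_factor = epochs_factor)
    growth[[length(growth) + 1]] <- tibble(
      rows = g[["rows"]], cols = g[["cols"]],
      units = prod(g), avg_distortion = fit$avg_distortion)
    if (fit$avg_distortion < distortion_cut) break
  }
  if (fit$avg_distortion >= distortion_cut) {
    warn(sprintf("distortion %.3f did not reach the cut %.3f at %d units",
                 fit$avg_distortion, distortion_cut, fit$rows * fit$cols))
  }
  membership <- tibble(gene_id = nfc$gene_id, unit = fit$membership,
                       qerror = fit$qerror)
  per_unit <- membership |>
    group_by(.data$unit) |>
    summarise(qerror = mean(.data$qerror), n = dplyr::n())
  structure(list(grid = c(rows = fit$rows, cols = fit$cols),
                 codebook = fit$codebook,
                 membership = membership,
                 qerror_per_unit = per_unit,
                 avg_distortion = fit$avg_distortion,
                 growth = list_rbind(growth),
                 distortion_cut = distortion_cut,
                 days = colnames(x)),
            class = "som_fit")
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("<som_fit> %dx%d grid, %d trajectories, avg distortion %.3f\n",
              x$grid["rows"], x$grid["cols"], nrow(x$membership),
              x$avg_distortion))
  invisible(x)
}

#' Smoothed per-cluster trajectory summaries
#'
#' Summarizes each occupied SOM unit by a local-regression (loess) smooth of
#' its members' trajectories across days, evaluated at the observed days.
#' Quadratic loess reproduces exactly any polynomial trajectory of degree
#' up to two, so linear cluster trends pass through unchanged.
#'
#' @param fit A [fit_som()] object.
#' @param nfc The trajectory tibble the SOM was fitted to.
#' @param span Loess span (default 1: every day in the local window).
#' @return Tibble `unit`, `day` (integer index), `day_label`, `mean_nfc`,
#'   `smooth_nfc`.
#' @export
cluster_summaries <- function(fit, nfc, span = 1) {
  days <- setdiff(names(nfc), "gene_id")
  long <- nfc |>
    left_join(fit$membership[, c("gene_id", "unit")], by = "gene_id") |>
    pivot_longer(all_of(days), names_to = "day_label", values_to = "nfc") |>
    mutate(day = match(.data$day_label, days))
  long |>
    group_by(.data$unit) |>
    group_map(function(df, key) {
      sm <- if (dplyr::n_distinct(df$day) >= 3) {
        lo <- loess(nfc ~ day, data = df, span = span, degree = 2,
                    family = "gaussian",
                    control = stats::loess.control(surface = "direct"))
        predict(lo, newdata = tibble(day = sort(unique(df$day))))
      } else {
        tapply(df$nfc, df$day, mean)
      }
      df |>
        group_by(.data$day, .data$day_label) |>
        summarise(mean_nfc = mean(.data$nfc), .groups = "drop") |>
        arrange(.data$day) |>
        mutate(unit = key$unit, smooth_nfc = as.numeric(sm)) |>
        select("unit", "day", "day_label", "mean_nfc", "smooth_nfc")
    }) |>
    list_rbind() |>
    arrange(.data$unit, .data$day)
}
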