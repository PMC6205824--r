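#' Plot a pileup track with called binding sites
#'
#' Coverage as an area, called sites shaded, summits marked.
#'
#' @param pileup Pileup tibble (one track).
#' @param sites Site tibble from [split_sites()].
#' @param regions Optional subset of region ids to show.
#' @return A ggplot object, faceted by region.
#' @export
plot_sites <- function(pileup, sites, regions = NULL) {
  if (!is.null(regions)) {
    pileup <- filter(pileup, .data$region_id %in% regions)
    sites <- filter(sites, .data$region_id %in% regions)
  }
  ggplot2::ggplot(pileup, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_rect(
      data = sites, inherit.aes = FALSE, alpha = 0.25, fill = "firebrick",
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = .data$summit_height)) +
    ggplot2::geom_point(
      data = sites, inherit.aes = FALSE, colour = "firebrick",
      ggplot2::aes(x = .data$summit_pos, y = .data$summit_height)) +
    ggplot2::facet_wrap(~region_id, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = "read depth")
}

#' @describeIn fit_som Member trajectories and codebook per SOM unit.
#' @param object A `som_fit`.
#' @param nfc The trajectory tibble the SOM was fitted to.
#' @param ... Unused.
#' @export
autoplot.som_fit <- function(object, nfc, ...) {
  days <- setdiff(names(nfc), "gene_id")
  long <- nfc |>
    left_join(object$membership[, c("gene_id", "unit")], by = "gene_id") |>
    pivot_longer(all_of(days), names_to = "day", values_to = "nfc") |>
    mutate(day = match(.data$day, days))
  code <- as_tibble(object$codebook) |>
    mutate(unit = dplyr::row_number()) |>
    pivot_longer(-"unit", names_to = "day", values_to = "nfc") |>
    mutate(day = match(.data$day, days)) |>
    filter(.data$unit %in% long$unit)
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$nfc,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = code, ggplot2::aes(group = NULL),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(~unit) +
    ggplot2::labs(x = "day", y = "normalized fold change")
}

#' @describeIn classify_links Scatter of scaled weights colored by category
#'   (first two networks).
#' @param object A `codina_links` tibble.
#' @param ... Unused.
#' @export
autoplot.codina_links <- function(object, ...) {
  nets <- attr(object, "networks")
  wx <- paste0("w_", nets[1])
  wy <- paste0("w_", nets[2])
  ggplot2::ggplot(object,
                  ggplot2::aes(.data[[wx]], .data[[wy]],
                               colour = .data$category,
                               alpha = .data$kept)) +
    ggplot2::geom_point() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.2)) +
    ggplot2::labs(x = wx, y = wy)
}

#' Heatmap of atlas correlation calls
#'
#' @param calls Output of [correlate_to_atlas()] /
#'   [call_region_age()].
#' @return A ggplot object (tiles r by region x age, significant calls
#'   outlined).
#' @export
plot_atlas_calls <- function(calls) {
  p <- ggplot2::ggplot(calls,
                       ggplot2::aes(x = stats::reorder(.data$age,
                                                       .data$age_order),
                                    y = .data$region, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "age", y = "region")
  if ("significant" %in% names(calls)) {
    p <- p + ggplot2::geom_tile(data = filter(calls, .data$significant),
                                fill = NA, colour = "black", linewidth = 0.8)
  }
  p
}
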