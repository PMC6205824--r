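#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-element table of a
#' result (links, memberships, long expression), `glance()` a one-row
#' summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name ripnet-tidiers
NULL

#' @rdname ripnet-tidiers
#' @export
tidy.wto_network <- function(x, ...) {
  as_tibble(unclass(x)[names(x) != ""])
}

#' @rdname ripnet-tidiers
#' @export
glance.wto_network <- function(x, ...) {
  tibble(n_nodes = length(attr(x, "nodes")),
         n_links = nrow(x),
         n_kept = if ("kept" %in% names(x)) sum(x$kept) else nrow(x),
         n_samples = attr(x, "n_samples"),
         n_bootstrap = attr(x, "n_bootstrap") %||% NA_integer_)
}

#' @rdname ripnet-tidiers
#' @export
tidy.codina_links <- function(x, ...) as_tibble(unclass(x)[names(x) != ""])

#' @rdname ripnet-tidiers
#' @export
glance.codina_links <- function(x, ...) {
  kept <- x[x$kept, ]
  tibble(n_links = nrow(x), n_kept = nrow(kept),
         n_alpha = sum(kept$category == "alpha"),
         n_beta = sum(kept$category == "beta"),
         n_gamma = sum(kept$category == "gamma"))
}

#' @rdname ripnet-tidiers
#' @export
tidy.som_fit <- function(x, ...) x$membership

#' @rdname ripnet-tidiers
#' @export
glance.som_fit <- function(x, ...) {
  tibble(rows = x$grid[["rows"]], cols = x$grid[["cols"]],
         units = prod(x$grid), n_occupied = nrow(x$qerror_per_unit),
         avg_distortion = x$avg_distortion)
}

#' @rdname ripnet-tidiers
#' @export
tidy.expr_set <- function(x, ...) {
  assay <- x$counts %||% x$rpkm
  nm <- if (is.null(x$counts)) "rpkm" else "counts"
  assay |>
    pivot_longer(-"gene_id", names_to = "sample", values_to = nm) |>
    left_join(x$samples, by = "sample")
}

#' @rdname ripnet-tidiers
#' @export
tidy.mirna_set <- function(x, ...) {
  tbl <- x$normalized %||% x$counts
  tbl |>
    pivot_longer(-"mirna_id", names_to = "sample", values_to = "value") |>
    left_join(x$samples, by = "sample") |>
    mutate(housekeeping = .data$mirna_id %in% x$housekeeping)
}
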