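#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a domains result
#'
#' One row per resolved feature, with the leaf display order attached.
#'
#' @param x a `domains_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.domains_result <- function(x, ...) {
  leaves <- order_leaves(x$tree)
  ids <- parse_leaf_id(sub("^[0-9]+\\. ", "", leaves))
  x$architectures |>
    dplyr::mutate(leaf_rank = match(.data$protein_id, ids)) |>
    dplyr::arrange(.data$leaf_rank, .data$start)
}

#' @rdname tidy.domains_result
#' @export
glance.domains_result <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$tree$tip.label),
    n_proteins_with_features = length(unique(x$architectures$protein_id)),
    n_features = nrow(x$architectures),
    mode = x$metadata$mode,
    tree_backend = x$metadata$tree_backend
  )
}

#' Tidy a neighborhoods result
#'
#' One row per gene per neighborhood, with cluster and operon assignments.
#'
#' @param x a `neighborhoods_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.neighborhoods_result <- function(x, ...) {
  dplyr::left_join(
    x$neighborhoods,
    dplyr::select(x$genes, "gene_id", "cluster_id", "operon_id",
                  "domain_accessions"),
    by = "gene_id")
}

#' @rdname tidy.neighborhoods_result
#' @export
glance.neighborhoods_result <- function(x, ...) {
  tibble::tibble(
    n_queries = x$metadata$n_queries,
    n_genes = nrow(x$genes),
    n_clusters = length(unique(stats::na.omit(x$genes$cluster_id))),
    n_operons = length(unique(x$operons$operon_id)),
    window = x$metadata$parameters$window,
    nonshared_max = x$metadata$parameters$nonshared_max,
    operon_gap_max = x$metadata$parameters$operon_gap_max
  )
}

#' Plot a neighborhoods result
#'
#' ggplot2 view of the neighborhood tracks: one row per leaf in tree order,
#' gene boxes colored by cluster, query genes outlined.
#'
#' @param object a `neighborhoods_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.neighborhoods_result <- function(object, ...) {
  rlang::check_installed("ggplot2")
  df <- tidy.neighborhoods_result(object)
  leaves <- order_leaves(object$tree)
  df$leaf <- factor(df$leaf_name, levels = rev(leaves))
  df <- df |>
    dplyr::group_by(.data$leaf_name) |>
    dplyr::mutate(x0 = (.data$start - min(.data$start)) / 1e3,
                  x1 = (.data$end - min(.data$start)) / 1e3) |>
    dplyr::ungroup()
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x0, xmax = .data$x1,
      ymin = as.integer(.data$leaf) - 0.35,
      ymax = as.integer(.data$leaf) + 0.35,
      fill = factor(.data$cluster_id),
      linewidth = .data$is_query), color = "grey20") +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 1.2),
                                    guide = "none") +
    ggplot2::scale_y_continuous(breaks = seq_along(rev(leaves)),
                                labels = rev(leaves)) +
    ggplot2::labs(x = "kb from neighborhood start", y = NULL,
                  fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot a domains result
#'
#' Feature boxes along a protein ruler, one row per leaf in tree order.
#'
#' @param object a `domains_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.domains_result <- function(object, ...) {
  rlang::check_installed("ggplot2")
  df <- tidy.domains_result(object)
  leaves <- order_leaves(object$tree)
  df$leaf <- factor(df$leaf_rank, levels = rev(seq_along(leaves)),
                    labels = rev(leaves))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(.data$leaf) - 0.3,
      ymax = as.integer(.data$leaf) + 0.3,
      fill = .data$accession)) +
    ggplot2::scale_y_continuous(breaks = seq_along(rev(leaves)),
                                labels = rev(leaves)) +
    ggplot2::labs(x = "residue", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}
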