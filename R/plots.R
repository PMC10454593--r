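# ggplot2 views of the main result objects.

#' Plot per-sample CCF distributions by cluster
#'
#' Scatter of clipped CCFs for a pair of samples (default: first two),
#' coloured by cluster assignment, with cluster centers overlaid.
#'
#' @param ccf_matrix A `ccf_matrix` tibble.
#' @param fit Optional `dp_cluster` result for colouring and centers.
#' @param samples Character vector of two sample ids (default: first two).
#' @return A ggplot object.
#' @export
plot_ccf <- function(ccf_matrix, fit = NULL, samples = NULL) {
  all_s <- unique(ccf_matrix$sample_id)
  if (is.null(samples)) samples <- head(all_s, 2)
  if (length(samples) == 1) samples <- rep(samples, 2)
  wide <- tidyr::pivot_wider(
    dplyr::filter(ccf_matrix, .data$sample_id %in% samples),
    id_cols = "variant_id", names_from = "sample_id",
    values_from = "ccf_clipped")
  if (!is.null(fit)) {
    wide <- dplyr::left_join(wide, fit$assignments, by = "variant_id")
  } else {
    wide$cluster <- "unassigned"
  }
  p <- ggplot2::ggplot(wide, ggplot2::aes(
    x = .data[[samples[1]]], y = .data[[samples[2]]],
    colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("CCF,", samples[1]),
                  y = paste("CCF,", samples[2]), colour = "cluster") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    cent <- tibble::tibble(x = fit$centers[, samples[1]],
                           y = fit$centers[, samples[2]],
                           cluster = rownames(fit$centers))
    p <- p + ggplot2::geom_point(data = cent,
                                 ggplot2::aes(x = .data$x, y = .data$y),
                                 shape = 4, size = 4, stroke = 1.5)
  }
  p
}

#' @describeIn dp_cluster Trace of occupied-cluster count and concentration
#'   across sweeps.
#' @param object A `dp_cluster` object.
#' @export
autoplot.dp_cluster <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("n_clusters", "alpha"),
                            names_to = "quantity")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$sweep, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$settings$burn_in,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "sweep", y = NULL)
}

#' @describeIn build_tree Simple layered rendering of the clone tree with
#'   per-node SNV counts and attached copy-number events.
#' @param object A `clone_tree` object.
#' @export
autoplot.clone_tree <- function(object, ...) {
  nodes <- object$nodes
  # layout: depth on y, siblings spread on x
  nodes <- dplyr::arrange(nodes, .data$depth, .data$cluster)
  nodes$x <- NA_real_
  nodes$x[nodes$cluster == object$root] <- 0
  for (d in sort(unique(nodes$depth[nodes$depth > 0]))) {
    lev <- which(nodes$depth == d)
    px <- nodes$x[match(nodes$parent[lev], nodes$cluster)]
    off <- stats::ave(px, nodes$parent[lev],
                      FUN = function(v) seq_along(v) - (length(v) + 1) / 2)
    nodes$x[lev] <- px + off
  }
  edges <- dplyr::filter(nodes, !is.na(.data$parent))
  edges$px <- nodes$x[match(edges$parent, nodes$cluster)]
  edges$pd <- nodes$depth[match(edges$parent, nodes$cluster)]
  lab <- nodes$cluster
  if (!is.null(object$events)) {
    ev <- dplyr::summarise(dplyr::group_by(object$events, .data$node),
                           txt = paste(paste0(.data$target, ":", .data$kind),
                                       collapse = "\n"))
    extra <- ev$txt[match(nodes$cluster, ev$node)]
    lab <- ifelse(is.na(extra), lab, paste0(lab, "\n", extra))
  }
  nodes$label <- paste0(lab, "\n(n=", nodes$size, ")")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
      ggplot2::aes(x = .data$px, y = -.data$pd, xend = .data$x,
                   yend = -.data$depth), colour = "grey50") +
    ggplot2::geom_label(data = nodes,
      ggplot2::aes(x = .data$x, y = -.data$depth, label = .data$label),
      size = 3) +
    ggplot2::theme_void()
}
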