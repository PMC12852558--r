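# ggplot2 views of the result objects: abundance heatmap, virus-host
# correlation tiles, and the pooled-profile dendrogram.

#' @describeIn heatmap_matrix Heatmap of the clustered log10 TPM matrix.
#' @param object A `heatmap_matrix`.
#' @param ... Unused.
#' @export
autoplot.heatmap_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$library_id, y = .data$feature_id,
                                 fill = .data$log10_tpm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] * "(TPM + 1)")) +
    ggplot2::labs(x = "library", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn spearman_matrix Tile plot of virus-host Spearman rho.
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$host_id, y = .data$virus_id,
                                 fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1),
                                  name = "Spearman\nrho") +
    ggplot2::labs(x = "candidate host", y = "virus") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn hier_cluster Dendrogram of the pooled profile clustering.
#' @param object A `profile_clustering`.
#' @param ... Unused.
#' @export
autoplot.profile_clustering <- function(object, ...) {
  seg <- hclust_segments(object$hclust)
  labs <- tibble::tibble(x = seq_along(object$leaf_order),
                         label = object$leaf_order)
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02,
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(name = "1 - Spearman rho",
                                expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

# hclust -> segment tibble (x positions follow the leaf order)
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)
  xpos <- numeric(nrow(hc$merge))
  hpos <- hc$height
  segs <- list()
  node_x <- function(id) {
    if (id < 0) leaf_x[as.character(-id)] else xpos[id]
  }
  node_h <- function(id) if (id < 0) 0 else hpos[id]
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- node_x(a); xb <- node_x(b)
    xpos[k] <- (xa + xb) / 2
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = c(xa, xb, xa), y = c(node_h(a), node_h(b), hpos[k]),
      xend = c(xa, xb, xb), yend = c(hpos[k], hpos[k], hpos[k]))
  }
  dplyr::bind_rows(segs)
}
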