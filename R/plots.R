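#' Plot a pairing-probability metaprofile
#'
#' @param metaprofile Tibble `rel_pos`, `mean`, `sem` (e.g. from
#'   [build_metaprofile()]), or a `peak_clusters` object (one panel per
#'   cluster).
#' @param control Optional control metaprofile drawn as a dashed line.
#' @param region Shaded clustering region (default `c(10, 75)`).
#' @return A ggplot.
#' @export
plot_metaprofile <- function(metaprofile, control = NULL,
                             region = c(10, 75)) {
  if (inherits(metaprofile, "peak_clusters")) {
    mp <- metaprofile$metaprofiles
    p <- ggplot2::ggplot(mp, ggplot2::aes(x = .data$rel_pos,
                                          y = .data$mean)) +
      ggplot2::facet_wrap(~cluster)
  } else {
    p <- ggplot2::ggplot(metaprofile,
                         ggplot2::aes(x = .data$rel_pos, y = .data$mean))
  }
  p <- p +
    ggplot2::annotate("rect", xmin = region[1], xmax = region[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line()
  if (!is.null(control) && nrow(control) > 0) {
    p <- p + ggplot2::geom_line(data = control, linetype = "dashed",
                                colour = "red3")
  }
  p + ggplot2::labs(x = "position relative to peak start (nt)",
                    y = "paired probability") +
    ggplot2::theme_minimal()
}

#' Arc plot of duplexes along one transcript
#' @param duplexes Duplex tibble.
#' @param transcript Transcript id.
#' @return A ggplot.
#' @export
plot_arcs <- function(duplexes, transcript) {
  arcs <- arc_table(duplexes, transcript)
  if (nrow(arcs) == 0) abort("no duplexes on that transcript")
  curve_df <- bind_rows(lapply(seq_len(nrow(arcs)), function(i) {
    t <- seq(0, pi, length.out = 50)
    mid <- (arcs$start[i] + arcs$end[i]) / 2
    r <- (arcs$end[i] - arcs$start[i]) / 2
    tibble(x = mid + r * cos(t), y = r * sin(t), id = i,
           count = arcs$count[i])
  }))
  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$x, y = .data$y,
                                         group = .data$id,
                                         linewidth = .data$count)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5)) +
    ggplot2::labs(x = paste0(transcript, " position (nt)"), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Contact-map plot of hybrid arm positions on one transcript
#' @param hybrids Hybrid or duplex tibble.
#' @param transcript Transcript id.
#' @param bin Bin width (nt).
#' @return A ggplot.
#' @export
plot_contact_map <- function(hybrids, transcript, bin = 10) {
  cm <- contact_matrix(hybrids, transcript, bin = bin)
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$bin_prox, y = .data$bin_dist,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "proximal arm (nt)", y = "distal arm (nt)",
                  fill = "hybrids") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.span_mixture <- function(object, data = NULL, bins = 40, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble(span = data),
      ggplot2::aes(x = .data$span, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey80", colour = "grey40")
  }
  rng <- range(object$mu + 3 * object$sigma, object$mu - 3 * object$sigma)
  grid <- seq(rng[1], rng[2], length.out = 400)
  dens <- bind_rows(lapply(seq_len(object$k), function(j) {
    tibble(span = grid, component = factor(j),
           density = object$lambda[j] * dnorm(grid, object$mu[j],
                                              object$sigma[j]))
  }))
  p + ggplot2::geom_line(data = dens,
                         ggplot2::aes(x = .data$span, y = .data$density,
                                      colour = .data$component)) +
    ggplot2::labs(x = "duplex span (nt)", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metabolism_clusters <- function(object, ...) {
  df <- as_tibble(object$scaled, rownames = "gene_id") %>%
    inner_join(object$assignments, by = "gene_id") %>%
    tidyr::pivot_longer(c("synthesis", "processing", "degradation"),
                        names_to = "rate", values_to = "z")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$z,
                                   fill = .data$cluster)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "scaled log10 rate") +
    ggplot2::theme_minimal()
}
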