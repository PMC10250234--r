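#' Arc diagram of a covariation model
#'
#' Consensus basepairs drawn as arcs over the alignment columns, coloured
#' by the number of distinct canonical pair types (the 6-colour
#' covariation map) with transparency by mismatch tint.
#'
#' @param object a `covariation_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot covariation_model
#' @export
autoplot.covariation_model <- function(object, ...) {
  stats <- object$stats
  if (nrow(stats) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "empty consensus") +
             ggplot2::theme_void())
  }
  arcs <- purrr::map_dfr(seq_len(nrow(stats)), function(r) {
    i <- stats$pair_i[r]; j <- stats$pair_j[r]
    t <- seq(0, pi, length.out = 30)
    tibble::tibble(arc = r, x = (i + j) / 2 + (j - i) / 2 * cos(t),
                   y = (j - i) / 2 * sin(t),
                   color = stats$color[r], tint = stats$tint[r])
  })
  alpha_map <- c(full = 1, medium = 0.7, light = 0.4, white = 0.15)
  pal <- setNames(COVARIATION_COLORS, COVARIATION_COLORS)
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$arc,
                                     colour = .data$color,
                                     alpha = .data$tint)) +
    ggplot2::geom_path(linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = pal, name = "pair types") +
    ggplot2::scale_alpha_manual(values = alpha_map, name = "mismatches") +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Dot plot of a basepair probability matrix
#'
#' @param object a `bppm`.
#' @param p_min smallest probability drawn.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bppm
#' @export
autoplot.bppm <- function(object, p_min = 1e-3, ...) {
  df <- tidy(object, p_min = p_min)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   size = .data$p)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_area(max_size = 2) +
    ggplot2::labs(x = "j", y = "i", size = "P(i,j)") +
    ggplot2::theme_minimal()
}

#' Histogram of hLT duplex lengths
#'
#' @param profiles a `flank_profiles` tibble.
#' @param threshold threshold line to draw (bp).
#' @return a ggplot object.
#' @export
plot_hlt_distribution <- function(profiles, threshold = 17) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$hlt_bp)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold + 0.5, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "hLT basepairs", y = "pairs") +
    ggplot2::theme_minimal()
}
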