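#' Plot a smoothed DS profile along the dendrogram leaf order
#'
#' Line of smoothed DS by leaf-order position; candidate intervals (when
#' supplied) are shaded.
#'
#' @param object a smoothed `ds_profile`
#' @param candidates optional interval tibble from [find_peaks()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ds_profile <- function(object, candidates = NULL, ...) {
  if (!"smoothed" %in% names(object)) {
    stop("profile is not smoothed; run smooth_scores()")
  }
  contrast <- attr(object, "contrast")
  p <- ggplot2::ggplot(
    as.data.frame(object),
    ggplot2::aes(x = position, y = smoothed)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(
      x = "position in dendrogram leaf order",
      y = sprintf("smoothed DS (window %d)", attr(object, "window")),
      title = sprintf("Discriminating-score profile (%s)", contrast$tissue)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as.data.frame(candidates),
      ggplot2::aes(
        xmin = start, xmax = end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.15, fill = "#2166ac"
    )
  }
  p
}

#' Plot per-column information content of a discovered motif
#'
#' Bar height is the column's information content in bits; each bar is
#' labelled with the consensus base (a text rendition of the sequence
#' logo's column heights).
#'
#' @param object a `motif_result`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.motif_result <- function(object, ...) {
  cons <- strsplit(object$consensus, "")[[1]]
  df <- data.frame(
    position = seq_along(object$ic), bits = object$ic, base = cons
  )
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = bits, fill = base)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = base), vjust = -0.4, size = 3.5) +
    ggplot2::scale_x_continuous(breaks = df$position) +
    ggplot2::labs(
      x = "motif position", y = "information content (bits)",
      title = sprintf("Motif %s", object$consensus)
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Heatmap of a PWM
#' @param object a `pwm`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pwm <- function(object, ...) {
  ggplot2::ggplot(
    tidy.pwm(object),
    ggplot2::aes(x = position, y = base, fill = freq)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "motif position", y = NULL, fill = "freq") +
    ggplot2::theme_minimal()
}
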