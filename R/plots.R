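#' Plot an elimination trace
#'
#' Leave-one-out cross-validation SSE against the number of remaining
#' context positions, with the global minimum highlighted -- the standard
#' way to read off the reduced-model optimum.
#'
#' @param object An `elim_trace` from [run_elimination()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elim_trace
#' @export
autoplot.elim_trace <- function(object, ...) {
  minima <- pick_minima(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_context_positions,
                                       y = .data$loo_sse)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = minima$global, color = "red", size = 3) +
    ggplot2::scale_x_reverse(breaks = 0:12) +
    ggplot2::labs(
      x = "context positions remaining (excluding stop)",
      y = "leave-one-out CV SSE",
      title = "Stepwise position elimination"
    ) +
    ggplot2::theme_minimal()
}

#' Plot model coefficients as a text logo
#'
#' Signed regression coefficients per position and base; positive weights
#' above the axis, negative below, character height proportional to the
#' coefficient magnitude. Stop-codon weights appear at the stop slot.
#'
#' @param object An `rtp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtp_model
#' @export
autoplot.rtp_model <- function(object, ...) {
  tw <- tidy(object)
  tw$slot <- ifelse(tw$position == "stop", 0L, as.integer(tw$position))
  ggplot2::ggplot(tw, ggplot2::aes(x = factor(.data$slot, levels = sort(unique(.data$slot))),
                                   y = .data$weight, label = .data$base,
                                   color = .data$weight > 0)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(size = abs(.data$weight)), show.legend = FALSE) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black", `FALSE` = "red")) +
    ggplot2::labs(x = "position (0 = stop codon)", y = "raw regression weight",
                  title = if (is.null(object$name)) "RTP model coefficients" else object$name) +
    ggplot2::theme_minimal()
}

#' Plot the product-score distribution of a transcriptome scan
#'
#' Product score (RTP+ x PTS1 posterior) against rank, with the half-max
#' rank marked; the shape shows how quickly candidate support decays across
#' the scanned set.
#'
#' @param object A `readthrough_scan` from [scan_transcriptome()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot readthrough_scan
#' @export
autoplot.readthrough_scan <- function(object, ...) {
  hm <- attr(object, "half_max_rank")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$product_score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "RTP+ × PTS1 product score",
                  title = "Readthrough-extension candidates") +
    ggplot2::theme_minimal()
  if (!is.na(hm)) {
    p <- p + ggplot2::geom_vline(xintercept = hm, linetype = "dashed",
                                 color = "darkgreen")
  }
  p
}
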