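# Lightweight plotting helpers (ggplot2 is a suggested dependency).

#' Plot a pretraining loss curve
#'
#' Per-step contrastive loss with the cyclic learning rate overlaid on a
#' secondary axis.
#'
#' @param object A `pretrain_result` from [pretrain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pretrain_result <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("autoplot.pretrain_result requires ggplot2")
  m <- object$metrics
  scale <- max(m$loss) / max(m$lr)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lr * scale),
                       colour = "steelblue", linetype = 2,
                       linewidth = 0.3) +
    ggplot2::scale_y_continuous(
      name = "contrastive loss",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "learning rate")) +
    ggplot2::labs(x = "optimizer step") +
    ggplot2::theme_minimal()
}

#' Plot embedding displacement distributions by modality
#'
#' Mirrors the before/after displacement comparison: one density per
#' modality of the per-protein Euclidean displacement in the original
#' embedding space.
#'
#' @param seq_disp,str_disp Numeric displacement vectors from
#'   [displacement_distribution()].
#' @return A ggplot object.
#' @export
plot_displacement <- function(seq_disp, str_disp) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_displacement requires ggplot2")
  df <- data.frame(
    displacement = c(seq_disp, str_disp),
    modality = rep(c("sequence", "structure"),
                   c(length(seq_disp), length(str_disp))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement,
                                   fill = .data$modality)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "embedding displacement (Euclidean)", y = "density") +
    ggplot2::theme_minimal()
}
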