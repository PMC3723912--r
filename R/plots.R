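# Convenience plots; ggplot2 is suggested, not required.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("install ggplot2 for plotting", call. = FALSE)
  }
}

#' Plot a phase-response curve
#' @param prc Tibble from [build_prc()].
#' @return A ggplot object.
#' @export
plot_prc <- function(prc) {
  need_ggplot2()
  ggplot2::ggplot(prc, ggplot2::aes(x = .data$pulse_start_zt,
                                    y = .data$delta_phi_min)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_phi_min - .data$sd_min,
                                        ymax = .data$delta_phi_min + .data$sd_min),
                           width = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::labs(x = "pulse start (h after transfer to LL)",
                  y = expression(Delta * phi ~ "(min; delays negative)")) +
    ggplot2::theme_classic()
}

#' Volcano plot of differential phospho-sites
#' @param diff Tibble from [differential_sites()].
#' @param fc_threshold,p_threshold Gate lines to draw.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, fc_threshold = 1.5, p_threshold = 0.05) {
  need_ggplot2()
  d <- dplyr::filter(diff, .data$testable, is.finite(.data$fold_change))
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold_change),
                                  y = -log10(.data$p_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_threshold), log2(fc_threshold)),
                        linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red3")) +
    ggplot2::labs(x = "log2 fold change (B/A, raw means)",
                  y = "-log10 p (arcsinh t-test)") +
    ggplot2::theme_classic()
}
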