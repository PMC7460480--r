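#' @export
autoplot.tgwas_scan <- function(object, fdr = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$chrom_f <- factor(df$chrom, levels = unique(df$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp / 1e6,
                                   y = -log10(pmax(.data$p.value, 1e-300)),
                                   colour = .data$chrom_f)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom_f, scales = "free_x", space = "free_x",
                        switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = "Single-marker scan") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   strip.text = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.mgwas_result <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = c("per_chromosome", "sda_independent",
                                          "minimal", "top"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp / 1e6, y = abs(.data$cnc))) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::facet_grid(stage ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "|standardized canonical coefficient|",
                  title = "Multivariate discriminant pipeline stages") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.05, "lines"),
                   strip.text.x = ggplot2::element_text(size = 6),
                   axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.mgwas_experiment <- function(object, ...) {
  df <- object$results[object$results$status == "ok", ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n),
                                   y = .data$n_qtls_detected,
                                   colour = .data$method)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.6),
                          width = 0.5) +
    ggplot2::labs(x = "animals in sub-dataset", y = "QTLs detected",
                  colour = "method",
                  title = "QTL detection across sample sizes") +
    ggplot2::theme_minimal()
}
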