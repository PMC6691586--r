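#' Plot R-squared convergence curves
#'
#' One line per sample; the plateau position indicates how many unbalanced
#' processes carry signal.
#'
#' @param curves tibble from [r_squared_curve()].
#' @param max_samples cap on the number of sample curves drawn (default 50).
#' @return a ggplot object.
#' @export
plot_r_squared_curves <- function(curves, max_samples = 50) {
  ids <- unique(curves$sample_id)
  if (length(ids) > max_samples) {
    curves <- curves[curves$sample_id %in% ids[seq_len(max_samples)], ]
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$n_processes, y = .data$r_squared,
                                       group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "unbalanced processes included",
                  y = expression(R^2), title = "Reconstruction convergence per sample") +
    ggplot2::theme_minimal()
}

#' Scree plot of a surprisal decomposition
#'
#' @param object a `surprisal_decomp`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot surprisal_decomp
#' @export
autoplot.surprisal_decomp <- function(object, ...) {
  df <- tidy(object, matrix = "d")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$process, y = .data$singular_value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "component (0 = steady state)", y = "singular value") +
    ggplot2::theme_minimal()
}

#' Barcode frequency chart
#'
#' Bar chart of the most recurrent barcodes, optionally stacked by sample
#' label composition (e.g. cancer type per barcode).
#'
#' @param object a `barcode_catalog`.
#' @param top number of most abundant barcodes to draw (default 16).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot barcode_catalog
#' @export
autoplot.barcode_catalog <- function(object, top = 16, ...) {
  df <- utils::head(object, top)
  df$barcode <- factor(df$barcode, levels = df$barcode)
  has_labels <- any(!vapply(df$label_counts, is.null, logical(1)))
  if (has_labels) {
    long <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
      t <- df$label_counts[[i]]
      if (is.null(t)) return(tibble())
      tibble(barcode = df$barcode[i], label = names(t), count = as.integer(t))
    })
    ggplot2::ggplot(long, ggplot2::aes(x = .data$barcode, y = .data$count,
                                       fill = .data$label)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "barcode", y = "samples") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$barcode, y = .data$count)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "barcode", y = "samples") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  }
}
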