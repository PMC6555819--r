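# Figure layer: information-content logos, spacer-preference landscapes,
# ROC curves and concordance scatters. All return ggplot objects.

#' Information-content sequence logo
#'
#' Stacked per-position bars of base contributions to the Kullback-Leibler
#' information content (bits), labelled by base. A uniform PFM yields
#' zero-height columns.
#'
#' @param pfm A `pfm`.
#' @param background Named base frequencies (default uniform).
#' @return A ggplot object.
#' @export
plot_logo <- function(pfm, background = uniform_background()) {
  f <- as_base_matrix(unclass(pfm), "pfm")
  ic <- information_content(pfm, background)
  df <- data.frame(
    position = rep(seq_len(ncol(f)), each = 4L),
    base = rep(DNA_BASES, ncol(f)),
    height = as.vector(sweep(f, 2L, ic, "*")))
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::scale_fill_manual(values = base_cols) +
    ggplot2::labs(x = "position", y = "information (bits)", fill = NULL) +
    ggplot2::theme_classic()
}

#' Spacer-preference landscape plot
#'
#' Strip plot of per-seed maximum SNV z-scores by spacer length, coloured by
#' binding mode, with box summaries.
#'
#' @param landscape A [spacer_landscape()] table (or plain data.frame with
#'   `spacer_len`, `zmax`, `mode`).
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  df <- as.data.frame(landscape)
  df$mode <- factor(df$mode, MODE_LEVELS)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$spacer_len),
                                   y = .data$zmax)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          colour = "grey50") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$mode), width = 0.15,
                         size = 1.6) +
    ggplot2::labs(x = "spacer length (DRn)", y = "max SNV z-score",
                  colour = "mode") +
    ggplot2::theme_classic()
}

#' ROC curve plot
#'
#' @param curve data.frame with `fpr`, `tpr` (from [roc_auc()]).
#' @param auc Optional AUC annotation.
#' @return A ggplot object.
#' @export
plot_roc_curve <- function(curve, auc = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#255C99", linewidth = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_classic()
  if (!is.null(auc))
    p <- p + ggplot2::annotate("text", x = 0.7, y = 0.12,
                               label = sprintf("AUC = %.3f", as.numeric(auc)))
  p
}

#' Concordance scatter of two binding profiles
#'
#' z-score scatter over shared sequences (e.g. the two detection antibodies),
#' annotated with R squared.
#'
#' @param a,b `binding_profile` objects.
#' @param label_a,label_b Axis labels.
#' @return A ggplot object.
#' @export
plot_concordance <- function(a, b, label_a = "profile A z",
                             label_b = "profile B z") {
  m <- merge(a[, c("unique_seq", "mean_z", "category")],
             b[, c("unique_seq", "mean_z")],
             by = "unique_seq", suffixes = c("_a", "_b"))
  r2 <- concordance(a, b)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$mean_z_a, y = .data$mean_z_b,
                                  colour = .data$category == "background")) +
    ggplot2::geom_point(size = 1, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "grey60"),
                                 labels = c("probe", "background"),
                                 name = NULL) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("R^2 == %.3f", r2), parse = TRUE) +
    ggplot2::labs(x = label_a, y = label_b) +
    ggplot2::theme_classic()
}
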