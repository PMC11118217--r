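# ggplot2 displays for the main result types.

#' Plot group composition as paired Cys/Met bars
#'
#' @param tab A tibble with `block`, `cys_pct`, `met_pct` (e.g. the packaged
#'   survey table or [composition_row()] output joined with blocks).
#' @return A ggplot.
#' @export
plot_composition <- function(tab) {
  long <- tidyr::pivot_longer(tab, c("cys_pct", "met_pct"),
                              names_to = "residue", values_to = "pct")
  long$residue <- ifelse(long$residue == "cys_pct", "Cys", "Met")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$block, y = .data$pct,
                                     fill = .data$residue)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = "residue content (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Conservation logo profile
#'
#' Plots the per-column information content of a multiple alignment, the
#' quantity underlying a sequence logo, with flagged (gappy) columns marked.
#'
#' @param logo Output of [conservation_logo()].
#' @return A ggplot.
#' @export
plot_logo_information <- function(logo) {
  cols <- dplyr::distinct(logo, .data$column, .data$information, .data$flagged)
  ggplot2::ggplot(cols, ggplot2::aes(x = .data$column, y = .data$information,
                                     fill = .data$flagged)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "orange"),
                               labels = c("ok", "> 50% gaps"), name = NULL) +
    ggplot2::labs(x = "alignment column", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Exposure report bar chart with baseline thresholds
#' @param object An `exposure_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot exposure_report
#' @export
autoplot.exposure_report <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("ntd_cys_sasa", "ctd_cys_sasa"),
                              names_to = "domain", values_to = "sasa")
  long$domain <- ifelse(long$domain == "ntd_cys_sasa", "NTD", "CTD")
  thr_mean <- object$baseline_mean[1]
  thr_hi <- object$baseline_mean[1] + object$baseline_sd[1]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$sasa,
                                     fill = .data$domain)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = thr_mean, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = thr_hi, linetype = "dashed",
                        colour = "black") +
    ggplot2::scale_fill_manual(values = c(NTD = "orange", CTD = "steelblue")) +
    ggplot2::labs(x = NULL, y = expression("combined Cys SASA (" * ring(A)^2 * ")"),
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dendrogram plot
#' @param object A `crystal_dendrogram`.
#' @param k Unused (reserved).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot crystal_dendrogram
#' @export
autoplot.crystal_dendrogram <- function(object, k = NULL, ...) {
  n <- length(object$labels)
  # leaf x-positions in dendrogram order
  xleaf <- setNames(seq_len(n), object$order)
  pos <- matrix(NA_real_, n - 1L, 2L)  # x, height per merge node
  segs <- list()
  coord <- function(v) {
    if (v < 0L) c(xleaf[[as.character(-v)]], 0) else pos[v, ]
  }
  for (s in seq_len(n - 1L)) {
    a <- coord(object$merge[s, 1L]); b <- coord(object$merge[s, 2L])
    h <- object$height[s]
    pos[s, ] <- c((a[1] + b[1]) / 2, h)
    segs[[length(segs) + 1L]] <- tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h), yend = c(h, h, b[2]))
  }
  segs <- dplyr::bind_rows(segs)
  labs <- tibble(x = unname(xleaf[as.character(seq_len(n))]),
                 label = object$labels)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(object$height),
                                    label = .data$label),
                       angle = 90, hjust = 1, size = 2.8) +
    ggplot2::labs(x = NULL, y = "dissimilarity at merge") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
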