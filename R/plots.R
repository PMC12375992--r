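#' Histogram panels of the physicochemical profile
#'
#' GRAVY, isoelectric point, length and cysteine count distributions,
#' coloured by class label. Hydrophobin sets typically show GRAVY between
#' 0 and 1 and pI concentrated between 4 and 6.
#'
#' @param profile Tibble from [physchem_profile()].
#' @param bins Histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_physchem <- function(profile, bins = 30) {
  long <- tidyr::pivot_longer(
    profile[, c("class_label", "length", "cys_count", "gravy", "pi")],
    -"class_label", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$class_label)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "sequences", fill = "class") +
    ggplot2::theme_minimal()
}

#' Benchmark metrics against their quality cut-offs
#'
#' Per-pair Calpha RMSD, lDDT-Calpha and TM-score with dashed lines at the
#' standard cut-offs (2.5 A, 0.6, 0.6).
#'
#' @param results Tibble from [benchmark_models()].
#' @param rmsd_cutoff,lddt_cutoff,tm_cutoff Cut-offs to draw.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, rmsd_cutoff = 2.5, lddt_cutoff = 0.6,
                           tm_cutoff = 0.6) {
  long <- tidyr::pivot_longer(
    results[, c("id", "class_label", "rmsd", "lddt_ca", "tm_score")],
    c("rmsd", "lddt_ca", "tm_score"),
    names_to = "metric", values_to = "value"
  )
  cuts <- tibble(
    metric = c("rmsd", "lddt_ca", "tm_score"),
    cutoff = c(rmsd_cutoff, lddt_cutoff, tm_cutoff)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class_label, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7,
                         ggplot2::aes(colour = .data$class_label)) +
    ggplot2::geom_hline(data = cuts,
                        ggplot2::aes(yintercept = .data$cutoff),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = "class") +
    ggplot2::theme_minimal()
}

#' Motif architecture diagram
#'
#' Draws each sequence as a horizontal line with cysteine positions as
#' ticks and intercysteine loops as labelled segments; a quick visual check
#' of motif detection and polyhydrophobin segmentation.
#'
#' @param motifs Tibble from [scan_motifs()].
#' @param lengths Optional named vector of sequence lengths (for the line
#'   extents).
#' @return A ggplot object.
#' @export
plot_motifs <- function(motifs, lengths = NULL) {
  pos <- motifs |>
    dplyr::mutate(row = .data$id) |>
    tidyr::unnest_longer("positions", values_to = "position")
  p <- ggplot2::ggplot(pos, ggplot2::aes(y = .data$row)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$position), shape = 124, size = 4) +
    ggplot2::labs(x = "residue position", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(lengths)) {
    seg <- tibble(row = names(lengths), len = unname(lengths))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = 1, xend = .data$len, y = .data$row, yend = .data$row),
      linewidth = 0.3, colour = "grey60"
    )
  }
  p
}
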