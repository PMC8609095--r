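#' Homology track plot
#'
#' Draws the classic screen figure: one horizontal lane per subject
#' protein along the autoantigen axis, with each homologous segment as a
#' black bar over the gray cumulative (merged) span of that protein, and
#' optional epitope underlines and domain shading.
#'
#' @param segments Tibble with `subject_id` and autoantigen-axis spans in
#'   `a_start`/`a_end` (or `q_start`/`q_end`).
#' @param protein_length Length of the autoantigen.
#' @param epitopes Optional epitope interval tibble (`start`, `end`).
#' @param domains Optional domain tibble (`name`, `start`, `end`).
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_homology_track <- function(segments, protein_length, epitopes = NULL,
                                domains = NULL, title = NULL) {
  segs <- tibble::as_tibble(segments)
  if (!"a_start" %in% names(segs) && "q_start" %in% names(segs)) {
    segs$a_start <- segs$q_start
    segs$a_end <- segs$q_end
  }
  lanes <- segs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(spans = list(merge_spans(interval(.data$a_start,
                                                       .data$a_end))),
                     .groups = "drop") |>
    dplyr::mutate(lane = dplyr::row_number())
  merged <- lanes |>
    tidyr::unnest("spans") |>
    dplyr::select("subject_id", "lane", "start", "end")
  segs <- dplyr::left_join(segs,
                           lanes[, c("subject_id", "lane")],
                           by = "subject_id")
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = merged,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   ymin = .data$lane - 0.35, ymax = .data$lane + 0.35),
      fill = "grey70"
    ) +
    ggplot2::geom_rect(
      data = segs,
      ggplot2::aes(xmin = .data$a_start - 0.5, xmax = .data$a_end + 0.5,
                   ymin = .data$lane - 0.2, ymax = .data$lane + 0.2),
      fill = "black"
    ) +
    ggplot2::scale_y_continuous(breaks = lanes$lane,
                                labels = lanes$subject_id,
                                expand = ggplot2::expansion(add = 1)) +
    ggplot2::coord_cartesian(xlim = c(1, protein_length)) +
    ggplot2::labs(x = "residue position", y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
  if (!is.null(domains) && nrow(domains)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(domains),
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
      ymin = -Inf, ymax = Inf, fill = "steelblue", alpha = 0.08
    )
  }
  if (!is.null(epitopes) && nrow(epitopes)) {
    p <- p + ggplot2::geom_segment(
      data = tibble::as_tibble(epitopes),
      ggplot2::aes(x = .data$start, xend = .data$end),
      y = 0.3, yend = 0.3, linewidth = 2, colour = "firebrick"
    )
  }
  p
}

#' @rdname plot_homology_track
#' @param object A `mimicry_screen`.
#' @param ... Passed to [plot_homology_track()].
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.mimicry_screen <- function(object, ...) {
  segs <- tidy(object)
  segs$a_start <- segs$q_start
  segs$a_end <- segs$q_end
  plot_homology_track(segs, protein_length = max(segs$q_end), ...,
                      title = attr(object, "autoantigen_id"))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coverage profile plot
#'
#' Step plot of the per-residue homology-group count along a protein.
#'
#' @param profile A tibble from [coverage_profile()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "residue position", y = "homology groups") +
    ggplot2::theme_minimal()
}
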