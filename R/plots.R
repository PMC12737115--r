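# ggplot2 views of the main result types

#' Presence/absence heatmap of a PAV matrix
#'
#' @param object A `panfam_pav` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot panfam_pav
#' @export
autoplot.panfam_pav <- function(object, ...) {
  long <- pav_long(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome_id, y = .data$gene_id,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#2c7fb8"),
                               name = "present") +
    ggplot2::labs(x = "genome", y = "gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Occupancy category bar chart
#'
#' @param object A `panfam_occupancy` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot panfam_occupancy
#' @export
autoplot.panfam_occupancy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "#2c7fb8") +
    ggplot2::labs(x = "occupancy category", y = "pan-genes") +
    ggplot2::theme_minimal()
}

#' Density plot of pairwise omega values per gene
#'
#' @param estimates Pairwise estimate table from [kaks_all_pairs()].
#' @param max_omega Truncate the x-axis (default 3).
#' @return A ggplot.
#' @export
plot_omega_density <- function(estimates, max_omega = 3) {
  dat <- estimates |> filter(!is.na(.data$omega), .data$omega <= max_omega)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$omega)) +
    ggplot2::geom_density(fill = "#2c7fb8", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene_id), scales = "free_y") +
    ggplot2::labs(x = expression(K[a] / K[s]), y = "density") +
    ggplot2::theme_minimal()
}

#' SV regions along the reference promoter
#'
#' @param object A `panfam_sv_regions` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot panfam_sv_regions
#' @export
autoplot.panfam_sv_regions <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(xend = ifelse(.data$ref_end > .data$ref_start,
                         .data$ref_end, .data$ref_start + 5))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ref_start, xend = .data$xend,
                                       y = .data$region_id,
                                       yend = .data$region_id,
                                       color = .data$type),
                          linewidth = 4) +
    ggplot2::geom_text(ggplot2::aes(x = .data$xend, y = .data$region_id,
                                    label = paste0("n=", .data$share_count)),
                       hjust = -0.3, size = 3) +
    ggplot2::labs(x = "reference position (bp)", y = NULL, color = "type") +
    ggplot2::theme_minimal()
}

#' Association results: group means with significance labels
#'
#' @param object A `panfam_assoc` tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot panfam_assoc
#' @export
autoplot.panfam_assoc <- function(object, ...) {
  dat <- as_tibble(object) |>
    tidyr::pivot_longer(c("mean_present", "mean_absent"),
                        names_to = "group", values_to = "mean") |>
    mutate(group = sub("mean_", "", .data$group))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$region_id, y = .data$mean,
                                    fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = as_tibble(object),
      ggplot2::aes(x = .data$region_id, label = .data$label,
                   y = pmax(.data$mean_present, .data$mean_absent)),
      inherit.aes = FALSE, vjust = -0.5
    ) +
    ggplot2::labs(x = NULL, y = "mean value", fill = "SV") +
    ggplot2::theme_minimal()
}
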