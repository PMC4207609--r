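mechanism_palette <- c(
  readthrough_PTS1 = "#1b9e77",
  in_ORF_PTS1 = "#7570b3",
  readthrough_PTS1_noncore_context = "#d95f02",
  PTS2 = "#e7298a",
  none = "grey80"
)

#' Plot mechanism-class tallies of a screen
#'
#' Bar chart of genes per targeting-mechanism class; genes with the core
#' TGA-CT context are distinguished within each bar.
#'
#' @param object An `rt_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rt_screen
#' @export
autoplot.rt_screen <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(
      mechanism_class = factor(.data$mechanism_class, levels = MECHANISM_LEVELS),
      context = ifelse(.data$context_core_pass, "TGA CT", "other")
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$mechanism_class, fill = .data$mechanism_class,
    alpha = .data$context
  )) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = mechanism_palette, guide = "none") +
    ggplot2::scale_alpha_manual(
      values = c("TGA CT" = 1, "other" = 0.45), name = "stop context"
    ) +
    ggplot2::labs(
      x = NULL, y = "genes",
      title = "Peroxisomal targeting mechanisms across the screen"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an ortholog-group conservation matrix
#'
#' Species-by-group tile map coloured by targeting mechanism, in the style
#' of a presence/absence conservation figure.
#'
#' @param object An `rt_conservation` object from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rt_conservation
#' @export
autoplot.rt_conservation <- function(object, ...) {
  d <- attr(object, "per_species") |>
    mutate(mechanism_class = factor(.data$mechanism_class, levels = MECHANISM_LEVELS))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$species, y = .data$group_id, fill = .data$mechanism_class
  )) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = mechanism_palette, name = "mechanism") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Conservation of peroxisomal targeting mechanism"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
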