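# ggplot2 views of the main result types.

#' Plot integrated anti-correlation scores
#'
#' Lollipop of the ranked shortlist, most anti-correlated at the top;
#' filled points passed the CSM expression gate.
#'
#' @param shortlist ranked `screen_result` from [rank_candidates()]
#' @return a ggplot
#' @export
plot_screen <- function(shortlist) {
  df <- dplyr::arrange(as_tibble(shortlist), dplyr::desc(.data$score))
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$gene_id),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "integrated score (r_cpm + r_frac) / 2", y = NULL,
                  title = sprintf("Anti-correlation screen vs %s",
                                  attr(shortlist, "target") %||% "target")) +
    ggplot2::theme_minimal()
}

#' Plot averaged spatial profiles with SEM ribbons
#'
#' @param profiles output of [profile_channels()] (or
#'   [average_profiles()] with a `channel` column added)
#' @return a ggplot
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$position, y = .data$mean,
                               colour = .data$channel, fill = .data$channel)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "normalized axis position", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot per-genotype penetrance
#'
#' @param summary output of [penetrance_summary()]
#' @return a ggplot
#' @export
plot_penetrance <- function(summary) {
  df <- summary$penetrance
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$penetrance)) +
    ggplot2::geom_col(fill = "grey35", width = 0.65) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d",
                                                    .data$n_mistargeted,
                                                    .data$n_total)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05), expand = c(0, 0)) +
    ggplot2::labs(y = "penetrance (mistargeted / lobes examined)", x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.screen_result <- function(x, ...) as_tibble(x)

#' @export
glance.screen_result <- function(x, ...) {
  df <- as_tibble(x)
  tibble(target = attr(x, "target") %||% NA_character_,
         n_candidates = nrow(df),
         n_passed = sum(df$passed_filter, na.rm = TRUE),
         min_score = min(df$score, na.rm = TRUE))
}
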