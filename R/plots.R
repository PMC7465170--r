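#' @importFrom ggplot2 ggplot aes autoplot geom_col geom_step geom_tile
#'   labs scale_fill_brewer theme_minimal
NULL

#' Sequence-logo style plot of a position frequency matrix
#'
#' Stacked per-base information contribution (`f_b * IC`) per position —
#' the column heights of a standard sequence logo, rendered as stacked
#' bars.
#'
#' @param object a `pfm` from [build_pfm()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pfm
#' @export
autoplot.pfm <- function(object, ...) {
  ic <- information_content(object)
  n <- attr(object, "n_sequences")
  d <- tidy.pfm(object) %>%
    mutate(bits = .data$count / n * ic[.data$position])
  ggplot(d, aes(x = .data$position, y = .data$bits, fill = .data$base)) +
    geom_col(width = 0.85) +
    scale_fill_brewer(palette = "Set1") +
    labs(x = "position", y = "information (bits)", fill = NULL) +
    theme_minimal()
}

#' Bar plot of MIV read-support counts
#'
#' @param calls tibble from [validate_miv()].
#' @return a ggplot of the [support_histogram()].
#' @export
plot_support_histogram <- function(calls) {
  h <- support_histogram(calls)
  ggplot(h, aes(x = factor(.data$support), y = .data$n)) +
    geom_col() +
    labs(x = "supporting reads", y = "accepted MIV calls") +
    theme_minimal()
}

#' Windowed piRNA abundance track
#'
#' @param windows tibble from [window_counts()].
#' @return a ggplot, one panel per contig.
#' @export
plot_window_counts <- function(windows) {
  ggplot(windows, aes(x = .data$window_start, y = .data$count)) +
    geom_step() +
    ggplot2::facet_wrap(~contig, ncol = 1, scales = "free_x") +
    labs(x = "window start (nt)", y = "piRNA count") +
    theme_minimal()
}

#' Heat map of per-sample, per-family accepted call counts
#'
#' @param counts tibble from [family_count_matrix()] or [copy_table()].
#' @return a ggplot.
#' @export
plot_family_counts <- function(counts) {
  ggplot(counts, aes(x = .data$sample_id, y = .data$family,
                     fill = .data$n)) +
    geom_tile() +
    labs(x = NULL, y = NULL, fill = "calls") +
    theme_minimal()
}
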