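# ggplot2 views of the main result types.

#' Plot per-position information content
#'
#' Bar chart of IC in bits (the height profile of a sequence logo), with
#' the core threshold drawn as a dashed line.
#'
#' @param profile A profile from [build_profile()].
#' @param ic_threshold Core cutoff drawn on the plot.
#' @return A ggplot object.
#' @export
plot_information_content <- function(profile, ic_threshold = 1.0) {
  ic <- information_content(profile)
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$position, y = .data$ic)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = ic_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "position", y = "information content (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot a covariation scan as an MI heat map
#'
#' @param scan Result of [covariation_scan()].
#' @return A ggplot object.
#' @export
plot_covariation <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$i, y = .data$j,
                                     fill = .data$mi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "MI (bits)") +
    ggplot2::labs(x = "position i", y = "position j") +
    ggplot2::theme_minimal()
}

#' Plot per-round survival of a selection simulation
#'
#' @param selection Result of [run_selection()].
#' @return A ggplot object.
#' @export
plot_selection <- function(selection) {
  ggplot2::ggplot(selection$summary,
                  ggplot2::aes(x = .data$round, y = 100 * .data$survival)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "round", y = "surviving molecules (%)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble(s = exp(seq(log(min(object$data$s)),
                             log(max(object$data$s)), length.out = 200)))
  grid$v0 <- mm_v0(object$vmax, object$km, grid$s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$s, y = .data$v0)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[S]", y = "initial rate") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble(x = exp(seq(log(min(object$data$x)),
                             log(max(object$data$x)), length.out = 200)))
  grid$y <- object$top * grid$x^object$n_hill /
    (object$k_half^object$n_hill + grid$x^object$n_hill)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
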