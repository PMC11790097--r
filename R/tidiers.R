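#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the iteration history of a fitted selection policy
#'
#' @param x an `rlwbs_fit`.
#' @param ... ignored.
#' @return the history tibble (one row per iteration: `iteration`,
#'   `reward`, `grad_norm`, `loss`, `wall_time`, list-columns `batch` and
#'   `actions`).
#' @method tidy rlwbs_fit
#' @export
tidy.rlwbs_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a fitted selection policy
#'
#' @param x an `rlwbs_fit`.
#' @param ... ignored.
#' @return tibble with `iterations`, `final_reward`, `mean_reward_last10`,
#'   `best_reward`, `terminated_early`.
#' @method glance rlwbs_fit
#' @export
glance.rlwbs_fit <- function(x, ...) {
  r <- x$history$reward
  tibble::tibble(
    iterations = nrow(x$history),
    final_reward = r[length(r)],
    mean_reward_last10 = mean(utils::tail(r, 10)),
    best_reward = max(r),
    terminated_early = x$terminated_early
  )
}

#' Reward-trace plot of a fitted selection policy
#'
#' @param object an `rlwbs_fit`.
#' @param window width of the superimposed running mean.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot rlwbs_fit
#' @export
autoplot.rlwbs_fit <- function(object, window = 10, ...) {
  h <- object$history
  h$running <- if (nrow(h) >= window)
    as.numeric(stats::filter(h$reward, rep(1 / window, window), sides = 1))
  else NA_real_
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$iteration, .data$reward)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "iteration", y = "reward",
                  title = "Evaluation reward per training iteration") +
    ggplot2::theme_minimal()
  if (nrow(h) >= window)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$running),
                                linewidth = 0.8, na.rm = TRUE)
  p
}

#' Selection-histogram plot
#'
#' @param distribution a `family_distribution` tibble from
#'   [evaluate_policy()] (optionally with a grouping column `group`).
#' @return a ggplot object.
#' @export
plot_selection_histogram <- function(distribution) {
  aes <- if ("group" %in% names(distribution))
    ggplot2::aes(.data$family, .data$share, fill = .data$group)
  else ggplot2::aes(.data$family, .data$share)
  ggplot2::ggplot(distribution, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "wavelet family", y = "selected [%]",
                  title = "Greedy base selection by family") +
    ggplot2::theme_minimal()
}
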