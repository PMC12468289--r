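#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an NRO run into its per-generation trace
#'
#' @param x An `nro_result` from [run_nro()].
#' @param ... Unused.
#' @return Tibble with `generation` and `best_fitness`.
#' @export
tidy.nro_result <- function(x, ...) {
  x$trace
}

#' One-row summary of an NRO run
#'
#' @inheritParams tidy.nro_result
#' @return Tibble with `best_fitness`, `n_genes`, `generations_run`,
#'   `stopped_early`, `evaluations`.
#' @export
glance.nro_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    n_genes = length(x$best_genes),
    generations_run = x$generations_run,
    stopped_early = x$stopped_early,
    evaluations = x$evaluations
  )
}

#' Tidy a subset-size sweep
#'
#' One row per (subset size, statistic): accuracy statistics in long form,
#' convenient for plotting and tabulation.
#'
#' @param x An `fnro_sweep` from [run_fnro_sweep()].
#' @param ... Unused.
#' @return Tibble with `k`, `statistic`, `value`.
#' @export
tidy.fnro_sweep <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[c(
      "k", "best_accuracy", "average_accuracy",
      "worst_accuracy", "precision", "recall", "f1"
    )],
    -"k",
    names_to = "statistic", values_to = "value"
  )
}

#' One-row summary of a sweep
#'
#' Reports the smallest subset size achieving the sweep's best accuracy.
#'
#' @inheritParams tidy.fnro_sweep
#' @return Tibble with `best_k`, `best_accuracy`, `precision`, `recall`,
#'   `f1`, `n_sizes`.
#' @export
glance.fnro_sweep <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  i <- which(tb$best_accuracy == max(tb$best_accuracy))[1]
  tibble::tibble(
    best_k = tb$k[i],
    best_accuracy = tb$best_accuracy[i],
    precision = tb$precision[i],
    recall = tb$recall[i],
    f1 = tb$f1[i],
    n_sizes = nrow(tb)
  )
}

#' Tidy a filter comparison grid
#'
#' @param x A `filter_eval` from [evaluate_filters()].
#' @param ... Unused.
#' @return Tibble with `method`, `size`, `accuracy`.
#' @export
tidy.filter_eval <- function(x, ...) {
  x$grid
}

#' One-row summary of a filter comparison
#'
#' @inheritParams tidy.filter_eval
#' @return Tibble with `best_method`, `best_size`, `best_accuracy`.
#' @export
glance.filter_eval <- function(x, ...) {
  tibble::tibble(
    best_method = x$best_method, best_size = x$best_size,
    best_accuracy = x$best_accuracy
  )
}

#' Plot the best-fitness trace of an NRO run
#'
#' @param object An `nro_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nro_result <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$generation, y = .data$best_fitness)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Generation", y = "Best LOOCV accuracy",
      title = "NRO search trace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot accuracy against subset size for a sweep
#'
#' Average accuracy with its 95% confidence ribbon, plus best and worst
#' run accuracies.
#'
#' @param object An `fnro_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fnro_sweep <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$average_accuracy)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$best_accuracy), shape = 2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$worst_accuracy), shape = 6) +
    ggplot2::labs(
      x = "Subset size (genes)", y = "LOOCV accuracy",
      title = "F-NRO accuracy vs subset size",
      subtitle = "line/ribbon: mean and 95% CI over repeats; triangles: best and worst run"
    ) +
    ggplot2::theme_minimal()
}

#' Plot filter accuracy across pool sizes
#'
#' @param object A `filter_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.filter_eval <- function(object, ...) {
  ggplot2::ggplot(
    object$grid,
    ggplot2::aes(
      x = .data$size, y = .data$accuracy,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Candidate pool size (genes)", y = "LOOCV accuracy",
      colour = "Filter", title = "Filter comparison"
    ) +
    ggplot2::theme_minimal()
}
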