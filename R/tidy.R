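#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training fit into its per-epoch history
#'
#' @param x A `colearn_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (epoch, loss component) pair, columns
#'   `epoch`, `component`, `value`, plus the per-epoch `val_ce`.
#' @export
tidy.colearn_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(
      c("total", "ce_image", "ce_text", "l1", "cosine", "ssl"),
      names_to = "component", values_to = "value"
    ) |>
    dplyr::select("epoch", "component", "value", "val_ce")
}

#' One-row summary of a training fit
#'
#' @inheritParams tidy.colearn_fit
#' @return A one-row tibble: `mode`, `ssl_kind`, `epochs`,
#'   `selected_epoch`, `best_val_ce`, `final_train_total`.
#' @export
glance.colearn_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    ssl_kind = x$config$loss_weights$ssl_kind,
    epochs = nrow(x$history),
    selected_epoch = x$selected_epoch,
    best_val_ce = if (nrow(x$history)) {
      min(x$history$val_ce, na.rm = TRUE)
    } else {
      NA_real_
    },
    final_train_total = if (nrow(x$history)) {
      x$history$total[nrow(x$history)]
    } else {
      NA_real_
    }
  )
}

#' Training curves
#'
#' Loss components and validation cross-entropy against epoch.
#'
#' @param object A `colearn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.colearn_fit <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$epoch, y = .data$value, colour = .data$component)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = object$history,
      ggplot2::aes(y = .data$val_ce, colour = "validation image CE"),
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "epoch", y = "loss",
      title = "Training loss components and validation image cross-entropy"
    )
}

#' Tidy a metric report
#'
#' @param x A `metric_report` from [repeat_experiment()].
#' @param ... Unused.
#' @return The per-run tibble (`run`, `seed`, `source`, `kappa`,
#'   `silhouette`).
#' @export
tidy.metric_report <- function(x, ...) x$per_run

#' One-row summary of a metric report
#'
#' @inheritParams tidy.metric_report
#' @return A one-row tibble with the setup and the across-source means of
#'   the per-run metric averages.
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    ssl_kind = x$config$loss_weights$ssl_kind,
    n_runs = max(x$per_run$run),
    mean_kappa = mean(x$per_run$kappa),
    mean_silhouette = mean(x$per_run$silhouette)
  )
}

#' Per-source kappa distribution across runs
#'
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(
    object$per_run,
    ggplot2::aes(x = .data$source, y = .data$kappa)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(
      x = "test source", y = "Cohen's kappa",
      title = "Per-run test kappa by source"
    )
}
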