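# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a metric report
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return long tibble: one row per (slice, metric) with the value.
#' @export
tidy.metric_report <- function(x, ...) {
  x$per_slice |>
    dplyr::mutate(slice = dplyr::row_number()) |>
    tidyr::pivot_longer(cols = c("dsc", "voe", "asd", "acc", "sen", "spe"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("slice", "metric", "value", "both_empty")
}

#' One-row summary of a metric report
#'
#' @param x a `metric_report`.
#' @param ... unused.
#' @return one-row wide tibble of metric means (VOE in percent, ASD in mm).
#' @export
glance.metric_report <- function(x, ...) {
  s <- x$summary
  tibble(dsc_mean = s$mean[s$metric == "dsc"],
         voe_mean = s$mean[s$metric == "voe"],
         asd_mean = s$mean[s$metric == "asd"],
         acc_mean = s$mean[s$metric == "acc"],
         sen_mean = s$mean[s$metric == "sen"],
         spe_mean = s$mean[s$metric == "spe"],
         n_slices = nrow(x$per_slice))
}

#' Per-slice metric distributions
#'
#' @param object a `metric_report`.
#' @param ... unused.
#' @return a ggplot of per-slice metric boxplots (VOE rescaled to \[0, 1\]).
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(value = ifelse(.data$metric == "voe",
                                 .data$value / 100, .data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "per-slice value (VOE / 100)")
}

#' Tidy a training history
#'
#' @param x a `train_history`.
#' @param ... unused.
#' @return long tibble: epoch, series, value.
#' @export
tidy.train_history <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(cols = -"epoch", names_to = "series",
                        values_to = "value")
}

#' One-row summary of a training run
#'
#' @param x a `train_history`.
#' @param ... unused.
#' @return one-row tibble with final losses and Dice values.
#' @export
glance.train_history <- function(x, ...) {
  last <- as_tibble(x)[nrow(x), ]
  tibble(epochs = nrow(x),
         final_g_loss = last$g_loss, final_d_loss = last$d_loss,
         final_train_dice = last$train_dice,
         final_val_loss = last$val_loss, final_val_dice = last$val_dice,
         best_val_dice = max(x$val_dice))
}

#' Loss and Dice curves for a training run
#'
#' @param object a `train_history`.
#' @param ... unused.
#' @return a ggplot with loss curves and Dice curves in two facets.
#' @export
autoplot.train_history <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(panel = ifelse(grepl("dice", .data$series), "Dice", "loss"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
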