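# ggplot2 methods for the result objects.

#' Plot sweep curves
#'
#' Log-rank p-value and ROC AUC versus the sweep axis (percentile or Ktrans
#' threshold), one panel per quantity, both endpoints overlaid, with the 0.05
#' significance line on the p-value panel.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  axis_lab <- if (identical(attr(object, "axis_type"), "percentile"))
    "Ktrans percentile" else "Ktrans threshold (1/min)"
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"axis", names_to = c("quantity", "endpoint"),
                        names_pattern = "(logrank_p|auc)_(dfs|os)") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           logrank_p = "log-rank p",
                                           auc = "ROC AUC"),
                  endpoint = toupper(.data$endpoint))
  ref <- tibble::tibble(quantity = c("log-rank p", "ROC AUC"),
                        y = c(0.05, 0.5))
  ggplot2::ggplot(long, ggplot2::aes(.data$axis, .data$value,
                                     colour = .data$endpoint)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = axis_lab, y = NULL, colour = "Endpoint") +
    ggplot2::theme_minimal()
}

#' Plot a parametric map slice
#'
#' @param object A `parametric_map`.
#' @param slice Axial slice index (default: middle of the mask).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.parametric_map <- function(object, slice = NULL, ...) {
  if (is.null(slice)) {
    ks <- which(apply(object$mask, 3, any))
    slice <- ks[ceiling(length(ks) / 2)]
  }
  df <- tibble::as_tibble(object) |> dplyr::filter(.data$k == slice)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$parameter_name) +
    ggplot2::coord_fixed(ratio = object$voxel_dims_mm[2] /
                           object$voxel_dims_mm[1]) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s map, slice %d",
                                  object$parameter_name, slice)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for one or two groups
#'
#' @param data Data frame with survival columns.
#' @param time,event Column names of the endpoint.
#' @param group Optional column name of a grouping variable.
#' @return A ggplot object with right-continuous step curves.
#' @export
plot_km <- function(data, time = "time_months", event = "event",
                    group = NULL) {
  groups <- if (is.null(group)) list(all = data)
            else split(data, data[[group]])
  steps <- purrr::imap(groups, function(d, nm) {
    f <- km_fit(d, time, event)
    tibble::tibble(group = nm, time = c(0, f$steps$time),
                   survival = c(1, f$steps$survival))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(steps, ggplot2::aes(.data$time, .data$survival,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of a frequency distribution
#'
#' @param object A `freq_dist`.
#' @param bins Number of bins.
#' @param ... Unused.
#' @export
autoplot.freq_dist <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tibble::tibble(value = object$values),
                  ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = object$parameter_name, y = "Voxels") +
    ggplot2::theme_minimal()
}
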