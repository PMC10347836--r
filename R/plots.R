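#' Heat map of a stage (or transition) correlation matrix
#'
#' @param object A `"stage_cor"` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage_cor <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "r") |>
    dplyr::mutate(
      row = factor(.data$row, levels = rev(rownames(object))),
      col = factor(.data$col, levels = colnames(object))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b",
      midpoint = 0, limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean trajectory per cluster or group
#'
#' @param x Stage-averaged long tibble of the clustered values.
#' @param assignments A `"cluster_assignments"` tibble (with or without
#'   `group_label`).
#' @return A ggplot of per-cluster mean log2 trajectories.
#' @export
plot_cluster_trajectories <- function(x, assignments) {
  grp <- if ("group_label" %in% names(assignments)) "group_label" else "cluster"
  df <- x |>
    dplyr::inner_join(assignments, by = "gene_id") |>
    dplyr::summarise(
      m = mean(.data$value),
      .by = dplyr::all_of(c(grp, "stage"))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$m,
    group = .data[[grp]], colour = factor(.data[[grp]])
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "stage", y = "mean log2 intensity", colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Predicted versus observed protein trajectories
#'
#' Observed protein (points) and kinetic-model prediction (lines), both on
#' log2 scale, for a set of genes.
#'
#' @param object A `"kinetic_fits"` tibble.
#' @param observed Stage-averaged protein tibble (log2) used in the fit.
#' @param genes Genes to display (defaults to the first 6 fitted genes).
#' @param ... Unused.
#' @return A faceted ggplot.
#' @export
autoplot.kinetic_fits <- function(object, observed, genes = NULL, ...) {
  if (is.null(genes)) genes <- utils::head(object$gene_id, 6)
  times <- attr(object, "times")
  stages <- names(times)
  pred <- object |>
    tibble::as_tibble() |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::mutate(predicted = purrr::map(.data$predicted, function(p) {
      tibble::tibble(stage = factor(stages, levels = stages), log2_pred = log2(pmax(p, 1e-12)))
    })) |>
    dplyr::select("gene_id", "predicted") |>
    tidyr::unnest("predicted")
  obs <- observed |>
    dplyr::filter(.data$gene_id %in% genes)
  ggplot2::ggplot(pred, ggplot2::aes(.data$stage, .data$log2_pred, group = 1)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(.data$stage, .data$value, group = 1),
      inherit.aes = FALSE
    ) +
    ggplot2::facet_wrap(~gene_id, scales = "free_y") +
    ggplot2::labs(x = "stage", y = "log2 protein abundance") +
    ggplot2::theme_minimal()
}

#' Concordance bin fractions by group
#'
#' @param concordance A `"gene_concordance"` tibble.
#' @param groups Optional tibble `gene_id`, `group` (e.g. trajectory
#'   groups); without it a single "All" bar is drawn.
#' @return A stacked-bar ggplot of high/medium/low fractions.
#' @export
plot_concordance_bins <- function(concordance, groups = NULL) {
  df <- tibble::as_tibble(concordance) |>
    dplyr::filter(!is.na(.data$bin))
  if (is.null(groups)) {
    df$group <- "All"
  } else {
    df <- dplyr::inner_join(df, groups, by = "gene_id")
  }
  frac <- df |>
    dplyr::count(.data$group, .data$bin) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), .by = "group") |>
    dplyr::mutate(bin = factor(.data$bin, levels = c("low", "medium", "high")))
  ggplot2::ggplot(frac, ggplot2::aes(.data$group, .data$fraction, fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(low = "#d1e5f0", medium = "#67a9cf", high = "#2166ac")
    ) +
    ggplot2::labs(x = NULL, y = "fraction of genes", fill = "protein-RPF r") +
    ggplot2::theme_minimal()
}
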