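#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a table of kinetic fits
#'
#' One row per gene and parameter (`p0`, `alpha`, `kd`), broom-style.
#'
#' @param x A `"kinetic_fits"` tibble from [fit_kinetics()].
#' @param ... Unused.
#' @return A long tibble `gene_id`, `mode`, `term`, `estimate`.
#' @export
tidy.kinetic_fits <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("gene_id", "mode", "p0", "alpha", "kd") |>
    tidyr::pivot_longer(c("p0", "alpha", "kd"),
      names_to = "term", values_to = "estimate"
    )
}

#' One-line summary of kinetic fits
#'
#' @param x A `"kinetic_fits"` tibble.
#' @param ... Unused.
#' @return One row: `mode`, `n_genes`, `n_skipped`, `n_boundary`,
#'   `median_r_pred_obs`, `median_sse`.
#' @export
glance.kinetic_fits <- function(x, ...) {
  tibble::tibble(
    mode = x$mode[1],
    n_genes = nrow(x),
    n_skipped = attr(x, "n_skipped") %||% NA_integer_,
    n_boundary = sum(x$boundary),
    median_r_pred_obs = stats::median(x$r_pred_obs, na.rm = TRUE),
    median_sse = stats::median(x$sse)
  )
}

#' One-line summary of dynamics calls
#'
#' @param x A `"dynamics_calls"` tibble from [classify_dynamics()].
#' @param ... Unused.
#' @return One row: `layer`, `n_eligible`, `n_dynamic`,
#'   `dynamic_fraction`, `threshold`.
#' @export
glance.dynamics_calls <- function(x, ...) {
  tibble::tibble(
    layer = attr(x, "layer") %||% NA_character_,
    n_eligible = nrow(x),
    n_dynamic = sum(x$label == "dynamic"),
    dynamic_fraction = attr(x, "fraction"),
    threshold = attr(x, "threshold")
  )
}

#' Per-transition summary of differential calls
#'
#' @param x A `"dep_table"` from [dep_table()].
#' @param ... Unused.
#' @return One row per transition: `transition`, `n_tested`, `n_up`,
#'   `n_down`, `n_de`.
#' @export
glance.dep_table <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      n_de = sum(.data$direction != "none"),
      .by = "transition"
    )
}

#' Bin fractions of gene-wise concordance
#'
#' @param x A `"gene_concordance"` tibble from [genewise_correlation()].
#' @param ... Unused.
#' @return One row: `n`, `median_r`, `frac_high`, `frac_medium`,
#'   `frac_low` (fractions over genes with a defined correlation).
#' @export
glance.gene_concordance <- function(x, ...) {
  def <- dplyr::filter(tibble::as_tibble(x), !is.na(.data$r))
  tibble::tibble(
    n = nrow(def),
    median_r = stats::median(def$r),
    frac_high = mean(def$bin == "high"),
    frac_medium = mean(def$bin == "medium"),
    frac_low = mean(def$bin == "low")
  )
}
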