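#' Developmental stage scaffolding
#'
#' The analyses in this package run over an ordered series of developmental
#' stages. The default series covers the mouse oocyte-to-embryo transition:
#' fully grown oocyte (FGO), MII oocyte, then 1-cell through blastocyst (BL)
#' embryos. Stage time coordinates default to the stage index (0, 1, ..., 6);
#' no absolute time axis is assumed, so kinetic rates are in per-stage units
#' unless other times are supplied.
#'
#' @return `oet_stages()` returns the ordered character vector of stage
#'   labels. `oet_stage_times()` returns a named numeric vector of time
#'   coordinates, one per stage.
#' @examples
#' oet_stages()
#' oet_stage_times()
#' @export
oet_stages <- function() {
  c("FGO", "MII", "1C", "2C", "4C", "8C", "BL")
}

#' @rdname oet_stages
#' @param stages Ordered character vector of stage labels.
#' @param times Optional numeric vector of strictly increasing time
#'   coordinates, same length as `stages`. Defaults to the 0-based stage
#'   index.
#' @export
oet_stage_times <- function(stages = oet_stages(), times = NULL) {
  if (anyDuplicated(stages)) stop("stage labels must be unique", call. = FALSE)
  if (is.null(times)) times <- seq_along(stages) - 1
  if (length(times) != length(stages)) {
    stop("`times` must have one entry per stage", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("stage times must be strictly increasing", call. = FALSE)
  }
  stats::setNames(as.numeric(times), stages)
}

#' Labels for transitions between consecutive stages
#'
#' @param stages Ordered character vector of stage labels.
#' @return Character vector of length `length(stages) - 1`, e.g.
#'   `"FGO->MII"`.
#' @examples
#' stage_transitions()
#' @export
stage_transitions <- function(stages = oet_stages()) {
  n <- length(stages)
  if (n < 2) stop("need at least two stages", call. = FALSE)
  paste0(stages[-n], "->", stages[-1])
}

#' Batch design of the stage-resolved proteome
#'
#' Label-free proteome runs are grouped into acquisition batches; FGO samples
#' are included in every batch so batch offsets can be anchored on a common
#' stage. The default design has three batches: replicate 1 of FGO-8C
#' (batch 1), replicate 2 of FGO-8C (batch 2), and FGO replicates 3-4 plus
#' both blastocyst replicates (batch 3).
#'
#' @return A tibble with columns `stage`, `replicate`, `batch`.
#' @examples
#' oet_batch_design()
#' @export
oet_batch_design <- function() {
  pre_bl <- c("FGO", "MII", "1C", "2C", "4C", "8C")
  dplyr::bind_rows(
    tibble::tibble(stage = pre_bl, replicate = 1L, batch = "batch1"),
    tibble::tibble(stage = pre_bl, replicate = 2L, batch = "batch2"),
    tibble::tibble(
      stage = c("FGO", "FGO", "BL", "BL"),
      replicate = c(3L, 4L, 1L, 2L),
      batch = "batch3"
    )
  )
}

# internal: order a stage column by the series, erroring on unknown labels
check_stages <- function(x, stages) {
  bad <- setdiff(unique(x), stages)
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = stages)
}
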