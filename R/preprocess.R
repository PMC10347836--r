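#' FGO-anchored batch correction factors for the proteome
#'
#' Label-free iBAQ intensities drift between acquisition batches. Because
#' FGO samples were run in every batch, the FGO stage anchors the
#' correction: proteins detected in the anchor stage in every batch are
#' selected, each protein's anchor intensity per batch is summarized (mean
#' over that batch's detected anchor replicates), the per-batch median
#' across these proteins is taken, and each batch's offset is its median
#' minus the reference batch's median. The reference batch offset is 0 by
#' construction.
#'
#' @param protein Replicate-level long tibble with `gene_id`, `stage`,
#'   `replicate`, `batch`, `value` (log2, `NA` = not detected).
#' @param anchor_stage Stage present in every batch (default `"FGO"`).
#' @param reference_batch Batch whose offset is fixed at 0; defaults to the
#'   first batch in sort order.
#' @return A tibble with columns `batch`, `offset` (additive log2), and the
#'   number of anchor proteins used in attribute `"n_anchor"`.
#' @export
compute_batch_factors <- function(protein, anchor_stage = "FGO",
                                  reference_batch = NULL) {
  anchor <- protein |>
    dplyr::filter(.data$stage == anchor_stage, !is.na(.data$value))
  if (nrow(anchor) == 0) {
    stop("anchor stage has no detected proteins", call. = FALSE)
  }
  batches <- sort(unique(protein$batch))
  if (length(batches) < 2) {
    stop("need the anchor stage in at least two batches", call. = FALSE)
  }
  if (is.null(reference_batch)) reference_batch <- batches[1]
  if (!reference_batch %in% batches) {
    stop("unknown reference batch: ", reference_batch, call. = FALSE)
  }
  per_gene <- anchor |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("gene_id", "batch")
    )
  common <- per_gene |>
    dplyr::summarise(n_batches = dplyr::n_distinct(.data$batch), .by = "gene_id") |>
    dplyr::filter(.data$n_batches == length(batches))
  if (nrow(common) == 0) {
    stop("no anchor proteins detected in all batches", call. = FALSE)
  }
  medians <- per_gene |>
    dplyr::semi_join(common, by = "gene_id") |>
    dplyr::summarise(m = stats::median(.data$value), .by = "batch")
  ref_m <- medians$m[medians$batch == reference_batch]
  out <- medians |>
    dplyr::transmute(batch = .data$batch, offset = .data$m - ref_m) |>
    dplyr::arrange(.data$batch)
  attr(out, "n_anchor") <- nrow(common)
  attr(out, "reference_batch") <- reference_batch
  out
}

#' Apply additive batch correction
#'
#' Subtracts each batch's offset from every value in that batch; the
#' missingness mask is unchanged. Re-deriving factors from the corrected
#' matrix yields all-zero offsets (idempotence).
#'
#' @param protein Replicate-level long tibble (see
#'   [compute_batch_factors()]).
#' @param factors Tibble with `batch` and `offset` covering every batch in
#'   `protein`.
#' @return The corrected tibble, same shape and mask.
#' @export
apply_batch_correction <- function(protein, factors) {
  missing_batches <- setdiff(unique(protein$batch), factors$batch)
  if (length(missing_batches) > 0) {
    stop("no offset for batch(es): ", paste(missing_batches, collapse = ", "),
      call. = FALSE
    )
  }
  layer <- attr(protein, "layer")
  out <- protein |>
    dplyr::left_join(dplyr::select(factors, "batch", "offset"), by = "batch") |>
    dplyr::mutate(value = .data$value - .data$offset) |>
    dplyr::select(-"offset")
  attr(out, "layer") <- layer
  out
}

#' Average replicates into a stage-level matrix
#'
#' Per gene and stage, the mean is taken over replicates in which the gene
#' was detected; a stage value is missing only when all its replicates are
#' missing. The anchor stage (FGO) with four replicates is handled
#' specially: replicates are first paired per `fgo_policy` into two derived
#' replicates (each the mean of its detected members), which are then
#' averaged. Genes detected in exactly one derived FGO replicate are
#' recorded in the `"fgo_single"` attribute for exclusion by
#' [filter_gene_universe()].
#'
#' @param x Replicate-level long tibble with `gene_id`, `stage`,
#'   `replicate`, `value`.
#' @param fgo_policy List of integer vectors pairing FGO replicate numbers
#'   into derived replicates; pairs with no replicates present in the data
#'   are dropped.
#' @param fgo_stage Label of the four-replicate anchor stage.
#' @return Stage-averaged long tibble (`gene_id`, `stage`, `value`), with
#'   attributes `"fgo_single"` (character vector of flagged genes) and
#'   `"layer"` carried over.
#' @export
merge_replicates <- function(x, fgo_policy = list(c(1, 2), c(3, 4)),
                             fgo_stage = "FGO") {
  if (!"replicate" %in% names(x)) {
    stop("`x` must be replicate-level (have a `replicate` column)",
      call. = FALSE
    )
  }
  if (nrow(x) == 0) stop("empty matrix", call. = FALSE)
  other <- x |>
    dplyr::filter(.data$stage != fgo_stage) |>
    dplyr::summarise(
      value = mean_detected(.data$value),
      .by = c("gene_id", "stage")
    )
  fgo <- dplyr::filter(x, .data$stage == fgo_stage)
  fgo_single <- character(0)
  if (nrow(fgo) > 0) {
    pair_of <- integer(0)
    for (i in seq_along(fgo_policy)) pair_of[fgo_policy[[i]]] <- i
    fgo$derived <- pair_of[fgo$replicate]
    if (anyNA(fgo$derived)) {
      stop("fgo_policy does not cover all FGO replicates", call. = FALSE)
    }
    derived <- fgo |>
      dplyr::summarise(
        value = mean_detected(.data$value),
        .by = c("gene_id", "derived")
      )
    fgo_avg <- derived |>
      dplyr::summarise(
        n_detected = sum(!is.na(.data$value)),
        value = mean_detected(.data$value),
        .by = "gene_id"
      )
    fgo_single <- fgo_avg$gene_id[fgo_avg$n_detected == 1]
    fgo_out <- fgo_avg |>
      dplyr::transmute(
        gene_id = .data$gene_id, stage = fgo$stage[1],
        value = .data$value
      )
    other <- dplyr::bind_rows(fgo_out, other)
  }
  out <- dplyr::arrange(other, .data$gene_id, .data$stage)
  attr(out, "layer") <- attr(x, "layer")
  attr(out, "fgo_single") <- fgo_single
  out
}

# mean over detected values; NA if nothing detected
mean_detected <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Build the analysis gene universe
#'
#' Combines two filters: (i) cross-batch consistency of the anchor stage --
#' genes whose protein was detected in exactly one of the two derived FGO
#' replicates are excluded (genes never detected in FGO, e.g. embryonic
#' proteins, are retained); (ii) RNA support -- genes never detected
#' (FPKM > 0) at any stage or replicate in either the RPF or the mRNA
#' layer are excluded.
#'
#' @param protein Replicate-level protein tibble (log2, `NA` = missing).
#' @param rpf,mrna RPF / mRNA tibbles (replicate-level or stage-averaged
#'   FPKM).
#' @param fgo_policy,fgo_stage Passed to [merge_replicates()].
#' @return Sorted character vector of gene ids passing both filters.
#' @export
filter_gene_universe <- function(protein, rpf, mrna,
                                 fgo_policy = list(c(1, 2), c(3, 4)),
                                 fgo_stage = "FGO") {
  genes_p <- unique(protein$gene_id)
  genes_rna <- union(unique(rpf$gene_id), unique(mrna$gene_id))
  if (length(intersect(genes_p, genes_rna)) == 0) {
    stop("protein and RNA layers share no gene ids", call. = FALSE)
  }
  merged <- merge_replicates(protein, fgo_policy, fgo_stage)
  fgo_single <- attr(merged, "fgo_single")
  rna_detected <- function(x) {
    x |>
      dplyr::summarise(
        any_pos = any(!is.na(.data$value) & .data$value > 0),
        .by = "gene_id"
      )
  }
  det <- dplyr::full_join(rna_detected(rpf), rna_detected(mrna),
    by = "gene_id", suffix = c("_rpf", "_mrna")
  )
  det$any <- dplyr::coalesce(det$any_pos_rpf, FALSE) |
    dplyr::coalesce(det$any_pos_mrna, FALSE)
  rna_ok <- det$gene_id[det$any]
  sort(setdiff(intersect(genes_p, rna_ok), fgo_single))
}

#' Impute missing log2 intensities at a global detection floor
#'
#' Downstream correlation and CV analyses need complete series. Missing
#' protein values are replaced with (global minimum detected log2 value -
#' `offset`), preserving "not detected = lowest abundance" semantics
#' without infinities.
#'
#' @param x Long tibble with a `value` column (log2 scale).
#' @param offset Log2 units below the global detected minimum.
#' @return `x` with `NA` values replaced; the floor used is stored in the
#'   `"impute_floor"` attribute.
#' @export
impute_missing <- function(x, offset = 1) {
  layer <- attr(x, "layer")
  floor_val <- min(x$value, na.rm = TRUE) - offset
  x$value[is.na(x$value)] <- floor_val
  attr(x, "layer") <- layer
  attr(x, "impute_floor") <- floor_val
  x
}
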