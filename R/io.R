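#' Read a gene-by-sample omics matrix from TSV
#'
#' Matrices are tab-delimited with genes as rows. Replicate-level files have
#' columns named `STAGE_repN` (e.g. `FGO_rep1`); stage-averaged files have
#' plain stage-label columns. Empty cells mean "not detected". For the
#' protein layer (log2 iBAQ), empty and zero-intensity cells are both masked
#' as missing; for FPKM layers an explicit 0 is a detected zero.
#'
#' @param path Path to a TSV file whose first column holds gene identifiers.
#' @param layer One of `"protein_log2_ibaq"`, `"rpf_fpkm"`, `"mrna_fpkm"`.
#' @param stages Ordered stage labels the columns must map into.
#' @param batch_design Tibble with `stage`, `replicate`, `batch` used to
#'   annotate replicate-level protein columns; `NULL` leaves `batch` `NA`.
#' @return A long tibble with columns `gene_id`, `stage`, `replicate`
#'   (absent for stage-averaged files), `batch` (replicate-level only),
#'   `value` (`NA` = not detected), with the layer stored in the `"layer"`
#'   attribute.
#' @seealso [write_omics()]
#' @export
read_omics <- function(path, layer, stages = oet_stages(),
                       batch_design = oet_batch_design()) {
  layer <- match.arg(layer, c("protein_log2_ibaq", "rpf_fpkm", "mrna_fpkm"))
  wide <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(wide)[1] <- "gene_id"
  if (anyDuplicated(wide$gene_id)) {
    stop("duplicate gene ids in ", path, call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"gene_id",
    names_to = "column", values_to = "value"
  ) |>
    dplyr::mutate(value = as.numeric(.data$value))
  rep_cols <- grepl("_rep[0-9]+$", long$column)
  if (all(rep_cols)) {
    long <- long |>
      tidyr::separate_wider_regex("column",
        c(stage = ".+", "_rep", replicate = "[0-9]+")
      ) |>
      dplyr::mutate(replicate = as.integer(.data$replicate))
    if (!is.null(batch_design)) {
      long <- dplyr::left_join(long, batch_design, by = c("stage", "replicate"))
    } else {
      long$batch <- NA_character_
    }
  } else if (any(rep_cols)) {
    stop("mixed replicate-level and stage-averaged columns in ", path,
      call. = FALSE
    )
  } else {
    long <- dplyr::rename(long, stage = "column")
  }
  long$stage <- check_stages(long$stage, stages)
  if (layer == "protein_log2_ibaq") {
    long$value[!is.na(long$value) & long$value == 0] <- NA_real_
  }
  out <- dplyr::arrange(long, .data$gene_id, .data$stage)
  attr(out, "layer") <- layer
  out
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_omics()]: long tibbles with a `replicate` column are
#' written with `STAGE_repN` headers, stage-averaged tibbles with stage
#' headers. Missing values are written as empty cells.
#'
#' @param x Long tibble as returned by [read_omics()] or produced by the
#'   synthetic generator / [merge_replicates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics <- function(x, path) {
  if ("replicate" %in% names(x)) {
    wide <- x |>
      dplyr::mutate(column = paste0(.data$stage, "_rep", .data$replicate)) |>
      dplyr::select("gene_id", "column", "value") |>
      tidyr::pivot_wider(names_from = "column", values_from = "value")
  } else {
    wide <- x |>
      dplyr::select("gene_id", "stage", "value") |>
      tidyr::pivot_wider(names_from = "stage", values_from = "value")
  }
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write per-residue disorder score files
#'
#' One line per protein: the gene identifier followed by whitespace-separated
#' per-residue disorder scores in \[0, 1\] (as produced by per-residue
#' disorder predictors; this package consumes scores, it does not compute
#' them).
#'
#' @param path File path.
#' @return `read_disorder_scores()` returns a named list of numeric vectors.
#' @export
read_disorder_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  scores <- lapply(parts, function(p) as.numeric(p[-1]))
  names(scores) <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names(scores))) {
    stop("duplicate gene ids in ", path, call. = FALSE)
  }
  scores
}

#' @rdname read_disorder_scores
#' @param scores Named list of numeric score vectors.
#' @export
write_disorder_scores <- function(scores, path) {
  lines <- vapply(
    seq_along(scores),
    function(i) paste(c(names(scores)[i], format(scores[[i]], trim = TRUE)),
      collapse = " "
    ),
    ""
  )
  writeLines(lines, path)
  invisible(path)
}
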