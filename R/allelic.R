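#' Variant-centered peptide windows for allele-resolved searches
#'
#' For a nonsynonymous variant at a protein position, builds the reference
#' and alternative peptide windows spanning `flank` residues on each side
#' of the variant (61 amino acids for the default flank of 30), clipped at
#' the protein termini rather than padded. The two windows differ at
#' exactly the variant residue.
#'
#' @param sequence Amino-acid string (single-letter code).
#' @param position 1-based index of the variant residue.
#' @param alt_residue Alternative amino acid (must differ from the
#'   reference residue; a match is a synonymous-variant error).
#' @param flank Residues retained on each side of the variant.
#' @return A one-row tibble: `ref_window`, `alt_window`, `window_start`,
#'   `window_end` (1-based inclusive protein coordinates), `variant_offset`
#'   (1-based position of the variant within the window).
#' @examples
#' extract_variant_peptide(paste(rep("A", 61), collapse = ""), 31, "V")
#' @export
extract_variant_peptide <- function(sequence, position, alt_residue,
                                    flank = 30) {
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop("variant position out of range", call. = FALSE)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!alt_residue %in% aa) {
    stop("alt_residue is not a standard amino acid", call. = FALSE)
  }
  ref <- substr(sequence, position, position)
  if (identical(ref, alt_residue)) {
    stop("synonymous variant: alternative equals reference residue",
      call. = FALSE
    )
  }
  start <- max(1, position - flank)
  end <- min(n, position + flank)
  ref_window <- substr(sequence, start, end)
  alt_window <- ref_window
  substr(alt_window, position - start + 1, position - start + 1) <- alt_residue
  tibble::tibble(
    ref_window = ref_window, alt_window = alt_window,
    window_start = start, window_end = end,
    variant_offset = position - start + 1
  )
}

#' Write variant peptide windows as FASTA
#'
#' Headers follow `gene_id|position|allele` with allele `ref` or `alt`.
#'
#' @param windows Tibble with `gene_id`, `position`, `ref_window`,
#'   `alt_window` (e.g. rows of [extract_variant_peptide()] bound with
#'   their gene and position).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_fasta <- function(windows, path) {
  lines <- unlist(purrr::pmap(
    windows[c("gene_id", "position", "ref_window", "alt_window")],
    function(gene_id, position, ref_window, alt_window) {
      c(
        sprintf(">%s|%d|ref", gene_id, position), ref_window,
        sprintf(">%s|%d|alt", gene_id, position), alt_window
      )
    }
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Call allele-specific protein expression
#'
#' Per gene and stage, maternal and paternal allele intensities are
#' compared with a two-tailed equal-variance t-test; stages where one
#' allele is entirely undetected are tested after substituting a detection
#' floor (minimum detected log2 value - `undetected_offset`) for the
#' missing allele, and stages where neither allele is detected are
#' skipped. The default offset of 2 places an absent allele at least one
#' full fold below every observed intensity, so a detected-versus-absent
#' contrast can always clear the two-fold rule. A gene shows ASE when
#' p < `p_threshold` and |log2 FC| > `fc_log2` at one or more embryo
#' stages.
#'
#' ASE genes are categorized by detection pattern: `oocyte_specific`
#' (maternal signal in oocyte stages, paternal never detected),
#' `oocyte_embryonic` (maternal from the oocyte onward, paternal appearing
#' after zygotic genome activation), `embryonic_maternal` /
#' `embryonic_paternal` (no oocyte detection, single-allele signal in
#' embryos), else `none`.
#'
#' @param table Long tibble: `gene_id`, `stage`, `replicate`, `allele`
#'   (`"maternal"`/`"paternal"`), `value` (log2, `NA` = not detected),
#'   batch-corrected with the same pipeline as total protein.
#' @param p_threshold,fc_log2 ASE thresholds (defaults: 0.05, two-fold).
#' @param undetected_offset Log2 units below the table's detected minimum
#'   at which an undetected allele is substituted for testing.
#' @param embryo_stages Stages at which ASE qualifies a gene.
#' @param oocyte_stages Stages defining oocyte detection.
#' @param post_zga_stages Stages after zygotic genome activation.
#' @return A tibble of class `"ase_calls"`: one row per gene with `ase`,
#'   `category`, `min_p`, `max_abs_log2_fc`; per-stage test detail in the
#'   `"stage_tests"` attribute.
#' @export
ase_call <- function(table, p_threshold = 0.05, fc_log2 = 1,
                     undetected_offset = 2,
                     embryo_stages = c("1C", "2C", "4C", "8C", "BL"),
                     oocyte_stages = c("FGO", "MII"),
                     post_zga_stages = c("2C", "4C", "8C", "BL")) {
  if (all(is.na(table$value))) stop("no detected allele intensities", call. = FALSE)
  floor_val <- min(table$value, na.rm = TRUE) - undetected_offset
  detected <- table |>
    dplyr::summarise(
      det = any(!is.na(.data$value)),
      .by = c("gene_id", "stage", "allele")
    )
  tests <- table |>
    dplyr::mutate(stage = as.character(.data$stage)) |>
    tidyr::pivot_wider(names_from = "allele", values_from = "value") |>
    dplyr::summarise(
      n_mat = sum(!is.na(.data$maternal)),
      n_pat = sum(!is.na(.data$paternal)),
      mat = list(.data$maternal), pat = list(.data$paternal),
      .by = c("gene_id", "stage")
    ) |>
    dplyr::filter(.data$n_mat > 0 | .data$n_pat > 0)
  stage_tests <- purrr::pmap_dfr(tests, function(gene_id, stage, n_mat, n_pat,
                                                 mat, pat) {
    m <- ifelse(is.na(mat), floor_val, mat)
    p <- ifelse(is.na(pat), floor_val, pat)
    if (length(m) < 2 || length(p) < 2) {
      return(NULL) # single-replicate stage: skipped
    }
    call <- dep_call(p, m, fc_log2 = fc_log2, p_threshold = p_threshold)
    tibble::tibble(
      gene_id = gene_id, stage = stage,
      log2_fc = call$log2_fc, # maternal minus paternal
      p_value = call$p_value,
      significant = call$p_value < p_threshold & abs(call$log2_fc) > fc_log2
    )
  })
  det_in <- function(g, allele_, stages_) {
    any(detected$det[
      detected$gene_id == g & detected$allele == allele_ &
        as.character(detected$stage) %in% stages_
    ])
  }
  genes <- unique(table$gene_id)
  out <- purrr::map_dfr(genes, function(g) {
    st <- dplyr::filter(stage_tests, .data$gene_id == g)
    emb <- dplyr::filter(st, .data$stage %in% embryo_stages)
    ase <- nrow(emb) > 0 && any(emb$significant)
    mat_oocyte <- det_in(g, "maternal", oocyte_stages)
    pat_oocyte <- det_in(g, "paternal", oocyte_stages)
    mat_any <- det_in(g, "maternal", unique(as.character(table$stage)))
    pat_any <- det_in(g, "paternal", unique(as.character(table$stage)))
    pat_post_zga <- det_in(g, "paternal", post_zga_stages)
    mat_embryo <- det_in(g, "maternal", embryo_stages)
    category <- if (!ase) {
      "none"
    } else if (mat_oocyte && !pat_any) {
      "oocyte_specific"
    } else if (mat_oocyte && pat_post_zga) {
      "oocyte_embryonic"
    } else if (!mat_oocyte && !pat_oocyte && mat_embryo && !pat_any) {
      "embryonic_maternal"
    } else if (!mat_oocyte && !pat_oocyte && pat_post_zga && !mat_any) {
      "embryonic_paternal"
    } else {
      "none"
    }
    tibble::tibble(
      gene_id = g, ase = ase, category = category,
      min_p = if (nrow(emb) > 0) min(emb$p_value) else NA_real_,
      max_abs_log2_fc = if (nrow(emb) > 0) max(abs(emb$log2_fc)) else NA_real_
    )
  })
  attr(out, "stage_tests") <- stage_tests
  class(out) <- c("ase_calls", class(out))
  out
}
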