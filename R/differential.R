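#' Differential-abundance call between two replicate groups
#'
#' Two-sample equal-variance (classical Student) two-tailed t-test on log2
#' values, combined with a fold-change rule: a gene is called up (down)
#' when log2 fold change >= `fc_log2` (<= -`fc_log2`) and p < `p_threshold`.
#' With only 2 replicates per group, the pooled-variance test is the stable
#' choice. Degenerate conventions: if both groups have zero variance, p = 1
#' when the means are equal and p = 0 otherwise.
#'
#' @param group_a,group_b Numeric log2 replicate values (>= 2 each).
#' @param fc_log2 Log2 fold-change threshold (1 = two-fold; CHX mode uses
#'   2 = four-fold).
#' @param p_threshold Raw p-value threshold (no multiple-testing
#'   correction is applied anywhere in these calls, by design).
#' @return A one-row tibble: `log2_fc` (mean B - mean A), `p_value`,
#'   `direction` (`"up"`, `"down"`, `"none"`).
#' @export
dep_call <- function(group_a, group_b, fc_log2 = 1, p_threshold = 0.05) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need >= 2 detected replicates per group", call. = FALSE)
  }
  lfc <- mean(group_b) - mean(group_a)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    p <- if (lfc == 0) 1 else 0
  } else {
    p <- stats::t.test(group_b, group_a, var.equal = TRUE)$p.value
  }
  direction <- if (abs(lfc) >= fc_log2 && p < p_threshold) {
    if (lfc > 0) "up" else "down"
  } else {
    "none"
  }
  tibble::tibble(log2_fc = lfc, p_value = p, direction = direction)
}

#' Differential expression between all consecutive stage transitions
#'
#' Applies [dep_call()] to every gene at every consecutive stage pair of a
#' replicate-level matrix. FPKM layers are log2(x + 1) transformed before
#' testing. Genes with fewer than 2 detected replicates on either side of
#' a transition are skipped there (counted in `"n_skipped"`).
#'
#' @param x Replicate-level long tibble (`gene_id`, `stage`, `replicate`,
#'   `value`).
#' @param layer Layer id (defaults to the `"layer"` attribute); FPKM
#'   layers trigger the log2(x + 1) transform.
#' @param fc_log2,p_threshold See [dep_call()].
#' @return A tibble of class `"dep_table"`: `gene_id`, `transition`,
#'   `log2_fc`, `p_value`, `direction`. Counts per transition via
#'   [glance()].
#' @export
dep_table <- function(x, layer = attr(x, "layer"), fc_log2 = 1,
                      p_threshold = 0.05) {
  stages <- if (is.factor(x$stage)) levels(x$stage) else unique(x$stage)
  if (!is.null(layer) && layer %in% c("rpf_fpkm", "mrna_fpkm")) {
    x <- dplyr::mutate(x, value = log2(.data$value + 1))
  }
  trans <- stage_transitions(stages)
  skipped <- 0L
  rows <- purrr::map_dfr(seq_along(trans), function(i) {
    a <- dplyr::filter(x, .data$stage == stages[i], !is.na(.data$value))
    b <- dplyr::filter(x, .data$stage == stages[i + 1], !is.na(.data$value))
    counts <- dplyr::inner_join(
      dplyr::count(a, .data$gene_id),
      dplyr::count(b, .data$gene_id),
      by = "gene_id"
    )
    testable <- counts$gene_id[counts$n.x >= 2 & counts$n.y >= 2]
    skipped <<- skipped +
      length(union(unique(a$gene_id), unique(b$gene_id))) - length(testable)
    if (length(testable) == 0) return(NULL)
    av <- split(a$value[a$gene_id %in% testable], a$gene_id[a$gene_id %in% testable])
    bv <- split(b$value[b$gene_id %in% testable], b$gene_id[b$gene_id %in% testable])
    purrr::map_dfr(testable, function(g) {
      dplyr::bind_cols(
        tibble::tibble(gene_id = g, transition = trans[i]),
        dep_call(av[[g]], bv[[g]], fc_log2, p_threshold)
      )
    })
  })
  rows$transition <- factor(rows$transition, levels = trans)
  attr(rows, "n_skipped") <- skipped
  attr(rows, "fc_log2") <- fc_log2
  attr(rows, "p_threshold") <- p_threshold
  class(rows) <- c("dep_table", class(rows))
  rows
}

#' Attribute protein changes to transcription or translation
#'
#' Because detectable protein changes lag behind translation and
#' transcription, each differential protein at transition i is compared
#' with mRNA and RPF changes at the current and up to `lag` preceding
#' transitions. A DEP is `mrna_contributed` when any same-direction mRNA
#' change in that window exceeds the fold threshold, else `rpf_only` when
#' an RPF change does, else `unexplained` (candidate post-translational
#' regulation).
#'
#' @param deps A `"dep_table"` of protein calls (only rows with direction
#'   != "none" are attributed).
#' @param rpf_changes,mrna_changes Outputs of [change_matrix()] covering
#'   the same transitions.
#' @param lag Number of preceding transitions in the window.
#' @param change_log2 Log2 change magnitude that counts as a contributing
#'   change (1 = two-fold).
#' @return Tibble `gene_id`, `transition`, `direction`, `category`;
#'   per-transition category fractions in the `"fractions"` attribute.
#' @export
attribute_changes <- function(deps, rpf_changes, mrna_changes, lag = 2,
                              change_log2 = 1) {
  hits <- dplyr::filter(deps, .data$direction != "none")
  trans <- levels(deps$transition)
  if (!identical(trans, levels(rpf_changes$transition)) ||
    !identical(trans, levels(mrna_changes$transition))) {
    stop("change tables do not cover the DEP transitions", call. = FALSE)
  }
  explained <- function(ch, gene, window, sign_dep) {
    sel <- ch$gene_id == gene & ch$transition %in% window
    any(!is.na(ch$change[sel]) &
      abs(ch$change[sel]) > change_log2 &
      sign(ch$change[sel]) == sign_dep)
  }
  out <- purrr::pmap_dfr(
    hits[c("gene_id", "transition", "direction")],
    function(gene_id, transition, direction) {
      i <- match(as.character(transition), trans)
      window <- trans[max(1, i - lag):i]
      s <- if (direction == "up") 1 else -1
      category <- if (explained(mrna_changes, gene_id, window, s)) {
        "mrna_contributed"
      } else if (explained(rpf_changes, gene_id, window, s)) {
        "rpf_only"
      } else {
        "unexplained"
      }
      tibble::tibble(
        gene_id = gene_id, transition = transition,
        direction = direction, category = category
      )
    }
  )
  fr <- out |>
    dplyr::count(.data$transition, .data$category) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), .by = "transition")
  attr(out, "fractions") <- fr
  out
}

#' FGO-originated proteins and their persistence to blastocyst
#'
#' Identifies proteins stocked in the fully grown oocyte with no or low
#' translation after fertilization: detected in the FGO proteome and with
#' RPF FPKM below `fpkm_threshold` at every stage from 1C onward. The
#' persistence fraction is the share of these genes whose protein is still
#' detected at the blastocyst stage.
#'
#' @param protein Stage-averaged protein tibble (log2, `NA` = not
#'   detected; do not impute before this call).
#' @param rpf Stage-averaged RPF FPKM tibble.
#' @param fpkm_threshold Strict upper bound on post-fertilization RPF.
#' @param post_stages Stages over which the RPF bound must hold.
#' @param final_stage Stage at which persistence is assessed.
#' @return Tibble `gene_id`, `persists` (detected at `final_stage`);
#'   attributes `"n"` and `"persistence_fraction"`.
#' @export
fgo_originated <- function(protein, rpf, fpkm_threshold = 5,
                           post_stages = c("1C", "2C", "4C", "8C", "BL"),
                           final_stage = "BL") {
  fgo_det <- protein |>
    dplyr::filter(.data$stage == "FGO", !is.na(.data$value)) |>
    dplyr::pull("gene_id")
  low_rpf <- rpf |>
    dplyr::filter(.data$stage %in% post_stages) |>
    dplyr::summarise(
      low = all(!is.na(.data$value) & .data$value < fpkm_threshold),
      .by = "gene_id"
    ) |>
    dplyr::filter(.data$low) |>
    dplyr::pull("gene_id")
  genes <- intersect(fgo_det, low_rpf)
  bl <- protein |>
    dplyr::filter(.data$stage == final_stage, .data$gene_id %in% genes)
  out <- tibble::tibble(
    gene_id = sort(genes),
    persists = !is.na(bl$value[match(sort(genes), bl$gene_id)])
  )
  attr(out, "n") <- nrow(out)
  attr(out, "persistence_fraction") <- mean(out$persists)
  out
}

#' Translation-inhibition (CHX) response of the proteome
#'
#' Compares protein intensities between translation-inhibitor-treated
#' (cycloheximide) and control (DMSO) samples; treated replicates may pool
#' treatment durations. Repressed proteins are called by the differential
#' rule at a four-fold threshold (|log2 FC| >= 2, p < 0.05), capturing
#' proteins whose abundance depends on ongoing synthesis; all other
#' detected genes are "unaffected".
#'
#' @param x Long tibble with `gene_id`, `condition` (`"DMSO"`/`"CHX"`),
#'   `replicate`, `value` (log2, `NA` = missing).
#' @param fc_log2,p_threshold Thresholds (defaults: four-fold, 0.05).
#' @return Tibble `gene_id`, `log2_fc` (CHX - DMSO), `p_value`, `status`
#'   (`"repressed"`/`"unaffected"`).
#' @export
chx_response <- function(x, fc_log2 = 2, p_threshold = 0.05) {
  conds <- unique(x$condition)
  if (!all(c("DMSO", "CHX") %in% conds)) {
    stop("need both DMSO and CHX conditions", call. = FALSE)
  }
  counts <- x |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$gene_id, .data$condition) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "n", values_fill = 0)
  testable <- counts$gene_id[counts$DMSO >= 2 & counts$CHX >= 2]
  purrr::map_dfr(testable, function(g) {
    a <- x$value[x$gene_id == g & x$condition == "DMSO" & !is.na(x$value)]
    b <- x$value[x$gene_id == g & x$condition == "CHX" & !is.na(x$value)]
    call <- dep_call(a, b, fc_log2, p_threshold)
    tibble::tibble(
      gene_id = g, log2_fc = call$log2_fc, p_value = call$p_value,
      status = if (call$direction == "down") "repressed" else "unaffected"
    )
  })
}

#' Overlap enrichment between two gene sets
#'
#' Builds the 2 x 2 membership table of two sets within a universe and
#' tests enrichment with a two-sided Fisher's exact test (hypergeometric).
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Nonempty character vector of all eligible genes.
#' @return One-row tibble: `overlap`, `overlap_fraction` (of `set_a`),
#'   `odds_ratio` (conditional MLE), `p_value`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  tibble::tibble(
    overlap = sum(in_a & in_b),
    overlap_fraction = if (sum(in_a) > 0) sum(in_a & in_b) / sum(in_a) else NA_real_,
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value
  )
}

#' Dormant maternal mRNAs
#'
#' Maternal transcripts stored untranslated in FGOs that gain translation
#' upon meiotic resumption: RPF MII/FGO ratio > `ratio` without a
#' comparable mRNA increase (mRNA MII/FGO < `ratio`). Ratios are computed
#' on FPKM with a pseudocount to avoid division by zero.
#'
#' @param rpf,mrna Stage-averaged FPKM tibbles containing FGO and MII.
#' @param ratio Fold threshold.
#' @param pseudocount Added to numerator and denominator FPKM.
#' @return Sorted character vector of dormant gene ids.
#' @export
dormant_mrna_set <- function(rpf, mrna, ratio = 2, pseudocount = 0.1) {
  stage_ratio <- function(x) {
    x |>
      dplyr::filter(.data$stage %in% c("FGO", "MII")) |>
      tidyr::pivot_wider(
        id_cols = "gene_id", names_from = "stage",
        values_from = "value"
      ) |>
      dplyr::mutate(
        ratio = (.data$MII + pseudocount) / (.data$FGO + pseudocount)
      )
  }
  r <- stage_ratio(rpf)
  m <- stage_ratio(mrna)
  joined <- dplyr::inner_join(
    dplyr::select(r, "gene_id", rpf_ratio = "ratio"),
    dplyr::select(m, "gene_id", mrna_ratio = "ratio"),
    by = "gene_id"
  )
  sort(joined$gene_id[
    !is.na(joined$rpf_ratio) & !is.na(joined$mrna_ratio) &
      joined$rpf_ratio > ratio & joined$mrna_ratio < ratio
  ])
}
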