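#' Gene-wise protein-translation/transcription correlation
#'
#' For each gene, the Spearman rank correlation between its protein
#' trajectory and its RPF (or mRNA) trajectory over the developmental
#' stages, with average ranks for ties. Genes are binned by concordance:
#' low (r < 0.2), medium (0.2 <= r <= 0.5), high (r > 0.5); boundary values
#' fall to the closed side of the lower bin, matching the strict "r > 0.5"
#' convention for the high bin.
#'
#' @param protein,other Stage-averaged long tibbles sharing a gene space.
#'   Stages missing (NA) in either layer for a gene are dropped pairwise;
#'   genes with fewer than `min_stages` complete pairs are skipped and
#'   counted in the `"n_skipped"` attribute.
#' @param min_stages Minimum complete stage pairs per gene.
#' @return A tibble of class `"gene_concordance"`: `gene_id`, `n_stages`,
#'   `r`, `bin`. `r` is `NA` when either series is constant (rank
#'   correlation undefined).
#' @export
genewise_correlation <- function(protein, other, min_stages = 3) {
  joined <- dplyr::inner_join(
    dplyr::select(protein, "gene_id", "stage", p = "value"),
    dplyr::select(other, "gene_id", "stage", o = "value"),
    by = c("gene_id", "stage")
  ) |>
    dplyr::filter(!is.na(.data$p), !is.na(.data$o))
  out <- joined |>
    dplyr::summarise(
      n_stages = dplyr::n(),
      r = if (dplyr::n() < min_stages ||
        stats::sd(.data$p) == 0 || stats::sd(.data$o) == 0) {
        NA_real_
      } else {
        stats::cor(.data$p, .data$o, method = "spearman")
      },
      .by = "gene_id"
    )
  skipped <- sum(out$n_stages < min_stages)
  out <- dplyr::filter(out, .data$n_stages >= min_stages) |>
    dplyr::mutate(bin = concordance_bin(.data$r))
  attr(out, "n_skipped") <- skipped
  class(out) <- c("gene_concordance", class(out))
  out
}

#' @rdname genewise_correlation
#' @param r Numeric vector of correlations.
#' @export
concordance_bin <- function(r) {
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r > 0.5 ~ "high",
    r >= 0.2 ~ "medium",
    .default = "low"
  )
}

#' Per-transition log2 changes of a stage-averaged matrix
#'
#' change(g, i -> i+1) = value at stage i+1 minus value at stage i on the
#' log2 scale. FPKM layers are log2(x + 1) transformed first (pseudocount 1
#' keeps zero FPKM at zero log signal); log2 protein intensities are used
#' as-is.
#'
#' @param x Stage-averaged long tibble.
#' @param layer Layer id; defaults to the `"layer"` attribute. FPKM layers
#'   trigger the log2(x + 1) transform.
#' @return Long tibble `gene_id`, `transition` (factor in stage order),
#'   `change`.
#' @export
change_matrix <- function(x, layer = attr(x, "layer")) {
  stages <- if (is.factor(x$stage)) levels(x$stage) else unique(x$stage)
  m <- stage_value_matrix(x, stages)
  if (!is.null(layer) && layer %in% c("rpf_fpkm", "mrna_fpkm")) {
    m <- log2(m + 1)
  }
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  trans <- stage_transitions(stages)
  colnames(d) <- trans
  tibble::as_tibble(d, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "transition", values_to = "change") |>
    dplyr::mutate(transition = factor(.data$transition, levels = trans))
}

#' Lagged correlation between protein changes and RNA-layer changes
#'
#' Entry (i, j) is the Spearman correlation across genes between the
#' protein change at transition i and the other layer's change at
#' transition j. The main diagonal captures synchronized changes; the
#' diagonals at offsets 1 and 2 are the one- and two-stage-lagging series
#' (protein transition i versus RNA transition i-1 or i-2).
#'
#' @param protein_changes,other_changes Outputs of [change_matrix()]
#'   sharing >= 3 genes.
#' @return A transitions x transitions matrix of class `"stage_cor"`
#'   (protein transitions in rows).
#' @seealso [lag_diagonal()]
#' @export
lagged_change_correlation <- function(protein_changes, other_changes) {
  widen <- function(ch) {
    trans <- levels(ch$transition)
    w <- tidyr::pivot_wider(ch,
      names_from = "transition", values_from = "change"
    )
    m <- as.matrix(w[, trans])
    rownames(m) <- w$gene_id
    m
  }
  mp <- widen(protein_changes)
  mo <- widen(other_changes)
  genes <- intersect(rownames(mp), rownames(mo))
  if (length(genes) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  out <- stats::cor(mp[genes, , drop = FALSE], mo[genes, , drop = FALSE],
    method = "spearman", use = "pairwise.complete.obs"
  )
  class(out) <- c("stage_cor", class(out))
  attr(out, "layers") <- c("protein_changes", "other_changes")
  out
}

#' @rdname lagged_change_correlation
#' @param m A square `"stage_cor"` matrix of transition correlations.
#' @param lag Offset: 0 = synchronized, 1 = RNA change one transition
#'   earlier, 2 = two earlier.
#' @return Named vector of the requested diagonal.
#' @export
lag_diagonal <- function(m, lag = 0) {
  n <- nrow(m)
  idx <- seq_len(n - lag) + lag
  stats::setNames(
    m[cbind(idx, idx - lag)],
    paste0(rownames(m)[idx], " vs ", colnames(m)[idx - lag])
  )
}

#' Segment intrinsically disordered regions from per-residue scores
#'
#' A residue is disordered when its prediction score exceeds `cutoff`; an
#' IDR is a maximal run of more than `min_len` consecutive disordered
#' residues. Coordinates are 1-based inclusive, so a qualifying run has
#' `end - start + 1 > min_len`.
#'
#' @param scores Numeric per-residue scores in \[0, 1\] (nonempty).
#' @param cutoff Disorder score threshold (strict >).
#' @param min_len Minimum run length (strict >; runs of exactly `min_len`
#'   do not qualify).
#' @return A tibble `start`, `end`, `length` with one row per IDR and the
#'   `"has_idr"` attribute.
#' @examples
#' idr_segments(c(rep(0, 9), rep(0.9, 31), rep(0, 60)))
#' @export
idr_segments <- function(scores, cutoff = 0.5, min_len = 30) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (any(is.na(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  r <- rle(scores > cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths > min_len
  out <- tibble::tibble(
    start = starts[keep], end = ends[keep],
    length = r$lengths[keep]
  )
  attr(out, "has_idr") <- nrow(out) > 0
  out
}

#' @rdname idr_segments
#' @param score_list Named list of per-residue score vectors (one protein
#'   each), as read by [read_disorder_scores()].
#' @return `idr_table()` returns one row per gene: `gene_id`, `n_idr`,
#'   `has_idr`, and the segments in a list-column.
#' @export
idr_table <- function(score_list, cutoff = 0.5, min_len = 30) {
  segs <- lapply(score_list, idr_segments, cutoff = cutoff, min_len = min_len)
  tibble::tibble(
    gene_id = names(score_list),
    n_idr = unname(vapply(segs, nrow, 0L)),
    has_idr = unname(vapply(segs, function(s) attr(s, "has_idr"), TRUE)),
    segments = unname(segs)
  )
}

#' Test association of a gene feature with group membership
#'
#' For a numeric per-gene feature (FGO protein level, half-life, ...)
#' grouped by concordance bin or trajectory group, runs two-tailed Wilcoxon
#' rank-sum tests for every group pair. For a binary feature (all values 0
#' or 1, e.g. IDR presence) a two-sided Fisher's exact test on the 2 x 2
#' contingency table is used instead. Groups with fewer than 2 members are
#' skipped with a warning.
#'
#' @param df Tibble with columns `value` (feature) and `group`.
#' @return Tibble with one row per group pair: `group1`, `group2`, `test`,
#'   `statistic` (rank-sum W or odds ratio), `p_value`.
#' @export
feature_association <- function(df) {
  df <- dplyr::filter(df, !is.na(.data$value), !is.na(.data$group))
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("skipping group(s) with < 2 members: ",
      paste(small, collapse = ", "),
      call. = FALSE
    )
    df <- dplyr::filter(df, !.data$group %in% small)
  }
  groups <- sort(unique(as.character(df$group)))
  if (length(groups) < 2) stop("need at least two testable groups", call. = FALSE)
  binary <- all(df$value %in% c(0, 1))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- df$value[df$group == pr[1]]
    b <- df$value[df$group == pr[2]]
    if (binary) {
      tab <- matrix(
        c(sum(a == 1), sum(a == 0), sum(b == 1), sum(b == 0)),
        nrow = 2
      )
      ft <- stats::fisher.test(tab)
      tibble::tibble(
        group1 = pr[1], group2 = pr[2], test = "fisher",
        statistic = unname(ft$estimate), p_value = ft$p.value
      )
    } else {
      wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = NULL)
      tibble::tibble(
        group1 = pr[1], group2 = pr[2], test = "wilcoxon",
        statistic = unname(wt$statistic), p_value = wt$p.value
      )
    }
  })
}
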