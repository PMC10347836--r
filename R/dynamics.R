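#' Coefficient of variation of a log2 expression series
#'
#' sd/mean with the sample standard deviation (n - 1 denominator). Used to
#' classify genes as dynamically or stably expressed across developmental
#' stages. Defined only for series with a positive mean (log2 intensities
#' and log2(FPKM + 1) values are positive after imputation).
#'
#' @param series Numeric vector of per-stage log2 values (>= 2 stages, no
#'   `NA`).
#' @return The coefficient of variation, a nonnegative scalar.
#' @examples
#' coefficient_of_variation(c(10, 10, 12, 12, 10, 10, 12))
#' @export
coefficient_of_variation <- function(series) {
  if (length(series) < 2) stop("need at least 2 stages", call. = FALSE)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  m <- mean(series)
  if (m <= 0) stop("CV undefined for nonpositive mean", call. = FALSE)
  stats::sd(series) / m
}

#' Classify genes as dynamically or stably expressed
#'
#' Computes the per-gene coefficient of variation of log2 values across
#' stages and labels genes with CV above `threshold` as dynamic. For FPKM
#' layers, only genes expressed (FPKM >= `expressed_fpkm`) at one or more
#' stages are eligible, and values are log2(x + 1) transformed first. For
#' the protein layer all genes are eligible and values are used as-is
#' (impute missing values first, see [impute_missing()]).
#'
#' @param x Stage-averaged long tibble (`gene_id`, `stage`, `value`).
#' @param layer `"protein_log2_ibaq"`, `"rpf_fpkm"` or `"mrna_fpkm"`;
#'   defaults to the tibble's `"layer"` attribute.
#' @param threshold CV above which a gene is called dynamic.
#' @param expressed_fpkm Minimum FPKM at >= 1 stage for RNA-layer
#'   eligibility.
#' @return A tibble of class `"dynamics_calls"` with `gene_id`, `cv`,
#'   `label` (`"dynamic"`/`"stable"`); the dynamic fraction among eligible
#'   genes is available via [glance()] or the `"fraction"` attribute.
#' @export
classify_dynamics <- function(x, layer = attr(x, "layer"), threshold = 0.2,
                              expressed_fpkm = 1) {
  if (is.null(layer)) stop("specify `layer`", call. = FALSE)
  if (layer %in% c("rpf_fpkm", "mrna_fpkm")) {
    eligible <- x |>
      dplyr::summarise(
        ok = any(!is.na(.data$value) & .data$value >= expressed_fpkm),
        .by = "gene_id"
      )
    x <- x |>
      dplyr::semi_join(dplyr::filter(eligible, .data$ok), by = "gene_id") |>
      dplyr::mutate(value = log2(.data$value + 1))
  }
  if (nrow(x) == 0) stop("no eligible genes", call. = FALSE)
  if (anyNA(x$value)) {
    stop("missing values present; impute before classifying", call. = FALSE)
  }
  out <- x |>
    dplyr::summarise(cv = coefficient_of_variation(.data$value), .by = "gene_id") |>
    dplyr::mutate(label = ifelse(.data$cv > threshold, "dynamic", "stable"))
  attr(out, "fraction") <- mean(out$label == "dynamic")
  attr(out, "threshold") <- threshold
  attr(out, "layer") <- layer
  class(out) <- c("dynamics_calls", class(out))
  out
}

#' Cluster protein trajectories by shape
#'
#' Per-gene z-scored trajectories are clustered with Euclidean K-means,
#' keeping the best of `restarts` random initializations by total
#' within-cluster sum of squares. Genes with zero across-stage variance get
#' an all-zero z-score profile. Deterministic given `seed`.
#'
#' @param x Stage-averaged long tibble with no missing values (impute
#'   first).
#' @param k Number of clusters.
#' @param restarts Random initializations (`nstart`).
#' @param seed Seed for the initialization stream.
#' @return A tibble of class `"cluster_assignments"` (`gene_id`,
#'   `cluster`), with attributes `"centers"` (k x stages matrix of z-score
#'   centroids), `"tot_withinss"`, `"seed"`.
#' @export
cluster_trajectories <- function(x, k = 10, restarts = 100, seed = 1) {
  stages <- levels(factor(x$stage))
  if (is.factor(x$stage)) stages <- levels(x$stage)
  m <- stage_value_matrix(x, stages)
  if (anyNA(m)) stop("missing values present; impute first", call. = FALSE)
  if (k > nrow(m)) stop("k exceeds the number of genes", call. = FALSE)
  z <- t(apply(m, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  colnames(z) <- stages
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = restarts, iter.max = 100)
  out <- tibble::tibble(gene_id = rownames(m), cluster = unname(km$cluster))
  attr(out, "centers") <- km$centers
  attr(out, "tot_withinss") <- km$tot.withinss
  attr(out, "seed") <- seed
  class(out) <- c("cluster_assignments", class(out))
  out
}

#' Merge K-means clusters into trajectory groups
#'
#' Reduces the k clusters to named trajectory groups. With an explicit
#' `mapping` (named vector, `"<cluster>" -> "<group>"`) every cluster must
#' be covered. Without one, an automated rule merges "embryonic" clusters:
#' clusters whose mean log2 trajectory stays below the detection floor
#' through the 2C stage and rises above it afterwards are merged into one
#' `"embryonic"` group; remaining clusters keep `"cluster_<i>"` labels for
#' manual annotation.
#'
#' @param assignments A `"cluster_assignments"` tibble.
#' @param mapping Optional named character vector from cluster id to group
#'   label.
#' @param profiles Stage-averaged long tibble of the clustered (imputed)
#'   log2 values; required for the automated rule.
#' @param floor Detection floor (log2) for the automated rule; defaults to
#'   the `"impute_floor"` attribute of `profiles` plus the imputation
#'   offset.
#' @param pre_zga_stages Stages regarded as "through 2C" by the rule.
#' @return `assignments` with an added `group_label` column.
#' @export
merge_to_groups <- function(assignments, mapping = NULL, profiles = NULL,
                            floor = NULL,
                            pre_zga_stages = c("FGO", "MII", "1C", "2C")) {
  if (!is.null(mapping)) {
    uncovered <- setdiff(unique(assignments$cluster), names(mapping))
    if (length(uncovered) > 0) {
      stop("mapping does not cover cluster(s): ",
        paste(uncovered, collapse = ", "),
        call. = FALSE
      )
    }
    assignments$group_label <- unname(mapping[as.character(assignments$cluster)])
    return(assignments)
  }
  if (is.null(profiles)) {
    stop("supply `mapping` or `profiles` for the automated rule", call. = FALSE)
  }
  if (is.null(floor)) {
    fl <- attr(profiles, "impute_floor")
    if (is.null(fl)) {
      stop("supply `floor` (profiles carry no impute_floor attribute)",
        call. = FALSE
      )
    }
    floor <- fl + 1 # at/near the imputation value means "not detected"
  }
  means <- profiles |>
    dplyr::inner_join(assignments, by = "gene_id") |>
    dplyr::summarise(m = mean(.data$value), .by = c("cluster", "stage"))
  is_embryonic <- means |>
    dplyr::summarise(
      embryonic = all(.data$m[.data$stage %in% pre_zga_stages] <= floor) &&
        any(.data$m[!.data$stage %in% pre_zga_stages] > floor),
      .by = "cluster"
    )
  emb <- is_embryonic$cluster[is_embryonic$embryonic]
  assignments$group_label <- ifelse(
    assignments$cluster %in% emb, "embryonic",
    paste0("cluster_", assignments$cluster)
  )
  assignments
}

#' Stage-by-stage correlation matrix between two layers
#'
#' Entry (i, j) is the correlation across the shared gene universe between
#' layer `a` at stage i and layer `b` at stage j. Spearman rank correlation
#' by default, so the matrix is invariant to monotone transforms of either
#' layer.
#'
#' @param a,b Stage-averaged long tibbles (no missing values for the genes
#'   used; rows with `NA` at a stage are dropped pairwise via complete
#'   observations).
#' @param method Correlation method (passed to [stats::cor()]).
#' @return A stages(a) x stages(b) matrix of class `"stage_cor"`.
#' @export
stage_correlation_matrix <- function(a, b = a, method = "spearman") {
  stages_a <- if (is.factor(a$stage)) levels(a$stage) else unique(a$stage)
  stages_b <- if (is.factor(b$stage)) levels(b$stage) else unique(b$stage)
  ma <- stage_value_matrix(a, stages_a)
  mb <- stage_value_matrix(b, stages_b)
  genes <- intersect(rownames(ma), rownames(mb))
  if (length(genes) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  out <- stats::cor(ma[genes, , drop = FALSE], mb[genes, , drop = FALSE],
    method = method, use = "pairwise.complete.obs"
  )
  class(out) <- c("stage_cor", class(out))
  attr(out, "layers") <- c(attr(a, "layer") %||% "a", attr(b, "layer") %||% "b")
  out
}
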