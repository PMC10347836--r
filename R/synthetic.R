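#' Configuration for the synthetic study generator
#'
#' Defines the conditions emulated by [generate_bundle()]: seven ordered
#' stages with the three-batch proteome design of [oet_batch_design()],
#' gene classes with characteristic translation/transcription templates and
#' kinetic parameters, additive log2 batch offsets anchored on FGO,
#' log-normal measurement noise, and a hard detection floor on log2
#' intensity emulating LC-MS/MS dropout.
#'
#' Class proportions default to a constitutive-dominated mixture (four
#' constitutive subgroups distinguished by their RPF dynamics, maternal,
#' OET down- and up-regulated, embryonic, lowly expressed), mirroring the
#' trajectory classes seen across the oocyte-to-embryo transition. Gene
#' counts per class are apportioned deterministically by largest remainder,
#' so realized counts match the proportions within one gene per class.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric vector over the nine gene
#'   classes; must sum to 1 (tolerance 1e-9).
#' @param noise_sd Log2-scale standard deviation of replicate measurement
#'   noise (applied multiplicatively on the linear scale); >= 0.
#' @param batch_offsets Named additive log2 offsets per proteome batch;
#'   the reference batch must have offset 0.
#' @param detection_floor Log2 intensity below which protein measurements
#'   are masked as not detected.
#' @param times Stage time coordinates (see [oet_stage_times()]).
#' @param n_undetected_rna Number of `low`-class genes planted with
#'   all-zero RPF and mRNA (never detected in either RNA layer).
#' @param ase_counts Named counts of genes planted per allele-specific
#'   expression category in the allele table.
#' @param seed Master seed; per-layer streams are derived from it so layers
#'   are reproducible independently.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 400,
                       class_proportions = c(
                         constitutive_rpf_constitutive = 0.13,
                         constitutive_rpf_oet_down = 0.10,
                         constitutive_rpf_low = 0.09,
                         constitutive_rpf_maternal = 0.08,
                         maternal = 0.08,
                         oet_down = 0.12,
                         oet_up = 0.06,
                         embryonic = 0.24,
                         low = 0.10
                       ),
                       noise_sd = 0.1,
                       batch_offsets = c(batch1 = 0, batch2 = 0.7, batch3 = -0.4),
                       detection_floor = 10,
                       times = oet_stage_times(),
                       n_undetected_rna = max(0L, round(0.0075 * n_genes)),
                       ase_counts = c(
                         oocyte_specific = max(1, round(0.015 * n_genes)),
                         oocyte_embryonic = max(1, round(0.010 * n_genes)),
                         embryonic_maternal = max(1, round(0.005 * n_genes)),
                         embryonic_paternal = max(1, round(0.005 * n_genes)),
                         none = max(1, round(0.015 * n_genes))
                       ),
                       seed = 1) {
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (any(class_proportions < 0)) {
    stop("class proportions must be nonnegative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (is.null(names(batch_offsets)) || batch_offsets[1] != 0) {
    stop("batch_offsets must be named with reference offset 0 first",
      call. = FALSE
    )
  }
  structure(
    list(
      n_genes = n_genes, class_proportions = class_proportions,
      noise_sd = noise_sd, batch_offsets = batch_offsets,
      detection_floor = detection_floor, times = times,
      n_undetected_rna = n_undetected_rna, ase_counts = ase_counts,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# class archetypes: FPKM templates over the 7 stages plus log-uniform
# sampling ranges for the kinetic parameters (p0 linear scale, alpha and kd
# per stage-unit). Templates encode the class-defining monotonicity; kinetic
# ranges are chosen so the forward-simulated protein matches the class shape.
class_archetypes <- function() {
  list(
    constitutive_rpf_constitutive = list(
      rpf = c(50, 45, 40, 45, 50, 55, 60),
      mrna = c(50, 48, 45, 40, 45, 50, 55),
      p0 = c(2e4, 2e6), alpha = c(20, 200), kd = c(0.05, 0.3)
    ),
    constitutive_rpf_oet_down = list(
      rpf = c(50, 10, 5, 5, 20, 40, 50),
      mrna = c(50, 45, 20, 10, 25, 45, 55),
      p0 = c(2e4, 2e6), alpha = c(20, 200), kd = c(0.05, 0.2)
    ),
    constitutive_rpf_low = list(
      rpf = c(2, 2, 1.5, 1.5, 2, 2, 2.5),
      mrna = c(3, 3, 2, 2, 2.5, 3, 3),
      p0 = c(2e4, 2e6), alpha = c(50, 500), kd = c(0.05, 0.15)
    ),
    constitutive_rpf_maternal = list(
      rpf = c(50, 50, 40, 25, 2, 1.5, 1),
      mrna = c(50, 40, 30, 12, 2, 1, 1),
      p0 = c(2e4, 2e6), alpha = c(20, 200), kd = c(0.05, 0.2)
    ),
    maternal = list(
      rpf = c(60, 55, 25, 8, 2, 1, 0.5),
      mrna = c(60, 45, 20, 5, 1, 0.5, 0.5),
      p0 = c(1e4, 1e6), alpha = c(50, 300), kd = c(0.15, 0.4)
    ),
    oet_down = list(
      rpf = c(40, 8, 4, 4, 5, 8, 70),
      mrna = c(40, 30, 10, 5, 8, 15, 70),
      p0 = c(1e4, 1e6), alpha = c(300, 2000), kd = c(1.0, 2.5)
    ),
    oet_up = list(
      rpf = c(4, 60, 60, 45, 25, 15, 10),
      mrna = c(45, 40, 35, 25, 18, 12, 10),
      p0 = c(500, 3e3), alpha = c(200, 1000), kd = c(0.3, 0.8)
    ),
    embryonic = list(
      rpf = c(0, 0, 0, 1, 3, 10, 80),
      mrna = c(0, 0, 2, 6, 15, 40, 85),
      p0 = c(50, 300), alpha = c(15, 400), kd = c(0.05, 0.3)
    ),
    low = list(
      rpf = c(0.3, 0.3, 0.2, 0.2, 0.3, 0.3, 0.4),
      mrna = c(0.4, 0.4, 0.3, 0.3, 0.3, 0.4, 0.5),
      p0 = c(10, 200), alpha = c(1, 10), kd = c(0.05, 0.5)
    )
  )
}

# deterministic largest-remainder apportionment of n among proportions
apportion_counts <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Generate a synthetic multi-layer study bundle with known ground truth
#'
#' Draws per-gene kinetic parameters (p0, alpha, kd) and class templates,
#' forward-simulates protein trajectories through [simulate_protein()] with
#' the gene's RPF template as translation input, log2-transforms them, adds
#' replicate-level log-normal noise and per-batch additive log2 offsets
#' (anchored so the reference batch is unshifted), and masks values below
#' the detection floor as missing. RPF and mRNA layers are class-templated
#' FPKM values with multiplicative noise over two replicates. An
#' allele-resolved intensity table with planted allele-specific-expression
#' categories and per-gene per-residue disorder scores (with planted
#' disordered regions) complete the bundle. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `"oet_bundle"` with elements `protein`, `rpf`,
#'   `mrna` (long replicate-level tibbles), `protein_true` (noiseless,
#'   unbatched, unfloored log2 stage matrix), `allele`, `disorder`,
#'   `truth` (per-gene [truth_report()] table), `config`.
#' @export
generate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  arch <- class_archetypes()
  counts <- apportion_counts(config$n_genes, config$class_proportions)
  classes <- rep(names(counts), counts)
  n <- length(classes)
  gene_ids <- sprintf("gene%04d", seq_len(n))
  times <- unname(config$times)
  stages <- names(config$times)

  # --- truth: kinetic parameters and templates per gene -------------------
  set.seed(config$seed)
  runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  truth <- purrr::map2_dfr(gene_ids, classes, function(g, cl) {
    a <- arch[[cl]]
    tibble::tibble(
      gene_id = g, class_label = cl,
      p0 = runif_log(1, a$p0),
      alpha = runif_log(1, a$alpha),
      kd = runif_log(1, a$kd),
      rpf_template = list(a$rpf),
      mrna_template = list(a$mrna),
      rna_undetected = FALSE
    )
  })
  if (config$n_undetected_rna > 0) {
    low_idx <- which(truth$class_label == "low")
    pick <- utils::head(low_idx, config$n_undetected_rna)
    if (length(pick) < config$n_undetected_rna) {
      stop("not enough `low`-class genes to plant RNA-undetected genes",
        call. = FALSE
      )
    }
    truth$rna_undetected[pick] <- TRUE
    truth$rpf_template[pick] <- list(rep(0, length(stages)))
    truth$mrna_template[pick] <- list(rep(0, length(stages)))
    truth$alpha[pick] <- 0 # nothing translated, nothing synthesized
  }

  # --- noiseless protein truth (log2 gene x stage) ------------------------
  p_lin <- t(vapply(seq_len(n), function(i) {
    simulate_protein(
      truth$p0[i], truth$alpha[i], truth$kd[i],
      times, truth$rpf_template[[i]]
    )
  }, numeric(length(stages))))
  protein_true <- log2(pmax(p_lin, 2^-20)) # guard log2(0) for alpha=p0=0 genes
  dimnames(protein_true) <- list(gene_ids, stages)

  # --- protein layer: replicates, noise, batch offsets, floor -------------
  design <- oet_batch_design()
  set.seed(derive_seed(config$seed, 1L))
  protein <- purrr::pmap_dfr(design, function(stage, replicate, batch) {
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(n, 0, config$noise_sd)
    } else {
      numeric(n)
    }
    vals <- unname(protein_true[, stage]) + noise + config$batch_offsets[[batch]]
    tibble::tibble(
      gene_id = gene_ids, stage = stage, replicate = replicate,
      batch = batch, value = vals
    )
  })
  protein$value[protein$value < config$detection_floor] <- NA_real_
  protein$stage <- check_stages(protein$stage, stages)
  protein <- dplyr::arrange(protein, .data$gene_id, .data$stage, .data$replicate)
  attr(protein, "layer") <- "protein_log2_ibaq"

  # --- RNA layers: templated FPKM with multiplicative noise, 2 reps -------
  make_rna <- function(templates, stream, layer) {
    set.seed(derive_seed(config$seed, stream))
    tmpl <- do.call(rbind, templates)
    out <- purrr::map_dfr(1:2, function(rep_i) {
      noise <- if (config$noise_sd > 0) {
        matrix(2^stats::rnorm(n * length(stages), 0, config$noise_sd),
          nrow = n
        )
      } else {
        matrix(1, n, length(stages))
      }
      vals <- tmpl * noise
      tibble::tibble(
        gene_id = rep(gene_ids, times = length(stages)),
        stage = rep(stages, each = n),
        replicate = rep_i,
        value = as.vector(vals)
      )
    })
    out$stage <- check_stages(out$stage, stages)
    out <- dplyr::arrange(out, .data$gene_id, .data$stage, .data$replicate)
    attr(out, "layer") <- layer
    out
  }
  rpf <- make_rna(truth$rpf_template, 2L, "rpf_fpkm")
  mrna <- make_rna(truth$mrna_template, 3L, "mrna_fpkm")

  # --- allele table with planted ASE categories ---------------------------
  set.seed(derive_seed(config$seed, 4L))
  allele <- simulate_allele_table(truth, protein_true, stages, config)
  truth <- dplyr::left_join(
    truth,
    dplyr::distinct(allele$truth, .data$gene_id, .data$ase_category),
    by = "gene_id"
  )

  # --- disorder scores with planted IDRs ----------------------------------
  set.seed(derive_seed(config$seed, 5L))
  disorder <- simulate_disorder_scores(truth)

  structure(
    list(
      protein = protein, rpf = rpf, mrna = mrna,
      protein_true = protein_true,
      allele = allele$table, allele_truth = allele$truth,
      disorder = disorder$scores,
      truth = dplyr::left_join(truth, disorder$truth, by = "gene_id"),
      config = config
    ),
    class = "oet_bundle"
  )
}

# sub-seed derivation keeps every stream reproducible independently and
# below .Machine$integer.max
derive_seed <- function(master, stream) {
  (as.integer(master) * 1000L + stream * 7L) %% 2147483647L
}

# allele-resolved intensities for a subset of genes; categories are planted
# by detection pattern: maternal-only everywhere (oocyte_specific), paternal
# appearing at BL (oocyte_embryonic), embryo-only single-allele signal
# (embryonic_maternal / embryonic_paternal), balanced biallelic (none)
simulate_allele_table <- function(truth, protein_true, stages, config) {
  pools <- list(
    oocyte_specific = "maternal",
    oocyte_embryonic = "constitutive_rpf_constitutive",
    embryonic_maternal = "embryonic",
    embryonic_paternal = "embryonic",
    none = "constitutive_rpf_constitutive"
  )
  used <- character(0)
  picks <- purrr::imap_dfr(config$ase_counts, function(k, cat) {
    if (k == 0) return(NULL)
    cand <- setdiff(truth$gene_id[truth$class_label == pools[[cat]]], used)
    if (length(cand) < k) {
      stop("not enough genes of class ", pools[[cat]],
        " to plant ASE category ", cat,
        call. = FALSE
      )
    }
    g <- utils::head(cand, k)
    used <<- c(used, g)
    tibble::tibble(gene_id = g, ase_category = cat)
  })
  floor_log2 <- config$detection_floor
  oocyte <- c("FGO", "MII")
  embryo_late <- c("8C", "BL")
  rows <- purrr::pmap_dfr(picks, function(gene_id, ase_category) {
    base <- protein_true[gene_id, ] - 1 # each allele ~ half the total
    mat <- base
    pat <- base
    if (ase_category == "oocyte_specific") {
      mat <- pmax(mat, floor_log2 + 4)
      pat[] <- NA_real_
    } else if (ase_category == "oocyte_embryonic") {
      pat[setdiff(stages, "BL")] <- NA_real_
      pat["BL"] <- max(base["BL"], floor_log2 + 4)
      mat <- pmax(mat, floor_log2 + 4) # clearly maternal-dominant pre-BL
    } else if (ase_category == "embryonic_maternal") {
      mat[] <- NA_real_
      mat[embryo_late] <- floor_log2 + 4
      pat[] <- NA_real_
    } else if (ase_category == "embryonic_paternal") {
      pat[] <- NA_real_
      pat[embryo_late] <- floor_log2 + 4
      mat[] <- NA_real_
    } else {
      mat <- pmax(mat, floor_log2 + 2)
      pat <- mat # balanced biallelic
    }
    purrr::map_dfr(1:2, function(rep_i) {
      jitter <- function(v) {
        out <- v + stats::rnorm(length(v), 0, config$noise_sd)
        out[is.na(v)] <- NA_real_
        out
      }
      tibble::tibble(
        gene_id = gene_id,
        stage = rep(stages, 2),
        replicate = rep_i,
        allele = rep(c("maternal", "paternal"), each = length(stages)),
        value = c(jitter(mat), jitter(pat))
      )
    })
  })
  rows$value[!is.na(rows$value) & rows$value < floor_log2] <- NA_real_
  rows$stage <- check_stages(rows$stage, stages)
  list(table = rows, truth = picks)
}

# per-residue disorder scores; roughly half the genes in non-low classes get
# one planted disordered run (length 40-80, scores > 0.5)
simulate_disorder_scores <- function(truth) {
  scores <- vector("list", nrow(truth))
  has_idr <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    len <- sample(120:400, 1)
    s <- stats::runif(len, 0, 0.45)
    if (truth$class_label[i] != "low" && stats::runif(1) < 0.5) {
      run <- sample(40:80, 1)
      start <- sample(seq_len(len - run + 1), 1)
      s[start:(start + run - 1)] <- stats::runif(run, 0.55, 1)
      has_idr[i] <- TRUE
    }
    scores[[i]] <- round(s, 4)
  }
  names(scores) <- truth$gene_id
  list(scores = scores, truth = tibble::tibble(
    gene_id = truth$gene_id,
    has_idr_truth = has_idr
  ))
}

#' Per-gene ground-truth table of a synthetic bundle
#'
#' @param bundle An `"oet_bundle"` from [generate_bundle()].
#' @return One row per gene: class label, kinetic parameters (p0, alpha,
#'   kd), whether the gene was planted as RNA-undetected, its planted
#'   allele-specific-expression category (`NA` if not in the allele table)
#'   and whether a disordered region was planted.
#' @export
truth_report <- function(bundle) {
  stopifnot(inherits(bundle, "oet_bundle"))
  dplyr::select(
    bundle$truth, "gene_id", "class_label", "p0", "alpha", "kd",
    "rna_undetected", "ase_category", "has_idr_truth"
  )
}

#' Write a bundle to disk in the pipeline's TSV dialect
#'
#' Writes `protein.tsv`, `rpf.tsv`, `mrna.tsv` (replicate-level, empty cell
#' = not detected), `allele.tsv`, `truth.tsv`, `disorder.txt` and
#' `config.yaml` into `dir`.
#'
#' @param bundle An `"oet_bundle"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "oet_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics(bundle$protein, file.path(dir, "protein.tsv"))
  write_omics(bundle$rpf, file.path(dir, "rpf.tsv"))
  write_omics(bundle$mrna, file.path(dir, "mrna.tsv"))
  readr::write_tsv(bundle$allele, file.path(dir, "allele.tsv"), na = "",
    progress = FALSE
  )
  readr::write_tsv(
    dplyr::select(truth_report(bundle), -dplyr::any_of(c())),
    file.path(dir, "truth.tsv"),
    na = "", progress = FALSE
  )
  write_disorder_scores(bundle$disorder, file.path(dir, "disorder.txt"))
  cfg <- bundle$config
  yaml::write_yaml(
    list(
      n_genes = cfg$n_genes,
      class_proportions = as.list(cfg$class_proportions),
      noise_sd = cfg$noise_sd,
      batch_offsets = as.list(cfg$batch_offsets),
      detection_floor = cfg$detection_floor,
      times = as.list(cfg$times),
      n_undetected_rna = cfg$n_undetected_rna,
      ase_counts = as.list(cfg$ase_counts),
      seed = cfg$seed
    ),
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}
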