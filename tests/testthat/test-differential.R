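test_that("dep_call matches a hand-computed t-test and fold rule", {
  none <- dep_call(c(10.0, 10.2), c(10.0, 10.2))
  expect_equal(none$direction, "none")
  a <- c(10.0, 10.1)
  b <- c(13.0, 13.1)
  up <- dep_call(a, b)
  expect_equal(up$log2_fc, 3)
  expect_equal(up$p_value, t_test_oracle(b, a))
  expect_equal(up$direction, "up")
  dn <- dep_call(b, a)
  expect_equal(dn$log2_fc, -3)
  expect_equal(dn$direction, "down")
})

test_that("degenerate zero-variance groups follow the documented convention", {
  same <- dep_call(c(10, 10), c(10, 10))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  diff <- dep_call(c(10, 10), c(13, 13))
  expect_equal(diff$p_value, 0)
  expect_equal(diff$direction, "up")
  expect_error(dep_call(c(10), c(11, 12)), "2 detected replicates")
})

test_that("DEP counts shrink as thresholds tighten", {
  b <- generate_bundle(sim_config(n_genes = 120, seed = 13))
  prot <- apply_batch_correction(b$protein, compute_batch_factors(b$protein))
  n_de <- function(fc, p) {
    sum(glance(dep_table(prot, fc_log2 = fc, p_threshold = p))$n_de)
  }
  expect_gte(n_de(1, 0.05), n_de(2, 0.05))
  expect_gte(n_de(1, 0.05), n_de(1, 0.01))
})

test_that("protein changes are attributed across the lag window", {
  trans <- stage_transitions()
  lv <- function(x) factor(x, levels = trans)
  deps <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    transition = lv(rep("4C->8C", 3)),
    log2_fc = c(2, 2, 2), p_value = 0.01, direction = "up"
  )
  class(deps) <- c("dep_table", class(deps))
  zero_changes <- tidyr::expand_grid(
    gene_id = c("g1", "g2", "g3"), transition = lv(trans)
  ) |>
    dplyr::mutate(change = 0)
  # g1: mRNA up 2.5-fold two transitions earlier -> mrna_contributed
  mrna <- dplyr::mutate(zero_changes, change = ifelse(
    gene_id == "g1" & transition == "1C->2C", log2(2.5), change
  ))
  # g2: RPF up 3-fold at the current transition -> rpf_only
  rpf <- dplyr::mutate(zero_changes, change = ifelse(
    gene_id == "g2" & transition == "4C->8C", log2(3), change
  ))
  att <- attribute_changes(deps, rpf, mrna, lag = 2)
  expect_equal(att$category[att$gene_id == "g1"], "mrna_contributed")
  expect_equal(att$category[att$gene_id == "g2"], "rpf_only")
  expect_equal(att$category[att$gene_id == "g3"], "unexplained")
  fr <- attr(att, "fractions")
  expect_equal(sum(fr$fraction), 1)
})

test_that("opposite-direction RNA changes do not count as contributing", {
  trans <- stage_transitions()
  lv <- function(x) factor(x, levels = trans)
  deps <- tibble::tibble(
    gene_id = "g1", transition = lv("4C->8C"),
    log2_fc = 2, p_value = 0.01, direction = "up"
  )
  class(deps) <- c("dep_table", class(deps))
  base <- tidyr::expand_grid(gene_id = "g1", transition = lv(trans)) |>
    dplyr::mutate(change = 0)
  mrna_down <- dplyr::mutate(base, change = ifelse(
    transition == "4C->8C", -2, change
  ))
  att <- attribute_changes(deps, base, mrna_down, lag = 2)
  expect_equal(att$category, "unexplained")
})

test_that("changes outside the two-transition window are ignored", {
  trans <- stage_transitions()
  lv <- function(x) factor(x, levels = trans)
  deps <- tibble::tibble(
    gene_id = "g1", transition = lv("4C->8C"),
    log2_fc = 2, p_value = 0.01, direction = "up"
  )
  class(deps) <- c("dep_table", class(deps))
  base <- tidyr::expand_grid(gene_id = "g1", transition = lv(trans)) |>
    dplyr::mutate(change = 0)
  # mRNA change three transitions before the DEP: outside the window
  mrna_early <- dplyr::mutate(base, change = ifelse(
    transition == "MII->1C", 3, change
  ))
  att <- attribute_changes(deps, base, mrna_early, lag = 2)
  expect_equal(att$category, "unexplained")
})

test_that("FGO-originated proteins follow the strict RPF bound", {
  stages <- oet_stages()
  prot <- matrix(
    c(
      15, 14, 14, 13, 13, 12, 12, # g1: detected throughout
      15, 14, 13, NA, NA, NA, NA, # g2: lost before blastocyst
      15, 14, 14, 13, 13, 12, 12, # g3: translated at 4C
      NA, NA, NA, NA, 12, 13, 14 # g4: not an FGO protein
    ),
    4, 7,
    byrow = TRUE, dimnames = list(sprintf("g%d", 1:4), stages)
  )
  rpf <- matrix(
    c(
      50, 40, 0, 1, 2, 3, 4,
      50, 40, 4, 4, 4, 4, 4,
      50, 40, 1, 1, 6, 1, 1, # 6 at 4C breaks the < 5 rule
      0, 0, 10, 20, 30, 40, 50
    ),
    4, 7,
    byrow = TRUE, dimnames = list(sprintf("g%d", 1:4), stages)
  )
  res <- fgo_originated(avg_tbl(prot), avg_tbl(rpf))
  expect_setequal(res$gene_id, c("g1", "g2"))
  expect_true(res$persists[res$gene_id == "g1"])
  expect_false(res$persists[res$gene_id == "g2"])
  expect_equal(attr(res, "persistence_fraction"), 0.5)
})

test_that("planted low-translation genes are recovered as FGO-originated", {
  b <- generate_bundle(quiet_config(n_genes = 200, seed = 27))
  tr <- b$truth
  res <- fgo_originated(merge_replicates(b$protein), merge_replicates(b$rpf))
  expected <- tr$gene_id[
    vapply(tr$rpf_template, function(v) max(v[3:7]) < 5, TRUE) &
      !is.na(b$protein_true[tr$gene_id, "FGO"]) &
      2^b$protein_true[tr$gene_id, "FGO"] > 0
  ]
  # with no detection floor every gene's FGO value is observed, so the
  # expected set is exactly the genes with low post-fertilization templates
  expect_setequal(res$gene_id, expected)
  expect_true(all(tr$class_label[match(res$gene_id, tr$gene_id)] %in%
    c("constitutive_rpf_low", "low")))
})

test_that("CHX response calls planted newly synthesized proteins", {
  set.seed(3)
  n <- 60
  genes <- sprintf("g%02d", 1:n)
  repressed_truth <- genes[1:20] # 8-fold lower under CHX
  base <- rnorm(n, 15, 1)
  rows <- purrr::map_dfr(1:2, function(rep_i) {
    tibble::tibble(
      gene_id = rep(genes, 2),
      condition = rep(c("DMSO", "CHX"), each = n),
      replicate = rep_i,
      value = c(base, base - ifelse(genes %in% repressed_truth, 3, 0)) +
        rnorm(2 * n, 0, 0.05)
    )
  })
  res <- chx_response(rows)
  expect_setequal(res$gene_id[res$status == "repressed"], repressed_truth)
  # a two-fold drop stays below the four-fold rule
  two_fold <- purrr::map_dfr(1:2, function(rep_i) {
    tibble::tibble(
      gene_id = "g", condition = c("DMSO", "CHX"), replicate = rep_i,
      value = c(15, 14) + c(0.01, -0.01) * rep_i
    )
  })
  expect_equal(chx_response(two_fold)$status, "unaffected")
  # identical conditions: nothing repressed
  same <- purrr::map_dfr(1:2, function(rep_i) {
    tibble::tibble(
      gene_id = rep(genes, 2), condition = rep(c("DMSO", "CHX"), each = n),
      replicate = rep_i, value = rep(base, 2) + rnorm(2 * n, 0, 0.01)
    )
  })
  expect_false(any(chx_response(same)$status == "repressed"))
})

test_that("overlap enrichment equals the hypergeometric oracle", {
  universe <- sprintf("g%03d", 1:40)
  set_a <- universe[1:20]
  set_b <- universe[1:20] # perfectly nested split
  res <- overlap_enrichment(set_a, set_b, universe)
  expect_equal(res$overlap, 20)
  expect_equal(res$overlap_fraction, 1)
  expect_equal(res$p_value, fisher_oracle(20, 20, 20, 40), tolerance = 1e-9)
  # disjoint covering sets: overlap 0
  res0 <- overlap_enrichment(universe[1:20], universe[21:40], universe)
  expect_equal(res0$overlap, 0)
  # partial overlap against the oracle
  res2 <- overlap_enrichment(universe[1:15], universe[10:30], universe)
  expect_equal(res2$overlap, 6)
  expect_equal(res2$p_value, fisher_oracle(6, 15, 21, 40), tolerance = 1e-9)
  expect_error(overlap_enrichment("x", set_b, universe), "subsets")
})

test_that("independent random sets give odds ratios near one on average", {
  set.seed(11)
  universe <- sprintf("g%03d", 1:200)
  ors <- replicate(30, {
    a <- sample(universe, 60)
    b <- sample(universe, 60)
    overlap_enrichment(a, b, universe)$odds_ratio
  })
  expect_gt(mean(log(ors)), -0.3)
  expect_lt(mean(log(ors)), 0.3)
})

test_that("dormant mRNAs require translation gain without mRNA gain", {
  stages <- oet_stages()
  mk <- function(fgo, mii) {
    m <- matrix(rep(c(fgo, mii, 1, 1, 1, 1, 1), each = 1), 1, 7,
      dimnames = list("g1", stages)
    )
    avg_tbl(m)
  }
  expect_equal(dormant_mrna_set(mk(10, 30), mk(50, 50)), "g1")
  # mRNA ratio 2.5 disqualifies
  expect_length(dormant_mrna_set(mk(10, 30), mk(20, 50)), 0)
  # RPF ratio exactly at threshold is not dormant (strict >)
  expect_length(dormant_mrna_set(mk(10, 20.05), mk(50, 50)), 0)
})

test_that("the planted dormant class is recovered exactly at zero noise", {
  b <- generate_bundle(quiet_config(n_genes = 150, seed = 37))
  tr <- b$truth
  dor <- dormant_mrna_set(merge_replicates(b$rpf), merge_replicates(b$mrna))
  expect_setequal(dor, tr$gene_id[tr$class_label == "oet_up"])
})
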