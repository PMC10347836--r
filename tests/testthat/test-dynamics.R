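test_that("coefficient of variation matches the direct formula", {
  expect_equal(coefficient_of_variation(rep(8, 7)), 0)
  s <- c(10, 10, 12, 12, 10, 10, 12)
  expect_equal(coefficient_of_variation(s), sd(s) / mean(s))
  # scale invariance
  expect_equal(coefficient_of_variation(3 * s), coefficient_of_variation(s))
  expect_error(coefficient_of_variation(c(1)), "2 stages")
  expect_error(coefficient_of_variation(c(-5, 1, 2)), "nonpositive")
})

test_that("dynamics classification recovers a planted dynamic fraction", {
  stages <- oet_stages()
  # 40 genes: 16 planted dynamic (CV > 0.2), 24 flat
  dyn <- t(sapply(1:16, function(i) 10 + c(0, 8, 0, 8, 0, 8, 0)))
  flat <- t(sapply(1:24, function(i) 10 + 0.01 * seq_len(7)))
  m <- rbind(dyn, flat)
  rownames(m) <- sprintf("g%02d", 1:40)
  colnames(m) <- stages
  calls <- classify_dynamics(avg_tbl(m), layer = "protein_log2_ibaq")
  expect_equal(attr(calls, "fraction"), 0.4)
  expect_equal(glance(calls)$n_dynamic, 16)
  # all-constant matrix: fraction 0
  flat_only <- classify_dynamics(avg_tbl(m * 0 + 10),
    layer = "protein_log2_ibaq"
  )
  expect_equal(attr(flat_only, "fraction"), 0)
})

test_that("dynamic fraction is monotone nonincreasing in the threshold", {
  b <- generate_bundle(sim_config(n_genes = 100, seed = 6))
  m <- impute_missing(merge_replicates(
    apply_batch_correction(b$protein, compute_batch_factors(b$protein))
  ))
  fracs <- vapply(
    c(0.05, 0.1, 0.2, 0.4, 0.8),
    function(th) attr(classify_dynamics(m, "protein_log2_ibaq", th), "fraction"),
    0
  )
  expect_true(all(diff(fracs) <= 0))
})

test_that("RNA layers apply the expression filter before CV", {
  m <- rbind(
    g1 = c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2, 0.1), # never reaches FPKM 1
    g2 = c(5, 50, 5, 50, 5, 50, 5)
  )
  colnames(m) <- oet_stages()
  calls <- classify_dynamics(avg_tbl(m), layer = "rpf_fpkm")
  expect_equal(calls$gene_id, "g2")
  expect_equal(calls$label, "dynamic")
})

test_that("clustering recovers two planted trajectory archetypes", {
  stages <- oet_stages()
  set.seed(2)
  up <- t(sapply(1:30, function(i) c(1, 2, 3, 4, 5, 6, 7) + rnorm(7, 0, 0.05)))
  down <- t(sapply(1:30, function(i) c(7, 6, 5, 4, 3, 2, 1) + rnorm(7, 0, 0.05)))
  m <- rbind(up, down)
  rownames(m) <- sprintf("g%02d", 1:60)
  colnames(m) <- stages
  cl <- cluster_trajectories(avg_tbl(m), k = 2, restarts = 10, seed = 4)
  truth <- rep(1:2, each = 30)
  # perfect recovery up to label permutation
  expect_equal(length(unique(cl$cluster[truth == 1])), 1)
  expect_equal(length(unique(cl$cluster[truth == 2])), 1)
  expect_false(cl$cluster[1] == cl$cluster[31])
  # determinism
  cl2 <- cluster_trajectories(avg_tbl(m), k = 2, restarts = 10, seed = 4)
  expect_identical(cl$cluster, cl2$cluster)
})

test_that("k = 1 puts everything in one cluster with total z variance as SSE", {
  m <- matrix(rnorm(70, 10), 10, 7,
    dimnames = list(sprintf("g%d", 1:10), oet_stages())
  )
  cl <- cluster_trajectories(avg_tbl(m), k = 1, restarts = 2, seed = 1)
  expect_equal(unique(cl$cluster), 1)
  z <- t(apply(m, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(
    attr(cl, "tot_withinss"),
    sum(scale(z, scale = FALSE)^2),
    tolerance = 1e-9
  )
})

test_that("best SSE is monotone nonincreasing in restarts", {
  b <- generate_bundle(sim_config(n_genes = 120, seed = 19))
  m <- impute_missing(merge_replicates(b$protein))
  sse <- vapply(c(1, 5, 25), function(r) {
    attr(cluster_trajectories(m, k = 6, restarts = r, seed = 7), "tot_withinss")
  }, 0)
  expect_true(all(diff(sse) <= 1e-9))
})

test_that("group merging honors explicit mappings", {
  asg <- tibble::tibble(gene_id = sprintf("g%d", 1:6), cluster = rep(1:3, 2))
  class(asg) <- c("cluster_assignments", class(asg))
  merged <- merge_to_groups(asg, mapping = c(
    "1" = "constitutive", "2" = "embryonic", "3" = "embryonic"
  ))
  expect_equal(dplyr::n_distinct(merged$group_label), 2)
  ident <- merge_to_groups(asg, mapping = c("1" = "1", "2" = "2", "3" = "3"))
  expect_equal(ident$group_label, as.character(ident$cluster))
  expect_error(merge_to_groups(asg, mapping = c("1" = "x")), "cover")
})

test_that("the automated rule merges late-detected clusters as embryonic", {
  stages <- oet_stages()
  # two embryonic archetypes (detectable from 8C vs only at BL) and one
  # constitutive archetype, on an imputed floor of 5
  at8c <- t(sapply(1:20, function(i) c(5, 5, 5, 5, 5, 14, 15)))
  atbl <- t(sapply(1:20, function(i) c(5, 5, 5, 5, 5, 5, 15)))
  const <- t(sapply(1:20, function(i) rep(15, 7) + 0.1 * seq_len(7)))
  m <- rbind(at8c, atbl, const)
  rownames(m) <- sprintf("g%02d", 1:60)
  colnames(m) <- stages
  profiles <- avg_tbl(m)
  cl <- cluster_trajectories(profiles, k = 3, restarts = 10, seed = 2)
  merged <- merge_to_groups(cl, profiles = profiles, floor = 6)
  expect_equal(unique(merged$group_label[1:40]), "embryonic")
  expect_false(any(merged$group_label[41:60] == "embryonic"))
})

test_that("stage correlation matches a rank oracle and is rank invariant", {
  m <- matrix(c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10), 5, 2,
    dimnames = list(sprintf("g%d", 1:5), c("FGO", "MII"))
  )
  sc <- stage_correlation_matrix(avg_tbl(m))
  expect_equal(unname(diag(unclass(sc))), c(1, 1))
  expect_equal(sc["FGO", "MII"], spearman_oracle(m[, 1], m[, 2]))
  # monotone transform of the second layer leaves the matrix unchanged
  m2 <- m
  m2[, 2] <- exp(m2[, 2] / 3)
  sc2 <- stage_correlation_matrix(avg_tbl(m), avg_tbl(m2))
  expect_equal(unclass(sc2), unclass(sc), ignore_attr = TRUE)
  expect_error(
    stage_correlation_matrix(avg_tbl(m[1:2, , drop = FALSE])),
    "3 shared genes"
  )
})

test_that("synthetic proteome shows an FGO-8C block broken at the blastocyst", {
  b <- generate_bundle(sim_config(n_genes = 300, seed = 23))
  corrected <- apply_batch_correction(b$protein, compute_batch_factors(b$protein))
  m <- impute_missing(merge_replicates(corrected))
  sc <- unclass(stage_correlation_matrix(m))
  # constitutive-dominated proteome: the FGO-8C stages cohere as a block,
  # the blastocyst is the most dissimilar stage overall
  block <- sc[1:6, 1:6]
  expect_gt(mean(block[upper.tri(block)]), mean(sc["BL", 1:6]))
  # and the 8C-to-blastocyst transition carries by far the most
  # differential proteins, dominated by up-regulation (newly accumulated
  # embryonic proteins)
  g <- glance(dep_table(corrected))
  bl_row <- g[g$transition == "8C->BL", ]
  expect_equal(max(g$n_de), bl_row$n_de)
  expect_gt(bl_row$n_up, bl_row$n_down)
})
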