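test_that("gene-wise correlation is 1 for monotone and -1 for antitone pairs", {
  stages <- oet_stages()
  rpf <- matrix(c(1, 3, 2, 5, 4, 7, 6), 1, dimnames = list("g1", stages))
  prot_up <- log2(rpf + 1) * 3 + 2 # strictly monotone transform
  prot_dn <- -prot_up
  r_up <- genewise_correlation(avg_tbl(prot_up), avg_tbl(rpf))
  expect_equal(r_up$r, 1)
  expect_equal(r_up$bin, "high")
  r_dn <- genewise_correlation(avg_tbl(prot_dn), avg_tbl(rpf))
  expect_equal(r_dn$r, -1)
  expect_equal(r_dn$bin, "low")
})

test_that("gene-wise correlation equals the rank-formula oracle", {
  set.seed(8)
  stages <- oet_stages()
  p <- matrix(rnorm(7 * 5, 10), 5, 7, dimnames = list(sprintf("g%d", 1:5), stages))
  o <- matrix(rexp(7 * 5, 0.1), 5, 7, dimnames = list(sprintf("g%d", 1:5), stages))
  res <- genewise_correlation(avg_tbl(p), avg_tbl(o))
  for (i in 1:5) {
    expect_equal(
      res$r[res$gene_id == sprintf("g%d", i)],
      spearman_oracle(p[i, ], o[i, ])
    )
  }
})

test_that("bin boundaries follow the documented closed-side convention", {
  expect_equal(
    concordance_bin(c(0.19, 0.2, 0.35, 0.5, 0.51, NA)),
    c("low", "medium", "medium", "medium", "high", NA)
  )
})

test_that("genes with too few complete stages are skipped and counted", {
  stages <- oet_stages()
  p <- matrix(c(1:7, 1, 2, rep(NA, 5)), 2, 7,
    byrow = TRUE, dimnames = list(c("g1", "g2"), stages)
  )
  o <- matrix(rep(1:7, 2), 2, 7, byrow = TRUE, dimnames = list(c("g1", "g2"), stages))
  res <- genewise_correlation(avg_tbl(p), avg_tbl(o))
  expect_equal(res$gene_id, "g1")
  expect_equal(attr(res, "n_skipped"), 1)
})

test_that("change tables hold consecutive log2 differences that telescope", {
  stages <- oet_stages()
  m <- matrix(c(10, 11, 9, 12, 12, 8, 14), 1, dimnames = list("g1", stages))
  ch <- change_matrix(avg_tbl(m, layer = "protein_log2_ibaq"))
  expect_equal(ch$change, diff(m[1, ]), ignore_attr = TRUE)
  expect_equal(sum(ch$change), m[1, 7] - m[1, 1], ignore_attr = TRUE)
  # constant gene: all zero
  ch0 <- change_matrix(avg_tbl(m * 0 + 5, layer = "protein_log2_ibaq"))
  expect_equal(ch0$change, rep(0, 6))
  # FPKM layers are log2(x + 1) transformed first
  fp <- matrix(c(0, 1, 3, 7, 15, 31, 63), 1, dimnames = list("g1", stages))
  chf <- change_matrix(avg_tbl(fp, layer = "rpf_fpkm"))
  expect_equal(chf$change, rep(1, 6))
})

test_that("lagged change correlation exposes planted lag structure", {
  set.seed(5)
  stages <- oet_stages()
  n <- 60
  rpf_changes <- matrix(rnorm(n * 6), n, 6)
  # protein change at transition i equals RPF change at transition i - 1
  prot_changes <- cbind(rnorm(n), rpf_changes[, 1:5])
  to_tbl <- function(chm) {
    trans <- stage_transitions(stages)
    colnames(chm) <- trans
    rownames(chm) <- sprintf("g%02d", 1:n)
    tibble::as_tibble(chm, rownames = "gene_id") |>
      tidyr::pivot_longer(-"gene_id",
        names_to = "transition", values_to = "change"
      ) |>
      dplyr::mutate(transition = factor(transition, levels = trans))
  }
  lcc <- lagged_change_correlation(to_tbl(prot_changes), to_tbl(rpf_changes))
  expect_true(all(lag_diagonal(lcc, 1) > 0.99))
  expect_true(all(abs(lag_diagonal(lcc, 0)) < 0.35))
  # identity: protein vs itself has unit main diagonal
  self <- lagged_change_correlation(to_tbl(prot_changes), to_tbl(prot_changes))
  expect_equal(unname(lag_diagonal(self, 0)), rep(1, 6))
  # permuted gene labels destroy the structure
  perm <- to_tbl(rpf_changes[sample(n), ])
  lcc_perm <- lagged_change_correlation(to_tbl(prot_changes), perm)
  expect_true(all(abs(lag_diagonal(lcc_perm, 1)) < 0.35))
})

test_that("IDR segmentation applies the strict >30-residue rule", {
  expect_equal(nrow(idr_segments(rep(0, 100))), 0)
  # 31 disordered residues at positions 10-40 qualify
  s <- rep(0, 100)
  s[10:40] <- 0.9
  seg <- idr_segments(s)
  expect_equal(seg$start, 10)
  expect_equal(seg$end, 40)
  expect_equal(seg$length, 31)
  # a run of exactly 30 does not
  s30 <- rep(0, 100)
  s30[10:39] <- 0.9
  expect_equal(nrow(idr_segments(s30)), 0)
  # score exactly at the cutoff is not disordered (strict >)
  s_cut <- rep(0.5, 100)
  expect_equal(nrow(idr_segments(s_cut)), 0)
  expect_error(idr_segments(numeric(0)), "empty")
  expect_error(idr_segments(c(0.2, 1.4)), "0, 1")
})

test_that("IDR segmentation matches the brute-force scan on random proteins", {
  set.seed(33)
  for (i in 1:12) {
    n <- sample(50:200, 1)
    s <- runif(n)
    # bias towards long runs in half the cases
    if (i %% 2 == 0) s[20:min(n, 90)] <- runif(length(20:min(n, 90)), 0.51, 1)
    got <- idr_segments(s)
    want <- idr_brute(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("feature association matches a rank-sum enumeration oracle", {
  # disjoint groups {1,2,3} vs {10,11,12}: the most extreme of the
  # choose(6,3) = 20 equally likely rank splits, so two-sided p = 2/20
  df <- tibble::tibble(
    value = c(1, 2, 3, 10, 11, 12),
    group = rep(c("a", "b"), each = 3)
  )
  res <- feature_association(df)
  expect_equal(res$test, "wilcoxon")
  expect_equal(unname(res$statistic), 0) # W: no a-value exceeds a b-value
  expect_equal(res$p_value, 2 / 20)
  # identical distributions: p = 1 by enumeration symmetry
  df_null <- tibble::tibble(value = rep(c(1, 2, 3), 2), group = rep(c("a", "b"), each = 3))
  # ties across groups force the normal approximation; p stays ~1
  expect_gt(suppressWarnings(feature_association(df_null)$p_value), 0.9)
})

test_that("binary features are tested with Fisher's exact test", {
  df <- tibble::tibble(
    value = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)),
    group = rep(c("high", "low"), each = 10)
  )
  res <- feature_association(df)
  expect_equal(res$test, "fisher")
  expect_equal(
    res$p_value,
    fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value
  )
})

test_that("planted half-life differences between bins are detected", {
  b <- generate_bundle(quiet_config(n_genes = 200, seed = 44))
  m <- impute_missing(merge_replicates(b$protein))
  conc <- genewise_correlation(m, merge_replicates(b$rpf))
  set.seed(1)
  # plant: low-concordance genes get 2x half-lives (lognormal around 20 vs 10)
  hl <- ifelse(conc$bin == "low", 20, 10) * exp(rnorm(nrow(conc), 0, 0.2))
  df <- tibble::tibble(
    value = hl,
    group = ifelse(conc$bin == "low", "low", "other")
  )
  res <- feature_association(df)
  expect_lt(res$p_value, 1e-6)
})

test_that("concordance bin fractions sum to one over defined genes", {
  b <- generate_bundle(sim_config(n_genes = 150, seed = 9))
  m <- impute_missing(merge_replicates(b$protein))
  conc <- genewise_correlation(m, merge_replicates(b$rpf))
  g <- glance(conc)
  expect_equal(g$frac_high + g$frac_medium + g$frac_low, 1)
})
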