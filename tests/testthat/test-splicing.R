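make_quant <- function(tpm_by_iso, gene_id = "g1", sample_id = "s1") {
  n <- length(tpm_by_iso)
  tibble::tibble(transcript_id = paste0(gene_id, ".", seq_len(n)),
                 gene_id = gene_id,
                 length = 1200, effective_length = 1000,
                 tpm = tpm_by_iso, num_reads = tpm_by_iso,
                 sample_id = sample_id)
}

test_that("PSI is the isoform share of gene TPM, with an expression floor", {
  q <- dplyr::bind_rows(make_quant(c(8, 2), "g1"),
                        make_quant(5, "g2"),
                        make_quant(c(0.3, 0.1), "g3"))
  psi <- psi_per_isoform(q, floor = 1)
  expect_equal(psi$psi[psi$gene_id == "g1"], c(0.8, 0.2))
  expect_equal(psi$psi[psi$gene_id == "g2"], 1)       # single isoform
  expect_true(all(is.na(psi$psi[psi$gene_id == "g3"])))  # total 0.4 < floor
  expect_error(psi_per_isoform(dplyr::mutate(q, tpm = -tpm)), "non-negative")
})

test_that("the alternative band is closed at 0.05 and 0.95", {
  expect_true(alternative_flag(0.5))
  expect_false(alternative_flag(0.97))
  expect_true(alternative_flag(0.05))
  expect_true(alternative_flag(0.95))
  expect_false(alternative_flag(0.0499))
  expect_true(is.na(alternative_flag(NA_real_)))
})

test_that("delta PSI is the difference of group means and is antisymmetric", {
  g1 <- make_psi_tbl(matrix(c(0.6, 0.4, 0.6, 0.4), ncol = 2), group = "G1")
  g2 <- make_psi_tbl(matrix(c(0.8, 0.2, 0.8, 0.2), ncol = 2), group = "G2")
  d <- delta_psi(g1, g2)
  expect_equal(d$delta_psi, c(0.2, -0.2))
  expect_equal(delta_psi(g2, g1)$delta_psi, -d$delta_psi)
  expect_equal(delta_psi(g1, g1)$delta_psi, c(0, 0))
  expect_true(all(abs(d$delta_psi) <= 1))
  # Undefined in one group propagates.
  g2na <- g2; g2na$psi <- NA_real_
  expect_true(all(is.na(delta_psi(g1, g2na)$delta_psi)))
})

test_that("empirical p-values respect the smoothing bounds", {
  # Identical groups: observed delta 0, every null draw >= 0 -> p = 1.
  g1 <- make_psi_tbl(matrix(c(0.6, 0.4, 0.62, 0.38), ncol = 2), group = "G1")
  g2 <- make_psi_tbl(matrix(c(0.61, 0.39, 0.59, 0.41), ncol = 2), group = "G2")
  sig <- empirical_significance(g1, g2, n_null = 999, seed = 2)
  expect_true(all(sig$p_empirical <= 1))
  zero_obs <- empirical_significance(g1, g1, n_null = 999, seed = 2)
  expect_equal(zero_obs$p_empirical, rep(1, 2))

  # An observed delta exceeding every null value hits the add-one floor.
  big1 <- make_psi_tbl(matrix(c(0.9, 0.1, 0.9, 0.1), ncol = 2), group = "G1")
  big2 <- make_psi_tbl(matrix(c(0.1, 0.9, 0.1, 0.9), ncol = 2), group = "G2")
  sig_big <- empirical_significance(big1, big2, n_null = 999, seed = 2)
  expect_equal(sig_big$p_empirical, rep(1 / 1000, 2))

  single_rep <- make_psi_tbl(matrix(c(0.6, 0.4), ncol = 1), group = "G1")
  expect_error(empirical_significance(single_rep, g2), ">= 2 replicates")
})

test_that("empirical p-values are reproducible and conservative under the null", {
  cfg <- simulation_config(seed = 47, n_isoforms = 600, n_das_isoforms = 0,
                           psi_noise_sdlog = 0.15)
  sim <- simulate_isoform_quants(cfg)
  psi <- psi_per_isoform(sim$quant)
  g1 <- psi[psi$sample_id %in% sim$groups[[1]], ]
  g2 <- psi[psi$sample_id %in% sim$groups[[2]], ]
  s1 <- empirical_significance(g1, g2, n_null = 500, seed = 9)
  s2 <- empirical_significance(g1, g2, n_null = 500, seed = 9)
  expect_identical(s1$p_empirical, s2$p_empirical)
  # Conservative: small p-values no more frequent than nominal.
  p <- s1$p_empirical[!is.na(s1$p_empirical)]
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("empirical p-values are not anticonservative vs exhaustive pairing on a toy", {
  # 2+2 replicates, one gene: enumerate all within-group replicate pairings
  # by hand and compare the plug-in exceedance fraction with the
  # Monte-Carlo, add-one-smoothed p-value.
  g1 <- make_psi_tbl(matrix(c(0.50, 0.50, 0.55, 0.45), ncol = 2), group = "G1")
  g2 <- make_psi_tbl(matrix(c(0.95, 0.05, 0.65, 0.35), ncol = 2), group = "G2")
  obs <- delta_psi(g1, g2)$delta_psi
  expect_equal(obs[1], 0.275)
  null_pool <- c(abs(0.50 - 0.55), abs(0.50 - 0.45),   # group 1, isoforms 1-2
                 abs(0.95 - 0.65), abs(0.05 - 0.35))   # group 2, isoforms 1-2
  p_exhaustive <- mean(null_pool >= abs(obs[1]))       # = 0.5
  sig <- empirical_significance(g1, g2, n_null = 2000, seed = 3)
  # The smoothed resampling p sits at or just above the exhaustive fraction.
  expect_gte(sig$p_empirical[1], p_exhaustive - 0.05)
  expect_equal(sig$p_empirical[1], p_exhaustive, tolerance = 0.1)
})

test_that("differential-splicing calls conjoin effect size and FDR strictly", {
  sig <- tibble::tibble(
    isoform_id = c("i1", "i2", "i3", "i4"),
    delta_psi = c(0.05, 0.3, -0.3, 0.1),
    p_empirical = c(1e-6, 0.19, 0.001, 1e-6))
  das <- das_call(sig)
  expect_false(das$significant[1])   # effect too small
  expect_false(das$significant[2])   # q too large
  expect_true(das$significant[3])
  expect_identical(das$direction[3], "down")
  expect_false(das$significant[4])   # |dPSI| = 0.1 is not strictly greater
  expect_equal(das_summary(das)$n, 1)
})

test_that("PSI distribution comparison delegates to the KS statistic", {
  a <- make_psi_tbl(matrix(runif(40, 0, 0.5), ncol = 2), group = "G1")
  b <- make_psi_tbl(matrix(runif(40, 0.5, 1), ncol = 2), group = "G2")
  same <- psi_distribution_compare(a, a)
  expect_equal(same$D, 0)
  disjoint <- psi_distribution_compare(a, b)
  expect_gt(disjoint$D, 0.95)
  empty <- a; empty$psi <- NA_real_
  expect_error(psi_distribution_compare(empty, b), "defined PSI")
})
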