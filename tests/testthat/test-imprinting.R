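# Builds a small reciprocal-pair count table: one row per gene x cross x
# replicate, splitting the given pooled counts across two replicates.
make_pair_counts <- function(gene_id, m_fwd, p_fwd, m_rev, p_rev,
                             stage = "E3", pair = c("AxC", "CxA")) {
  split2 <- function(x) cbind(floor(x / 2), ceiling(x / 2))
  rows <- list()
  for (i in seq_along(gene_id)) {
    m1 <- split2(m_fwd[i]); p1 <- split2(p_fwd[i])
    m2 <- split2(m_rev[i]); p2 <- split2(p_rev[i])
    rows[[i]] <- tibble::tibble(
      gene_id = gene_id[i],
      cross = rep(pair, each = 2),
      stage = stage,
      tissue = tissue_for_stage(stage),
      replicate = c(1L, 2L, 1L, 2L),
      maternal_reads = c(m1[1], m1[2], m2[1], m2[2]),
      paternal_reads = c(p1[1], p1[2], p2[1], p2[2]))
  }
  dplyr::bind_rows(rows)
}

test_that("maternal fraction is the maternal share of informative reads", {
  expect_equal(maternal_fraction(30, 10), 0.75)
  expect_equal(maternal_fraction(0, 40), 0)
  expect_equal(maternal_fraction(20, 20), 0.5)
  expect_error(maternal_fraction(0, 0), "at least one read")
})

test_that("a strongly maternal embryo gene is called MEG against a balanced background", {
  set.seed(55)
  n_bg <- 500
  bg_tot <- rpois(n_bg, 60) + 20
  bg_m_f <- rbinom(n_bg, bg_tot, 0.5)
  bg_m_r <- rbinom(n_bg, bg_tot, 0.5)
  # Maternal fractions 0.95 / 0.90 at 100 reads per direction: deep enough
  # that the BH-adjusted chi-square q stays below 0.01 even inside a
  # family of ~1000 null tests.
  counts <- make_pair_counts(
    gene_id = c("meg1", sprintf("bg%03d", seq_len(n_bg))),
    m_fwd = c(95, bg_m_f), p_fwd = c(5, bg_tot - bg_m_f),
    m_rev = c(90, bg_m_r), p_rev = c(10, bg_tot - bg_m_r))
  calls <- call_imprinted(counts, "E3", "embryo", c("AxC", "CxA"))
  meg <- calls[calls$gene_id == "meg1", ]
  expect_identical(meg$status, "MEG")
  expect_equal(meg$maternal_fraction_forward, 0.95)
  expect_equal(meg$maternal_fraction_reverse, 0.90)
  expect_lt(meg$q, 0.01)
  # The balanced background stays unimprinted.
  expect_lte(mean(calls$status %in% c("MEG", "PEG")), 1 / n_bg + 0.01)
})

test_that("read-depth and ratio thresholds apply exactly", {
  counts <- make_pair_counts(
    gene_id = c("lowdepth", "meg_low", "peg_end", "bg1", "bg2"),
    m_fwd = c(5, 150, 10, 100, 95),
    p_fwd = c(4, 50, 190, 100, 105),
    m_rev = c(100, 156, 12, 98, 101),
    p_rev = c(100, 44, 188, 102, 99),
    stage = "E8")
  calls <- call_imprinted(counts, "E8", "endosperm", c("AxC", "CxA"))
  # 9 pooled reads in the forward direction -> insufficient_data.
  expect_identical(calls$status[calls$gene_id == "lowdepth"],
                   "insufficient_data")
  # Maternal fractions 0.75/0.78: biased, but below the endosperm MEG
  # threshold of 0.85 -> not called.
  expect_identical(calls$status[calls$gene_id == "meg_low"], "not_imprinted")
  # Paternal fractions 0.95/0.94 with q << 0.01 -> PEG (threshold 0.6).
  expect_identical(calls$status[calls$gene_id == "peg_end"], "PEG")
})

test_that("endosperm calls are tested against the 2:1 dosage, not 1:1", {
  # Maternal fraction exactly 2/3 in both directions: expected under the
  # endosperm dosage, so chi-square must not fire however deep the coverage.
  counts <- make_pair_counts("dosage", 400, 200, 400, 200, stage = "E8")
  calls <- call_imprinted(counts, "E8", "endosperm", c("AxC", "CxA"))
  expect_identical(calls$status, "not_imprinted")
  expect_equal(calls$p_forward, 1)
})

test_that("swapping parental columns converts embryo MEG calls to PEG calls", {
  cfg <- simulation_config(seed = 41, n_genes_ase = 800, frac_meg = 0.05,
                           frac_peg = 0.05, imprint_strength = 0.95)
  sim <- simulate_allele_counts(cfg)
  calls <- call_imprinted(sim$counts, "E3", "embryo", cfg$cross_pair)
  swapped <- sim$counts
  swapped$maternal_reads <- sim$counts$paternal_reads
  swapped$paternal_reads <- sim$counts$maternal_reads
  calls_sw <- call_imprinted(swapped, "E3", "embryo", cfg$cross_pair)
  m <- match(calls$gene_id, calls_sw$gene_id)
  expect_identical(calls_sw$status[m][calls$status == "MEG"],
                   rep("PEG", sum(calls$status == "MEG")))
  expect_identical(calls_sw$status[m][calls$status == "PEG"],
                   rep("MEG", sum(calls$status == "PEG")))
})

test_that("calls are invariant to replicate ordering and re-splitting", {
  cfg <- simulation_config(seed = 43, n_genes_ase = 300, frac_meg = 0.03,
                           frac_peg = 0.03)
  sim <- simulate_allele_counts(cfg)
  base <- call_imprinted(sim$counts, "E3", "embryo", cfg$cross_pair)
  # Reverse row order.
  shuffled <- sim$counts[rev(seq_len(nrow(sim$counts))), ]
  expect_equal(dplyr::arrange(call_imprinted(shuffled, "E3", "embryo",
                                             cfg$cross_pair), gene_id),
               dplyr::arrange(base, gene_id))
  # Re-split pooled counts into four replicates with the same totals.
  resplit <- sim$counts |>
    dplyr::group_by(gene_id, cross, stage, tissue) |>
    dplyr::summarise(maternal_reads = sum(maternal_reads),
                     paternal_reads = sum(paternal_reads), .groups = "drop")
  quarters <- dplyr::bind_rows(lapply(1:4, function(r) {
    q <- resplit
    q$replicate <- as.integer(r)
    q$maternal_reads <- floor(resplit$maternal_reads / 4) +
      (r <= resplit$maternal_reads %% 4)
    q$paternal_reads <- floor(resplit$paternal_reads / 4) +
      (r <= resplit$paternal_reads %% 4)
    q
  }))
  requartered <- call_imprinted(quarters, "E3", "embryo", cfg$cross_pair)
  expect_equal(dplyr::arrange(requartered, gene_id),
               dplyr::arrange(base, gene_id))
})

test_that("per-replicate concordance mode demotes replicate-inconsistent genes", {
  # Pooled fraction 0.75 passes, but replicate 2 alone (10m/10p) does not.
  counts <- tibble::tibble(
    gene_id = "g1",
    cross = rep(c("AxC", "CxA"), each = 2),
    stage = "E3", tissue = "embryo",
    replicate = rep(1:2, 2),
    maternal_reads = c(50L, 10L, 50L, 10L),
    paternal_reads = c(10L, 10L, 10L, 10L))
  pooled <- call_imprinted(counts, "E3", "embryo", c("AxC", "CxA"))
  strict <- call_imprinted(counts, "E3", "embryo", c("AxC", "CxA"),
                           require_each_replicate = TRUE)
  expect_identical(pooled$status, "MEG")
  expect_identical(strict$status, "not_imprinted")
})

test_that("missing cross direction and tissue mismatch are errors", {
  counts <- make_pair_counts("g1", 10, 10, 10, 10)
  expect_error(call_imprinted(counts, "E3", "embryo", c("AxC", "ZxA")),
               "ZxA")
  expect_error(call_imprinted(counts, "E3", "endosperm", c("AxC", "CxA")),
               "not a endosperm stage")
})
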