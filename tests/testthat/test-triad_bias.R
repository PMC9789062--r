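test_that("triad fractions normalize per-sample TPM within each triad", {
  meta <- make_meta("AxC_E3_r1", replicate = 1L)
  vals <- matrix(c(10, 30, 60,   # t1
                   0, 0, 0,      # t2 (silent)
                   5, 5, 5),     # t3
                 ncol = 1, dimnames = list(
                   c("a1", "b1", "d1", "a2", "b2", "d2", "a3", "b3", "d3"),
                   meta$sample_id))
  triads <- tibble::tibble(triad_id = c("t1", "t2", "t3"),
                           gene_A = c("a1", "a2", "a3"),
                           gene_B = c("b1", "b2", "b3"),
                           gene_D = c("d1", "d2", "d3"))
  fr <- triad_fractions(make_expr(vals, meta), triads, floor = 0.5)
  expect_equal(fr$frac_A, c(0.1, NA, 1 / 3))
  expect_equal(fr$frac_B, c(0.3, NA, 1 / 3))
  expect_equal(fr$frac_D, c(0.6, NA, 1 / 3))
  expect_equal(fr$defined, c(TRUE, FALSE, TRUE))

  bad_map <- triads; bad_map$gene_D[1] <- "nope"
  expect_error(triad_fractions(make_expr(vals, meta), bad_map), "nope")
})

test_that("every centroid classifies to its own category in both modes", {
  for (ng in c(3, 2)) {
    cents <- bias_centroids(ng)
    for (k in seq_len(nrow(cents))) {
      expect_identical(classify_triad(cents[k, ], cents), rownames(cents)[k])
    }
  }
})

test_that("classification matches a brute-force oracle and breaks ties canonically", {
  expect_identical(classify_triad(c(1, 1, 1) / 3), "Balanced")
  expect_identical(classify_triad(c(0.5, 0.5, 0)), "D_suppressed")
  expect_identical(classify_triad(c(0.70, 0.15, 0.15)), "A_dominant")
  # Exact tie between A_dominant and D_suppressed resolves to A_dominant
  # (earlier in the canonical order).
  expect_identical(classify_triad(c(0.75, 0.25, 0)), "A_dominant")

  # Brute-force oracle on random simplex points: explicit distance loop.
  oracle <- function(x, cents) {
    d <- apply(cents, 1, function(ct) sqrt(sum((x - ct)^2)))
    names(d)[which.min(d)]
  }
  set.seed(9)
  cents <- bias_centroids(3)
  for (i in 1:200) {
    x <- rgamma(3, 1); x <- x / sum(x)
    expect_identical(classify_triad(x, cents), oracle(x, cents))
  }
  expect_error(classify_triad(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("axis permutation permutes the assigned category consistently", {
  perm <- c(2, 3, 1)  # A->B, B->D, D->A
  cents <- bias_centroids(3)
  cents_perm <- cents[, perm]
  colnames(cents_perm) <- colnames(cents)
  set.seed(21)
  for (i in 1:50) {
    x <- rgamma(3, 1); x <- x / sum(x)
    orig <- classify_triad(x, cents)
    permuted <- classify_triad(x[perm], cents_perm)
    expect_identical(permuted, orig)
  }
})

test_that("classify_all summarises percentages over defined triads only", {
  fr <- tibble::tibble(
    triad_id = c("t1", "t2", "t3", "t4"),
    sample_id = "s1",
    frac_A = c(1 / 3, 0.5, 1, NA),
    frac_B = c(1 / 3, 0.5, 0, NA),
    frac_D = c(1 / 3, 0, 0, NA),
    total_tpm = c(10, 10, 10, 0),
    defined = c(TRUE, TRUE, TRUE, FALSE))
  res <- classify_all(fr)
  expect_equal(res$calls$category,
               c("Balanced", "D_suppressed", "A_dominant", NA))
  expect_equal(sum(res$summary$percent), 100)
  expect_equal(sort(res$summary$percent), rep(100 / 3, 3))

  empty <- fr; empty$defined <- FALSE
  expect_warning(classify_all(empty), "No defined")
})

test_that("transition table counts flows over triads defined in both calls", {
  a <- tibble::tibble(triad_id = c("t1", "t2", "t3", "t4"),
                      category = c("Balanced", "Balanced", "D_suppressed", NA))
  b <- tibble::tibble(triad_id = c("t1", "t2", "t3", "t4"),
                      category = c("Balanced", "D_suppressed", "D_suppressed",
                                   "Balanced"))
  tt <- transition_table(a, b)
  expect_equal(tt$counts["Balanced", "Balanced"], 1)
  expect_equal(tt$counts["Balanced", "D_suppressed"], 1)
  expect_equal(tt$counts["D_suppressed", "D_suppressed"], 1)
  expect_equal(sum(tt$counts), tt$n_both_defined)
  expect_equal(unname(tt$undefined["a_only"]), 1)

  # Identity case: diagonal table; row sums match category counts.
  tt2 <- transition_table(b, b)
  expect_equal(sum(diag(tt2$counts)), sum(tt2$counts))
  expect_equal(rowSums(tt2$counts)[["Balanced"]], 2)

  disjoint <- tibble::tibble(triad_id = "zz", category = "Balanced")
  expect_error(transition_table(a, disjoint), "shared")
})

test_that("subgenome contribution averages defined fractions to percentages", {
  fr <- tibble::tibble(
    triad_id = c("t1", "t2"), sample_id = "s1",
    frac_A = c(0.4, 0.4), frac_B = c(0.4, 0.4), frac_D = c(0.2, 0.2),
    total_tpm = 10, defined = TRUE)
  sc <- subgenome_contribution(fr)
  expect_equal(sc$mean_percent[sc$subgenome == "A"], 40)
  expect_equal(sc$mean_percent[sc$subgenome == "D"], 20)
  expect_equal(sum(sc$mean_percent), 100)
})

test_that("simulated mixture contributions match the closed-form centroid mean", {
  props <- c(Balanced = 0.6, D_suppressed = 0.4)
  cfg <- simulation_config(seed = 31, n_triads = 3000,
                           category_proportions = props,
                           triad_total_tpm_mean = 500)
  tri <- simulate_triads(cfg)
  fr <- triad_fractions(tri$expr, tri$triads)
  sc <- subgenome_contribution(fr)
  # Closed form: 0.6 * (1/3,1/3,1/3) + 0.4 * (0.5,0.5,0) = (0.4, 0.4, 0.2).
  means <- tapply(sc$mean_percent, sc$subgenome, mean)
  expect_equal(as.numeric(means[c("A", "B", "D")]), c(40, 40, 20),
               tolerance = 0.03)
})
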