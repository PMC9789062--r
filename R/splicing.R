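#' Percent spliced-in per isoform
#'
#' For each gene in each sample, PSI of an isoform is its TPM divided by the
#' summed TPM of the gene's isoforms. When the gene total falls below the
#' expression floor the PSI of all its isoforms is undefined (`NA`) in that
#' sample: inclusion fractions of an unexpressed gene are noise.
#'
#' @param quant Transcript quantification tibble (see
#'   [read_transcript_quant()]); may hold one or many samples.
#' @param floor Minimum gene TPM for PSI to be defined. Default 1.
#' @return Tibble with columns `gene_id`, `isoform_id`, `sample_id`, `psi`,
#'   `gene_tpm`.
#' @export
psi_per_isoform <- function(quant, floor = 1) {
  require_columns(quant, c("transcript_id", "gene_id", "tpm", "sample_id"),
                  "Transcript quantification")
  if (any(quant$tpm < 0)) stop("TPM must be non-negative", call. = FALSE)
  quant |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::mutate(gene_tpm = sum(.data$tpm)) |>
    dplyr::ungroup() |>
    dplyr::transmute(gene_id = .data$gene_id,
                     isoform_id = .data$transcript_id,
                     sample_id = .data$sample_id,
                     psi = ifelse(.data$gene_tpm >= floor & .data$gene_tpm > 0,
                                  .data$tpm / .data$gene_tpm, NA_real_),
                     gene_tpm = .data$gene_tpm)
}

#' Is an inclusion fraction "alternative"?
#'
#' An isoform (or splicing outcome) is considered alternatively spliced when
#' its PSI lies in the closed band \[0.05, 0.95\]; values outside it indicate
#' an essentially constitutive inclusion or exclusion.
#'
#' @param psi Numeric PSI vector; `NA` propagates.
#' @return Logical vector.
#' @export
alternative_flag <- function(psi) {
  psi >= 0.05 & psi <= 0.95
}

#' Average PSI difference between two sample groups
#'
#' Per isoform, the difference of group mean PSI (`group2 - group1`), using
#' defined PSI values only; the difference is undefined when either group
#' has no defined value for the isoform.
#'
#' @param psi_group1,psi_group2 PSI tibbles (see [psi_per_isoform()]), one
#'   per sample group.
#' @return Tibble with columns `isoform_id`, `gene_id`, `psi_group1`,
#'   `psi_group2`, `delta_psi`, `mean_gene_tpm`.
#' @export
delta_psi <- function(psi_group1, psi_group2) {
  mean_defined <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  g1 <- psi_group1 |>
    dplyr::group_by(.data$isoform_id, .data$gene_id) |>
    dplyr::summarise(psi_group1 = mean_defined(.data$psi),
                     tpm1 = mean(.data$gene_tpm), .groups = "drop")
  g2 <- psi_group2 |>
    dplyr::group_by(.data$isoform_id, .data$gene_id) |>
    dplyr::summarise(psi_group2 = mean_defined(.data$psi),
                     tpm2 = mean(.data$gene_tpm), .groups = "drop")
  dplyr::inner_join(g1, g2, by = c("isoform_id", "gene_id")) |>
    dplyr::transmute(isoform_id = .data$isoform_id,
                     gene_id = .data$gene_id,
                     psi_group1 = .data$psi_group1,
                     psi_group2 = .data$psi_group2,
                     delta_psi = .data$psi_group2 - .data$psi_group1,
                     mean_gene_tpm = (.data$tpm1 + .data$tpm2) / 2)
}

#' Empirical significance of PSI differences
#'
#' Builds an abundance-matched empirical null for |dPSI| from
#' between-replicate, within-group PSI differences: isoforms are binned by
#' log10 mean gene TPM (`n_bins` quantile bins), all within-group replicate
#' pair differences are pooled per bin, and each isoform's p-value is the
#' add-one-smoothed fraction of `n_null` draws from its bin's pool that
#' reach its observed |dPSI|:
#' `p = (1 + #\{null >= |dPSI|\}) / (n_null + 1)`.
#'
#' Replicate variability within a group is at least as large as the
#' between-group difference of group means under the null, so these p-values
#' are conservative. Deterministic given `seed`.
#'
#' @param psi_group1,psi_group2 PSI tibbles, each with at least two samples.
#' @param n_null Null draws per isoform. Default 1000.
#' @param n_bins Abundance bins on log10 gene TPM. Default 3.
#' @param seed Seed for the null resampling. Default 1.
#' @return Tibble: `isoform_id`, `gene_id`, `delta_psi`, `p_empirical`,
#'   `abundance_bin`.
#' @export
empirical_significance <- function(psi_group1, psi_group2, n_null = 1000,
                                   n_bins = 3, seed = 1) {
  for (g in list(psi_group1, psi_group2)) {
    if (length(unique(g$sample_id)) < 2) {
      stop("empirical_significance() needs >= 2 replicates per group; ",
           "with a single replicate the empirical null is undefined",
           call. = FALSE)
    }
  }
  obs <- delta_psi(psi_group1, psi_group2)

  within_diffs <- function(psi_tbl) {
    wide <- tidyr::pivot_wider(psi_tbl[, c("isoform_id", "sample_id", "psi")],
                               names_from = "sample_id", values_from = "psi")
    m <- as.matrix(wide[, -1, drop = FALSE])
    pairs <- utils::combn(ncol(m), 2)
    diffs <- lapply(seq_len(ncol(pairs)), function(j) {
      abs(m[, pairs[1, j]] - m[, pairs[2, j]])
    })
    tibble::tibble(isoform_id = rep(wide$isoform_id, ncol(pairs)),
                   diff = unlist(diffs))
  }
  null_tbl <- dplyr::bind_rows(within_diffs(psi_group1),
                               within_diffs(psi_group2))
  null_tbl <- null_tbl[!is.na(null_tbl$diff), , drop = FALSE]
  if (nrow(null_tbl) == 0) {
    stop("No defined within-group PSI differences to build the null from",
         call. = FALSE)
  }

  log_tpm <- log10(obs$mean_gene_tpm + 1e-8)
  breaks <- unique(quantile(log_tpm, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(breaks) > 2) {
    cut(log_tpm, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(log_tpm))
  }
  null_bin <- bin[match(null_tbl$isoform_id, obs$isoform_id)]
  pools <- split(null_tbl$diff, null_bin)
  all_diffs <- null_tbl$diff

  set.seed(seed)
  p <- rep(NA_real_, nrow(obs))
  for (b in sort(unique(bin))) {
    pool <- pools[[as.character(b)]]
    if (is.null(pool) || length(pool) == 0) pool <- all_diffs
    idx <- which(bin == b & !is.na(obs$delta_psi))
    if (length(idx) == 0) next
    draws <- matrix(sample(pool, n_null * length(idx), replace = TRUE),
                    nrow = length(idx))
    exceed <- rowSums(draws >= abs(obs$delta_psi[idx]))
    p[idx] <- (1 + exceed) / (n_null + 1)
  }
  tibble::tibble(isoform_id = obs$isoform_id,
                 gene_id = obs$gene_id,
                 delta_psi = obs$delta_psi,
                 p_empirical = p,
                 abundance_bin = bin)
}

#' Call differential alternative splicing
#'
#' BH-adjusts the empirical p-values and flags an isoform as differentially
#' spliced when `|dPSI|` strictly exceeds `dpsi_threshold` and the adjusted
#' p-value falls below `fdr`. The direction of change (sign of dPSI,
#' group2 relative to group1) is reported for significant isoforms.
#'
#' @param significance Output of [empirical_significance()] (columns
#'   `isoform_id`, `delta_psi`, `p_empirical`).
#' @param dpsi_threshold Effect-size threshold on |dPSI| (strict). Default 0.1.
#' @param fdr FDR cutoff. Default 0.05.
#' @return Tibble with added `q`, `significant`, `direction` columns.
#' @export
das_call <- function(significance, dpsi_threshold = 0.1, fdr = 0.05) {
  require_columns(significance, c("isoform_id", "delta_psi", "p_empirical"),
                  "Significance table")
  out <- significance
  out$q <- NA_real_
  tested <- !is.na(out$p_empirical)
  if (any(tested)) out$q[tested] <- bh_adjust(out$p_empirical[tested])
  out$significant <- tested & !is.na(out$delta_psi) &
    abs(out$delta_psi) > dpsi_threshold & out$q < fdr
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$delta_psi > 0, "up", "down"))
  tibble::as_tibble(out)
}

#' Summarise up/down counts of differential splicing calls
#'
#' @param das Output of [das_call()].
#' @return Tibble with `direction` (`up`/`down`) and `n` among significant
#'   isoforms.
#' @export
das_summary <- function(das) {
  das |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$direction, name = "n")
}

#' Compare PSI distributions of two groups
#'
#' Two-sample Kolmogorov-Smirnov test on the pooled defined PSI values of
#' each group, as used to compare inclusion-level distributions between
#' reciprocal crosses.
#'
#' @param psi_a,psi_b PSI tibbles.
#' @return A list with `D` and `p_value` (see [ks_two_sample()]).
#' @export
psi_distribution_compare <- function(psi_a, psi_b) {
  a <- psi_a$psi[!is.na(psi_a$psi)]
  b <- psi_b$psi[!is.na(psi_b$psi)]
  if (length(a) == 0 || length(b) == 0) {
    stop("psi_distribution_compare() requires defined PSI values in both groups",
         call. = FALSE)
  }
  ks_two_sample(a, b)
}
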