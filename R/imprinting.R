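#' Thresholds for imprinting calls
#'
#' Defaults follow the standard criteria for dosage-aware imprinting calling
#' from reciprocal-cross allele counts: a minimum of 10 SNP-informative reads
#' per cross direction, a maternal (or paternal) read-fraction of at least
#' 0.7 in embryo tissue, 0.85 (maternal, MEG) and 0.6 (paternal, PEG) in
#' endosperm, chi-square goodness-of-fit FDR below 0.01, and expected
#' maternal fractions of 0.5 (embryo, 1:1 parental dosage) and 2/3
#' (endosperm, 2:1 maternal:paternal dosage). The embryo PEG threshold
#' equals the embryo MEG threshold: the embryo criteria are symmetric in the
#' two parents.
#'
#' @param min_reads_per_cross Minimum pooled reads per cross direction.
#' @param embryo_fraction Embryo read-fraction threshold (both MEG and PEG).
#' @param endosperm_meg_fraction,endosperm_peg_fraction Endosperm maternal
#'   (MEG) and paternal (PEG) fraction thresholds.
#' @param fdr FDR cutoff on the BH-adjusted chi-square p-values.
#' @param embryo_expected_maternal,endosperm_expected_maternal Expected
#'   maternal read fractions under parental genome dosage.
#' @return A validated list of class `imprinting_thresholds`.
#' @export
imprinting_thresholds <- function(min_reads_per_cross = 10L,
                                  embryo_fraction = 0.7,
                                  endosperm_meg_fraction = 0.85,
                                  endosperm_peg_fraction = 0.6,
                                  fdr = 0.01,
                                  embryo_expected_maternal = 0.5,
                                  endosperm_expected_maternal = 2 / 3) {
  th <- list(min_reads_per_cross = as.integer(min_reads_per_cross),
             embryo_fraction = embryo_fraction,
             endosperm_meg_fraction = endosperm_meg_fraction,
             endosperm_peg_fraction = endosperm_peg_fraction,
             fdr = fdr,
             embryo_expected_maternal = embryo_expected_maternal,
             endosperm_expected_maternal = endosperm_expected_maternal)
  fr <- unlist(th[-1])
  if (any(fr <= 0) || any(fr >= 1)) {
    stop("All fraction and FDR thresholds must lie strictly in (0, 1)",
         call. = FALSE)
  }
  structure(th, class = "imprinting_thresholds")
}

#' Maternal read fraction
#'
#' @param maternal,paternal Non-negative read counts (vectorized); each pair
#'   must total at least one read.
#' @return `maternal / (maternal + paternal)`, in \[0, 1\].
#' @export
maternal_fraction <- function(maternal, paternal) {
  total <- maternal + paternal
  if (any(total < 1)) {
    stop("maternal_fraction() requires at least one read", call. = FALSE)
  }
  maternal / total
}

#' Call imprinted genes from reciprocal-cross allele counts
#'
#' For one stage/tissue and a reciprocal cross pair: replicates are pooled
#' within each cross direction; genes below `min_reads_per_cross` in either
#' direction are `insufficient_data`. For the remaining genes a chi-square
#' goodness-of-fit test against the tissue's dosage-expected maternal
#' fraction is computed per direction, all (gene x direction) p-values are
#' BH-adjusted together, and a gene is called:
#'
#' * `MEG` when both directions have q below the FDR cutoff and both
#'   maternal fractions reach the tissue MEG threshold;
#' * `PEG` when both directions have q below the cutoff and both paternal
#'   fractions reach the tissue PEG threshold;
#' * `not_imprinted` otherwise.
#'
#' Requiring both directions to pass enforces reciprocal concordance: the
#' bias must follow the parent role, not the genotype.
#'
#' @param counts Allele count table (see [read_allele_counts()]).
#' @param stage Stage to call (e.g. `"E3"`).
#' @param tissue `"embryo"` or `"endosperm"`; must match the stage.
#' @param pair Character vector of the two cross labels (forward, reverse).
#' @param thresholds An [imprinting_thresholds()] object.
#' @param require_each_replicate Additionally require every replicate with
#'   at least one read to pass the fraction threshold individually for the
#'   called direction of bias. Default `FALSE` (pooled counts only).
#' @return Tibble with one row per gene: maternal fractions, per-direction
#'   p and q values, pooled read totals, and `status` in
#'   MEG/PEG/not_imprinted/insufficient_data.
#' @export
call_imprinted <- function(counts, stage, tissue, pair,
                           thresholds = imprinting_thresholds(),
                           require_each_replicate = FALSE) {
  counts <- validate_allele_counts(counts)
  if (!tissue %in% c("embryo", "endosperm")) {
    stop("Unknown tissue: ", tissue, call. = FALSE)
  }
  if (tissue != tissue_for_stage(stage)) {
    stop("Stage ", stage, " is not a ", tissue, " stage", call. = FALSE)
  }
  if (length(pair) != 2) stop("pair must name two cross directions", call. = FALSE)
  sub <- counts[counts$stage == stage & counts$cross %in% pair, , drop = FALSE]
  for (cr in pair) {
    if (!any(sub$cross == cr)) {
      stop("No counts for cross direction ", cr, " at stage ", stage,
           call. = FALSE)
    }
  }
  th <- thresholds
  expected <- if (tissue == "embryo") th$embryo_expected_maternal
              else th$endosperm_expected_maternal
  meg_thr <- if (tissue == "embryo") th$embryo_fraction
             else th$endosperm_meg_fraction
  peg_thr <- if (tissue == "embryo") th$embryo_fraction
             else th$endosperm_peg_fraction

  pooled <- sub |>
    dplyr::group_by(.data$gene_id, .data$cross) |>
    dplyr::summarise(maternal = sum(.data$maternal_reads),
                     paternal = sum(.data$paternal_reads), .groups = "drop")
  wide <- tidyr::pivot_wider(pooled, names_from = "cross",
                             values_from = c("maternal", "paternal"),
                             values_fill = 0L)
  fw <- pair[1]; rv <- pair[2]
  m_f <- wide[[paste0("maternal_", fw)]]
  p_f <- wide[[paste0("paternal_", fw)]]
  m_r <- wide[[paste0("maternal_", rv)]]
  p_r <- wide[[paste0("paternal_", rv)]]
  tot_f <- m_f + p_f
  tot_r <- m_r + p_r
  sufficient <- tot_f >= th$min_reads_per_cross & tot_r >= th$min_reads_per_cross

  n <- nrow(wide)
  frac_f <- ifelse(tot_f > 0, m_f / tot_f, NA_real_)
  frac_r <- ifelse(tot_r > 0, m_r / tot_r, NA_real_)
  pv_f <- rep(NA_real_, n); pv_r <- rep(NA_real_, n)
  q_f <- rep(NA_real_, n); q_r <- rep(NA_real_, n)
  if (any(sufficient)) {
    test_f <- chi_square_gof(m_f[sufficient], p_f[sufficient], expected)
    test_r <- chi_square_gof(m_r[sufficient], p_r[sufficient], expected)
    pv_f[sufficient] <- test_f$p_value
    pv_r[sufficient] <- test_r$p_value
    # One BH family over all gene x direction tests of this stage/tissue.
    q_all <- bh_adjust(c(test_f$p_value, test_r$p_value))
    k <- sum(sufficient)
    q_f[sufficient] <- q_all[seq_len(k)]
    q_r[sufficient] <- q_all[k + seq_len(k)]
  }

  sig <- sufficient & q_f < th$fdr & q_r < th$fdr
  is_meg <- sig & frac_f >= meg_thr & frac_r >= meg_thr
  is_peg <- sig & (1 - frac_f) >= peg_thr & (1 - frac_r) >= peg_thr

  if (require_each_replicate) {
    rep_frac <- sub |>
      dplyr::filter(.data$maternal_reads + .data$paternal_reads > 0) |>
      dplyr::mutate(frac = .data$maternal_reads /
                      (.data$maternal_reads + .data$paternal_reads))
    meg_ok <- rep_frac |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(ok = all(.data$frac >= meg_thr), .groups = "drop")
    peg_ok <- rep_frac |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(ok = all(1 - .data$frac >= peg_thr), .groups = "drop")
    is_meg <- is_meg & wide$gene_id %in% meg_ok$gene_id[meg_ok$ok]
    is_peg <- is_peg & wide$gene_id %in% peg_ok$gene_id[peg_ok$ok]
  }

  status <- ifelse(!sufficient, "insufficient_data",
                   ifelse(is_meg, "MEG",
                          ifelse(is_peg, "PEG", "not_imprinted")))
  tibble::tibble(gene_id = wide$gene_id,
                 stage = stage,
                 tissue = tissue,
                 maternal_fraction_forward = frac_f,
                 maternal_fraction_reverse = frac_r,
                 total_reads_forward = tot_f,
                 total_reads_reverse = tot_r,
                 p_forward = pv_f,
                 p_reverse = pv_r,
                 q_forward = q_f,
                 q_reverse = q_r,
                 q = pmax(q_f, q_r),
                 status = status)
}

#' Per-gene maternal fraction distributions
#'
#' Pools replicates per gene within each grouping combination and returns the
#' maternal read fractions with their dosage-expected reference value (0.5
#' embryo, 2/3 endosperm), in a shape suitable for density plotting of the
#' maternal-fraction distribution per cross and tissue.
#'
#' @param counts Allele count table.
#' @param by Grouping columns; default `c("cross", "tissue", "stage")`.
#' @return Tibble with per-gene pooled counts, `maternal_fraction` and
#'   `expected_maternal`.
#' @export
maternal_fraction_summary <- function(counts, by = c("cross", "tissue", "stage")) {
  counts <- validate_allele_counts(counts)
  counts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene_id", by)))) |>
    dplyr::summarise(maternal = sum(.data$maternal_reads),
                     paternal = sum(.data$paternal_reads), .groups = "drop") |>
    dplyr::filter(.data$maternal + .data$paternal > 0) |>
    dplyr::mutate(
      maternal_fraction = maternal_fraction(.data$maternal, .data$paternal),
      expected_maternal = if ("tissue" %in% by) {
        ifelse(.data$tissue == "embryo", 0.5, 2 / 3)
      } else if ("stage" %in% by) {
        ifelse(tissue_for_stage(.data$stage) == "embryo", 0.5, 2 / 3)
      } else {
        NA_real_
      })
}
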