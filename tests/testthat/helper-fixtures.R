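# Small in-code fixtures shared across test files.

make_meta <- function(sample_ids = c("AxC_E3_r1", "AxC_E3_r2"),
                      cross = "AxC", stage = "E3", replicate = NULL) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    cross = rep_len(cross, n),
    maternal_parent = "A", paternal_parent = "C",
    maternal_ploidy = 6L, paternal_ploidy = 4L,
    tissue = tissue_for_stage(rep_len(stage, n)),
    stage = rep_len(stage, n),
    replicate = if (is.null(replicate)) seq_len(n) else replicate)
}

make_expr <- function(values, meta) {
  expression_matrix(values, meta)
}

# Two-replicate PSI table for a set of isoforms; psi_by_rep is a matrix of
# isoform x replicate PSI values for one gene group.
make_psi_tbl <- function(psi_by_rep, gene_id = "g1", group = "G1",
                         gene_tpm = 50) {
  n_iso <- nrow(psi_by_rep)
  n_rep <- ncol(psi_by_rep)
  iso_ids <- paste0(gene_id, ".", seq_len(n_iso))
  tibble::tibble(
    gene_id = rep(gene_id, n_iso * n_rep),
    isoform_id = rep(iso_ids, n_rep),
    sample_id = rep(paste0(group, "_r", seq_len(n_rep)), each = n_iso),
    psi = as.vector(psi_by_rep),
    gene_tpm = gene_tpm)
}
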