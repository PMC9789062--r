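# All tables are TSV with a header row, UTF-8, "." decimal point, NA for
# missing values. Sample metadata travels in a sidecar TSV rather than being
# packed into expression column names.

SAMPLE_META_COLS <- c("sample_id", "cross", "maternal_parent", "paternal_parent",
                      "maternal_ploidy", "paternal_ploidy", "tissue", "stage",
                      "replicate")

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA", col_types = readr::cols())
}

write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Validate a sample metadata table
#'
#' Checks the invariants of the per-sample metadata: known tissues and
#' stages, tissue consistent with stage (embryo E1-E7, endosperm E8-E9),
#' unique sample ids and unique (cross, stage, replicate) keys.
#'
#' @param meta A data frame with columns `sample_id`, `cross`,
#'   `maternal_parent`, `paternal_parent`, `maternal_ploidy`,
#'   `paternal_ploidy`, `tissue`, `stage`, `replicate`.
#' @return The validated metadata as a tibble.
#' @export
validate_sample_meta <- function(meta) {
  require_columns(meta, SAMPLE_META_COLS, "Sample metadata")
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$sample_id)) {
    stop("Duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(meta$tissue %in% c("embryo", "endosperm"))) {
    stop("tissue must be 'embryo' or 'endosperm'", call. = FALSE)
  }
  if (!all(meta$stage %in% ALL_STAGES)) {
    stop("stage must be one of E1..E9", call. = FALSE)
  }
  bad <- meta$tissue != tissue_for_stage(meta$stage)
  if (any(bad)) {
    stop("Stage/tissue mismatch for sample(s): ",
         paste(meta$sample_id[bad], collapse = ", "),
         " (embryo spans E1-E7, endosperm E8-E9)", call. = FALSE)
  }
  if (!all(meta$maternal_ploidy %in% c(4L, 6L)) ||
      !all(meta$paternal_ploidy %in% c(4L, 6L))) {
    stop("Parental ploidies must be 4 (tetraploid) or 6 (hexaploid)",
         call. = FALSE)
  }
  if (any(meta$replicate < 1)) stop("replicate must be >= 1", call. = FALSE)
  key <- paste(meta$cross, meta$stage, meta$replicate)
  if (anyDuplicated(key)) {
    stop("(cross, stage, replicate) must be unique; duplicated: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  meta
}

#' Construct an expression matrix object
#'
#' Container pairing a genes-by-samples TPM matrix with its sample metadata.
#' Values must be non-negative, gene ids unique, and matrix columns must
#' match `meta$sample_id` exactly (order is aligned to the metadata).
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @return An object of class `expr_matrix`: a list with `values` and `meta`.
#' @export
expression_matrix <- function(values, meta) {
  meta <- validate_sample_meta(meta)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene ids as rownames", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    bad <- which(apply(values, 1, function(v) any(!is.finite(v)) || any(v < 0)))
    stop("Expression values must be finite and non-negative; offending gene(s): ",
         paste(head(rownames(values)[bad], 5), collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(meta$sample_id, colnames(values))
  extra_cols <- setdiff(colnames(values), meta$sample_id)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    stop("Sample mismatch between matrix and metadata; ",
         if (length(missing_cols) > 0)
           paste0("missing from matrix: ", paste(missing_cols, collapse = ", "), "; ")
         else "",
         if (length(extra_cols) > 0)
           paste0("unknown in metadata: ", paste(extra_cols, collapse = ", "))
         else "",
         call. = FALSE)
  }
  structure(list(values = values[, meta$sample_id, drop = FALSE], meta = meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("Crosses:", paste(unique(x$meta$cross), collapse = ", "), "\n")
  cat("Stages:", paste(unique(x$meta$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix with its sample metadata sidecar
#'
#' The expression TSV has a `gene_id` column followed by one column per
#' sample; the metadata TSV has one row per sample. Samples present in one
#' file but not the other are an error naming the sample.
#'
#' @param path Expression TSV path.
#' @param metadata_path Sample metadata TSV path.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, metadata_path) {
  tab <- read_tsv_quiet(path)
  require_columns(tab, "gene_id", "Expression table")
  if (anyDuplicated(tab$gene_id)) {
    stop("Duplicate gene_id in ", path, ": ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  values <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  rownames(values) <- tab$gene_id
  meta <- validate_sample_meta(read_tsv_quiet(metadata_path))
  expression_matrix(values, meta)
}

#' Write an expression matrix and its metadata sidecar
#'
#' @param x An [expression_matrix()] object.
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- tibble::as_tibble(x$values, rownames = "gene_id")
  write_tsv_na(tab, path)
  write_tsv_na(x$meta, metadata_path)
  invisible(x)
}

#' Transcripts-per-million from counts and effective lengths
#'
#' Length-normalizes counts to per-transcript rates and rescales the rates
#' to a library concentration of one million: `rate_i = count_i / efflen_i`,
#' `TPM_i = rate_i / sum(rate) * 1e6`. An all-zero count vector yields
#' all-zero TPM (not an error); otherwise the output sums to 1e6.
#'
#' @param counts Non-negative numeric vector.
#' @param effective_lengths Positive numeric vector, same length as `counts`.
#' @return Numeric TPM vector.
#' @export
tpm_from_counts <- function(counts, effective_lengths) {
  if (length(counts) != length(effective_lengths)) {
    stop("counts and effective_lengths must have equal length", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (any(effective_lengths <= 0) || any(!is.finite(effective_lengths))) {
    stop("effective_lengths must be finite and positive", call. = FALSE)
  }
  rate <- counts / effective_lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  rate / s * 1e6
}

#' Read a triad mapping table
#'
#' Format: `triad_id  gene_A  gene_B  gene_D`, one row per homoeolog triad.
#' `gene_D = NA` throughout signals two-genome mode (tetraploid crosses,
#' which carry only the A and B subgenomes). Each gene may appear in at most
#' one triad.
#'
#' @param path TSV path.
#' @return Tibble with columns `triad_id`, `gene_A`, `gene_B`, `gene_D`.
#' @export
read_triad_map <- function(path) {
  tab <- read_tsv_quiet(path)
  validate_triad_map(tab)
}

#' @rdname read_triad_map
#' @param triads A candidate triad map data frame.
#' @export
validate_triad_map <- function(triads) {
  require_columns(triads, c("triad_id", "gene_A", "gene_B"), "Triad map")
  triads <- tibble::as_tibble(triads)
  if (!"gene_D" %in% names(triads)) triads$gene_D <- NA_character_
  if (anyDuplicated(triads$triad_id)) {
    stop("Duplicate triad_id: ",
         paste(unique(triads$triad_id[duplicated(triads$triad_id)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  genes <- genes[!is.na(genes)]
  if (anyDuplicated(genes)) {
    stop("Gene(s) assigned to more than one triad: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(triads$gene_A)) || any(is.na(triads$gene_B))) {
    stop("gene_A and gene_B are required for every triad", call. = FALSE)
  }
  has_d <- !is.na(triads$gene_D)
  if (any(has_d) && !all(has_d)) {
    stop("gene_D must be present for all triads (three-genome mode) or none ",
         "(two-genome mode); mixed maps are not supported", call. = FALSE)
  }
  triads
}

#' Write a triad mapping table
#' @param triads Validated triad map tibble.
#' @param path Output TSV path.
#' @export
write_triad_map <- function(triads, path) {
  write_tsv_na(validate_triad_map(triads), path)
  invisible(triads)
}

#' Read a per-gene allele count table
#'
#' Format: `gene_id  cross  stage  tissue  replicate  maternal_reads
#' paternal_reads`. Counts are SNP-informative reads assigned to the maternal
#' or paternal allele of a gene in one replicate of one cross direction.
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_allele_counts <- function(path) {
  validate_allele_counts(read_tsv_quiet(path))
}

#' @rdname read_allele_counts
#' @param counts Candidate allele count data frame.
#' @export
validate_allele_counts <- function(counts) {
  require_columns(counts, c("gene_id", "cross", "stage", "tissue", "replicate",
                            "maternal_reads", "paternal_reads"),
                  "Allele count table")
  counts <- tibble::as_tibble(counts)
  bad <- counts$maternal_reads < 0 | counts$paternal_reads < 0 |
    counts$maternal_reads != round(counts$maternal_reads) |
    counts$paternal_reads != round(counts$paternal_reads)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("Allele counts must be non-negative integers; offending row: gene ",
         counts$gene_id[i], ", cross ", counts$cross[i], ", replicate ",
         counts$replicate[i], call. = FALSE)
  }
  if (!all(counts$tissue == tissue_for_stage(counts$stage))) {
    stop("Stage/tissue mismatch in allele count table", call. = FALSE)
  }
  key <- paste(counts$gene_id, counts$cross, counts$stage, counts$replicate)
  if (anyDuplicated(key)) {
    stop("(gene, cross, stage, replicate) must be unique; duplicated: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  counts
}

#' Write an allele count table
#' @param counts Validated allele count tibble.
#' @param path Output TSV path.
#' @export
write_allele_counts <- function(counts, path) {
  write_tsv_na(validate_allele_counts(counts), path)
  invisible(counts)
}

#' Read a transcript-level quantification table
#'
#' Accepts the `quant.sf` column dialect (`Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`) together with a transcript-to-gene mapping TSV with
#' columns `transcript_id` and `gene_id`. Every transcript must map to
#' exactly one gene.
#'
#' @param path Quantification TSV path.
#' @param tx2gene_path Mapping TSV path.
#' @param sample_id Sample identifier to attach to the records.
#' @return Tibble with columns `transcript_id`, `gene_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`, `sample_id`.
#' @export
read_transcript_quant <- function(path, tx2gene_path, sample_id) {
  quant <- read_tsv_quiet(path)
  require_columns(quant, c("Name", "Length", "EffectiveLength", "TPM", "NumReads"),
                  "Transcript quantification")
  map <- read_tsv_quiet(tx2gene_path)
  require_columns(map, c("transcript_id", "gene_id"), "tx2gene mapping")
  if (anyDuplicated(map$transcript_id)) {
    stop("tx2gene mapping assigns transcript(s) to more than one gene: ",
         paste(unique(map$transcript_id[duplicated(map$transcript_id)]),
               collapse = ", "), call. = FALSE)
  }
  unmapped <- setdiff(quant$Name, map$transcript_id)
  if (length(unmapped) > 0) {
    stop("Transcript(s) without a gene mapping: ",
         paste(head(unmapped, 5), collapse = ", "), call. = FALSE)
  }
  if (any(quant$EffectiveLength <= 0)) {
    stop("EffectiveLength must be positive", call. = FALSE)
  }
  if (any(quant$TPM < 0) || any(quant$NumReads < 0)) {
    stop("TPM and NumReads must be non-negative", call. = FALSE)
  }
  gene <- map$gene_id[match(quant$Name, map$transcript_id)]
  tibble::tibble(transcript_id = quant$Name,
                 gene_id = gene,
                 length = quant$Length,
                 effective_length = quant$EffectiveLength,
                 tpm = quant$TPM,
                 num_reads = quant$NumReads,
                 sample_id = sample_id)
}

#' Write a transcript quantification table in the quant.sf dialect
#'
#' @param quant Tibble as returned by [read_transcript_quant()] (a single
#'   sample).
#' @param path Output quantification TSV path.
#' @param tx2gene_path Optional path; when given, the transcript-to-gene
#'   mapping is written alongside.
#' @export
write_transcript_quant <- function(quant, path, tx2gene_path = NULL) {
  require_columns(quant, c("transcript_id", "gene_id", "length",
                           "effective_length", "tpm", "num_reads"),
                  "Transcript quantification")
  out <- tibble::tibble(Name = quant$transcript_id,
                        Length = quant$length,
                        EffectiveLength = quant$effective_length,
                        TPM = quant$tpm,
                        NumReads = quant$num_reads)
  write_tsv_na(out, path)
  if (!is.null(tx2gene_path)) {
    map <- unique(tibble::tibble(transcript_id = quant$transcript_id,
                                 gene_id = quant$gene_id))
    write_tsv_na(map, tx2gene_path)
  }
  invisible(quant)
}
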