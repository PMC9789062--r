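#' Expression-bias category centroids
#'
#' The canonical centroid compositions of the homoeolog expression-bias
#' categories, on the within-triad relative-expression simplex. In
#' three-genome mode (hexaploid/pentaploid samples) the seven categories are
#' balanced, A/B/D dominant and A/B/D suppressed; in two-genome mode
#' (tetraploid crosses, A and B subgenomes only) they are balanced and A/B
#' dominant. The balanced centroid uses exact thirds (halves in two-genome
#' mode) so the compositions sum to one.
#'
#' Row order is the canonical category order used for tie-breaking in
#' [classify_triad()].
#'
#' @param n_genomes 3 (default) or 2.
#' @return Numeric matrix, one centroid per row, rownames = category names.
#' @export
bias_centroids <- function(n_genomes = 3) {
  if (n_genomes == 3) {
    m <- rbind(Balanced     = c(1, 1, 1) / 3,
               A_dominant   = c(1, 0, 0),
               B_dominant   = c(0, 1, 0),
               D_dominant   = c(0, 0, 1),
               A_suppressed = c(0, 1, 1) / 2,
               B_suppressed = c(1, 0, 1) / 2,
               D_suppressed = c(1, 1, 0) / 2)
    colnames(m) <- c("A", "B", "D")
  } else if (n_genomes == 2) {
    m <- rbind(Balanced   = c(1, 1) / 2,
               A_dominant = c(1, 0),
               B_dominant = c(0, 1))
    colnames(m) <- c("A", "B")
  } else {
    stop("n_genomes must be 2 or 3", call. = FALSE)
  }
  m
}

#' Per-triad homoeolog expression fractions
#'
#' For each triad and sample, the relative contribution of each homoeolog to
#' total triad TPM. Triads whose total expression falls below `floor` in a
#' sample are marked undefined there (the composition of a silent triad is
#' meaningless).
#'
#' @param expr An [expression_matrix()] object.
#' @param triads A validated triad map (see [read_triad_map()]); `gene_D`
#'   all-`NA` selects two-genome mode.
#' @param floor Minimum total triad TPM for the fractions to be defined.
#'   Default 0.5.
#' @return Tibble with columns `triad_id`, `sample_id`, `frac_A`, `frac_B`,
#'   `frac_D` (`NA` in two-genome mode), `total_tpm`, `defined`.
#' @export
triad_fractions <- function(expr, triads, floor = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"))
  triads <- validate_triad_map(triads)
  two_genome <- all(is.na(triads$gene_D))
  needed <- c(triads$gene_A, triads$gene_B, if (!two_genome) triads$gene_D)
  missing <- setdiff(needed, rownames(expr$values))
  if (length(missing) > 0) {
    stop("Triad gene(s) missing from expression matrix: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  v <- expr$values
  a <- v[triads$gene_A, , drop = FALSE]
  b <- v[triads$gene_B, , drop = FALSE]
  d <- if (two_genome) a * 0 else v[triads$gene_D, , drop = FALSE]
  total <- a + b + d
  defined <- total >= floor & total > 0
  fa <- ifelse(defined, a / total, NA_real_)
  fb <- ifelse(defined, b / total, NA_real_)
  fd <- if (two_genome) NA_real_ else ifelse(defined, d / total, NA_real_)
  n_s <- ncol(v)
  tibble::tibble(
    triad_id = rep(triads$triad_id, times = n_s),
    sample_id = rep(colnames(v), each = nrow(triads)),
    frac_A = as.vector(fa),
    frac_B = as.vector(fb),
    frac_D = if (two_genome) NA_real_ else as.vector(fd),
    total_tpm = as.vector(total),
    defined = as.vector(defined))
}

#' Average replicate fractions within (cross, stage)
#'
#' Collapses per-replicate triad fractions to one composition per triad and
#' (cross, stage) group by averaging the defined replicate compositions
#' (the mean of compositions is itself a composition). A triad is defined in
#' the collapsed set when it is defined in at least one replicate.
#'
#' @param fractions Output of [triad_fractions()].
#' @param meta Sample metadata matching the sample ids in `fractions`.
#' @return Tibble in the same shape as [triad_fractions()], with synthetic
#'   `sample_id = "<cross>_<stage>"` and columns `cross` and `stage`.
#' @export
average_replicate_fractions <- function(fractions, meta) {
  meta <- validate_sample_meta(meta)
  unknown <- setdiff(unique(fractions$sample_id), meta$sample_id)
  if (length(unknown) > 0) {
    stop("Sample(s) missing from metadata: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fractions |>
    dplyr::left_join(meta[, c("sample_id", "cross", "stage")], by = "sample_id") |>
    dplyr::group_by(.data$triad_id, .data$cross, .data$stage) |>
    dplyr::summarise(
      frac_A = mean(.data$frac_A[.data$defined]),
      frac_B = mean(.data$frac_B[.data$defined]),
      frac_D = mean(.data$frac_D[.data$defined]),
      total_tpm = mean(.data$total_tpm),
      defined = any(.data$defined),
      .groups = "drop") |>
    dplyr::mutate(
      sample_id = paste(.data$cross, .data$stage, sep = "_"),
      frac_A = ifelse(.data$defined, .data$frac_A, NA_real_),
      frac_B = ifelse(.data$defined, .data$frac_B, NA_real_),
      frac_D = ifelse(.data$defined, .data$frac_D, NA_real_)) |>
    dplyr::select("triad_id", "sample_id", "cross", "stage",
                  "frac_A", "frac_B", "frac_D", "total_tpm", "defined")
}

#' Classify one composition into an expression-bias category
#'
#' Nearest-centroid assignment: the Euclidean distance from the composition
#' to every category centroid is computed and the closest category wins.
#' Exact ties are broken by the canonical category order of
#' [bias_centroids()] (balanced first, then dominant, then suppressed).
#'
#' @param fraction Numeric composition vector of length 3 (or 2 in two-genome
#'   mode); must sum to 1 within `1e-6`.
#' @param centroids Centroid matrix; defaults to [bias_centroids()] of
#'   matching dimension.
#' @return The category name (character scalar).
#' @examples
#' classify_triad(c(1, 1, 1) / 3)        # "Balanced"
#' classify_triad(c(0.5, 0.5, 0))        # "D_suppressed"
#' classify_triad(c(0.70, 0.15, 0.15))   # "A_dominant"
#' @export
classify_triad <- function(fraction, centroids = bias_centroids(length(fraction))) {
  if (any(is.na(fraction))) {
    stop("classify_triad() requires a defined composition", call. = FALSE)
  }
  if (length(fraction) != ncol(centroids)) {
    stop("Composition length does not match the centroid set", call. = FALSE)
  }
  if (abs(sum(fraction) - 1) > 1e-6) {
    stop("Composition must sum to 1 (got ", format(sum(fraction)), ")",
         call. = FALSE)
  }
  d2 <- rowSums(sweep(centroids, 2, fraction)^2)
  # Ties (within floating-point tolerance) resolve to the earliest category
  # in canonical order.
  rownames(centroids)[which(d2 <= min(d2) + 1e-9)[1]]
}

#' Classify every defined triad composition
#'
#' Applies [classify_triad()] to a table of per-triad compositions and
#' summarises per-sample category counts and percentages (undefined triads
#' are excluded from the percentages).
#'
#' @param fractions Output of [triad_fractions()] or
#'   [average_replicate_fractions()].
#' @param centroids Optional centroid matrix; inferred from the data
#'   (two- vs three-genome) when `NULL`.
#' @return A list with `calls` (tibble `triad_id`, `sample_id`, `category`;
#'   `NA` category for undefined triads) and `summary` (tibble `sample_id`,
#'   `category`, `n`, `percent`).
#' @export
classify_all <- function(fractions, centroids = NULL) {
  two_genome <- all(is.na(fractions$frac_D))
  if (is.null(centroids)) centroids <- bias_centroids(if (two_genome) 2 else 3)
  comp <- if (two_genome) {
    cbind(fractions$frac_A, fractions$frac_B)
  } else {
    cbind(fractions$frac_A, fractions$frac_B, fractions$frac_D)
  }
  category <- rep(NA_character_, nrow(fractions))
  idx <- which(fractions$defined)
  if (length(idx) == 0) {
    warning("No defined triad compositions to classify", call. = FALSE)
  } else {
    # Vectorized nearest-centroid over all defined rows at once.
    x <- comp[idx, , drop = FALSE]
    bad <- abs(rowSums(x) - 1) > 1e-6
    if (any(bad)) {
      stop("Defined composition(s) not summing to 1; first offending triad: ",
           fractions$triad_id[idx[which(bad)[1]]], call. = FALSE)
    }
    d2 <- sapply(seq_len(nrow(centroids)), function(k) {
      rowSums(sweep(x, 2, centroids[k, ])^2)
    })
    if (length(idx) == 1) d2 <- matrix(d2, nrow = 1)
    category[idx] <- rownames(centroids)[
      apply(d2, 1, function(d) which(d <= min(d) + 1e-9)[1])]
  }
  calls <- tibble::tibble(triad_id = fractions$triad_id,
                          sample_id = fractions$sample_id,
                          category = category)
  summary <- calls |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::count(.data$sample_id, .data$category, name = "n") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(calls = calls, summary = summary)
}

#' Category transition table between two call sets
#'
#' Cross-tabulates the bias category of each triad in two call sets (for
#' example the two directions of a reciprocal cross at the same stage),
#' counting only triads defined in both; triads undefined in either set are
#' tallied separately.
#'
#' @param calls_a,calls_b Call tibbles (`triad_id`, `category`) for a single
#'   sample each, e.g. one element of [classify_all()]'s `calls` split by
#'   sample.
#' @return A list with `counts` (matrix, rows = from-category in `calls_a`,
#'   columns = to-category in `calls_b`), `n_both_defined`, and `undefined`
#'   (named counts of triads undefined in a only, b only, or both).
#' @export
transition_table <- function(calls_a, calls_b) {
  shared <- intersect(calls_a$triad_id, calls_b$triad_id)
  if (length(shared) == 0) {
    stop("transition_table() requires a shared triad universe", call. = FALSE)
  }
  a <- calls_a$category[match(shared, calls_a$triad_id)]
  b <- calls_b$category[match(shared, calls_b$triad_id)]
  # Two-genome categories are a subset of the canonical seven.
  levels <- rownames(bias_centroids(3))
  both <- !is.na(a) & !is.na(b)
  counts <- table(factor(a[both], levels = levels),
                  factor(b[both], levels = levels))
  counts <- unclass(counts)
  dimnames(counts) <- list(from = levels, to = levels)
  list(counts = counts,
       n_both_defined = sum(both),
       undefined = c(a_only = sum(is.na(a) & !is.na(b)),
                     b_only = sum(!is.na(a) & is.na(b)),
                     both = sum(is.na(a) & is.na(b))))
}

#' Mean subgenome contribution per sample
#'
#' Arithmetic mean of the defined triad fractions, per subgenome and sample,
#' expressed as percentages (summing to 100 over subgenomes).
#'
#' @param fractions Output of [triad_fractions()] or
#'   [average_replicate_fractions()].
#' @return Tibble with columns `sample_id`, `subgenome`, `mean_percent`.
#' @export
subgenome_contribution <- function(fractions) {
  two_genome <- all(is.na(fractions$frac_D))
  long <- fractions |>
    dplyr::filter(.data$defined) |>
    dplyr::select("sample_id", "frac_A", "frac_B", "frac_D") |>
    tidyr::pivot_longer(cols = c("frac_A", "frac_B", "frac_D"),
                        names_to = "subgenome", values_to = "fraction",
                        names_prefix = "frac_")
  if (two_genome) long <- dplyr::filter(long, .data$subgenome != "D")
  long |>
    dplyr::group_by(.data$sample_id, .data$subgenome) |>
    dplyr::summarise(mean_percent = 100 * mean(.data$fraction), .groups = "drop")
}
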