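# Synthetic-data generator emulating the data structure of a reciprocal
# interploidy wheat cross experiment: negative-binomial homoeolog counts with
# planted bias categories, binomial maternal/paternal allele counts with
# tissue dosage (1:1 embryo, 2:1 endosperm) and planted MEGs/PEGs, and
# isoform quantifications with planted PSI shifts. Two biological replicates
# per sample is the default, matching the study design being emulated.
#
# Each sub-simulation draws from its own seed sub-stream (config seed plus a
# fixed documented offset: triads +101, allele counts +202, isoforms +303) so
# adding one stage never perturbs the draws of another.

#' Simulation configuration
#'
#' Parameters and planted ground-truth settings for the synthetic-data
#' generator. Defaults emulate a pentaploid embryo sample pair: category
#' proportions with a balanced majority and a large D-suppressed class (the
#' univalent D genome), negative-binomial counts with bulk-RNA-seq-typical
#' overdispersion, Poisson/binomial allele counts at 100x SNP-read depth,
#' and isoform quantifications with a planted PSI shift of 0.3.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_triads Number of homoeolog triads.
#' @param category_proportions Named numeric vector over bias categories,
#'   summing to 1. The default approximates a pentaploid embryo: 50%
#'   balanced, 28% D suppressed, modest A/B dominance; its mixture-weighted
#'   centroid mean puts the A and B subgenomes near 40% and D near 20% of
#'   triad expression.
#' @param triad_total_tpm_mean Mean total TPM of a triad (Gamma-distributed
#'   across triads, shape 2).
#' @param nb_dispersion Negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2). Default 0.05, typical bulk RNA-seq
#'   overdispersion.
#' @param n_replicates Biological replicates per sample. Default 2.
#' @param stages Stages to simulate (subset of E1..E9).
#' @param cross_pair Labels of the forward and reverse cross.
#' @param n_genes_ase Number of genes in the allele-specific count
#'   simulation.
#' @param frac_meg,frac_peg Fractions of `n_genes_ase` planted as MEGs and
#'   PEGs (`frac_meg + frac_peg <= 1`).
#' @param imprint_strength Maternal read fraction of a planted MEG (and
#'   paternal fraction of a planted PEG), in (0.5, 1].
#' @param ase_depth_mean Mean SNP-informative read depth per gene, replicate
#'   and cross direction (Poisson).
#' @param n_isoforms Target number of isoforms in the splicing simulation
#'   (genes of 2-4 isoforms are drawn until the target is reached).
#' @param n_das_isoforms Number of isoforms with a planted PSI shift.
#' @param delta_psi_planted Magnitude of the planted PSI shift, in (0, 1].
#' @param psi_noise_sdlog Standard deviation (log scale) of the
#'   multiplicative lognormal noise on per-replicate isoform TPM.
#'   Default 0.15.
#' @param dirichlet_conc Symmetric Dirichlet concentration for baseline
#'   isoform PSI within a gene. Default 1.5 (broad, mildly interior).
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_triads = 2000L,
                              category_proportions = c(
                                Balanced = 0.50, A_dominant = 0.07,
                                B_dominant = 0.07, D_dominant = 0.01,
                                A_suppressed = 0.03, B_suppressed = 0.04,
                                D_suppressed = 0.28),
                              triad_total_tpm_mean = 300,
                              nb_dispersion = 0.05,
                              n_replicates = 2L,
                              stages = "E3",
                              cross_pair = c("AxC", "CxA"),
                              n_genes_ase = 5000L,
                              frac_meg = 0.01,
                              frac_peg = 0.01,
                              imprint_strength = 0.95,
                              ase_depth_mean = 100,
                              n_isoforms = 2000L,
                              n_das_isoforms = 100L,
                              delta_psi_planted = 0.3,
                              psi_noise_sdlog = 0.15,
                              dirichlet_conc = 1.5) {
  cfg <- list(seed = as.integer(seed), n_triads = as.integer(n_triads),
              category_proportions = category_proportions,
              triad_total_tpm_mean = triad_total_tpm_mean,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              stages = stages, cross_pair = cross_pair,
              n_genes_ase = as.integer(n_genes_ase),
              frac_meg = frac_meg, frac_peg = frac_peg,
              imprint_strength = imprint_strength,
              ase_depth_mean = ase_depth_mean,
              n_isoforms = as.integer(n_isoforms),
              n_das_isoforms = as.integer(n_das_isoforms),
              delta_psi_planted = delta_psi_planted,
              psi_noise_sdlog = psi_noise_sdlog,
              dirichlet_conc = dirichlet_conc)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  cats <- rownames(bias_centroids(3))
  p <- cfg$category_proportions
  if (is.null(names(p)) || !all(names(p) %in% cats)) {
    stop("category_proportions must be named by bias categories (",
         paste(cats, collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("category_proportions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  }
  if (any(p < 0)) stop("category_proportions must be non-negative", call. = FALSE)
  if (cfg$frac_meg < 0 || cfg$frac_peg < 0 || cfg$frac_meg + cfg$frac_peg > 1) {
    stop("frac_meg and frac_peg must be non-negative with sum <= 1",
         call. = FALSE)
  }
  if (cfg$imprint_strength <= 0.5 || cfg$imprint_strength > 1) {
    stop("imprint_strength must lie in (0.5, 1]", call. = FALSE)
  }
  if (!all(cfg$stages %in% ALL_STAGES)) {
    stop("stages must be a subset of E1..E9", call. = FALSE)
  }
  if (length(cfg$cross_pair) != 2 || anyDuplicated(cfg$cross_pair)) {
    stop("cross_pair must be two distinct cross labels", call. = FALSE)
  }
  if (cfg$n_triads < 1 || cfg$triad_total_tpm_mean <= 0 ||
      cfg$nb_dispersion <= 0 || cfg$n_replicates < 1 ||
      cfg$ase_depth_mean <= 0) {
    stop("Counts, means and dispersion must be positive", call. = FALSE)
  }
  if (cfg$delta_psi_planted <= 0 || cfg$delta_psi_planted > 1) {
    stop("delta_psi_planted must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

sim_parents <- function(cross) {
  # Cross labels are "<maternal>x<paternal>" single-letter variety codes.
  parts <- strsplit(cross, "x", fixed = TRUE)[[1]]
  if (length(parts) != 2) parts <- c(substr(cross, 1, 1), substr(cross, nchar(cross), nchar(cross)))
  parts
}

sim_sample_meta <- function(cfg) {
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      stage = cfg$stages,
                      cross = cfg$cross_pair,
                      stringsAsFactors = FALSE)
  parents <- t(vapply(grid$cross, sim_parents, character(2)))
  # The forward cross is taken as hexaploid mother x tetraploid father and
  # the reverse as its reciprocal; ploidies are metadata only and do not
  # drive the triad simulation.
  mat_ploidy <- ifelse(grid$cross == cfg$cross_pair[1], 6L, 4L)
  validate_sample_meta(tibble::tibble(
    sample_id = paste(grid$cross, grid$stage, paste0("r", grid$replicate),
                      sep = "_"),
    cross = grid$cross,
    maternal_parent = parents[, 1],
    paternal_parent = parents[, 2],
    maternal_ploidy = mat_ploidy,
    paternal_ploidy = ifelse(mat_ploidy == 6L, 4L, 6L),
    tissue = tissue_for_stage(grid$stage),
    stage = grid$stage,
    replicate = as.integer(grid$replicate)))
}

#' Simulate a triad expression matrix with planted bias categories
#'
#' Each triad draws a bias category from `category_proportions` and a total
#' expression level `T ~ Gamma(shape 2, mean triad_total_tpm_mean)`; its
#' three homoeolog means are `T` times the category centroid components.
#' Per-sample counts are negative binomial with dispersion `nb_dispersion`
#' and are converted to TPM at unit effective length. The planted category is
#' shared by all samples, so both cross directions carry the same truth.
#'
#' @param config A [simulation_config()].
#' @return A list: `expr` ([expression_matrix()]), `triads` (triad map
#'   tibble), `truth` (tibble `triad_id`, `category`).
#' @export
simulate_triads <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 101L)
  cents <- bias_centroids(3)
  props <- cfg$category_proportions
  cats <- sample(names(props), cfg$n_triads, replace = TRUE, prob = props)
  total <- rgamma(cfg$n_triads, shape = 2, rate = 2 / cfg$triad_total_tpm_mean)
  mu <- cents[cats, , drop = FALSE] * total   # n_triads x 3 homoeolog means
  triad_id <- sprintf("triad%05d", seq_len(cfg$n_triads))
  triads <- tibble::tibble(triad_id = triad_id,
                           gene_A = paste0(triad_id, "_A"),
                           gene_B = paste0(triad_id, "_B"),
                           gene_D = paste0(triad_id, "_D"))
  gene_ids <- as.vector(t(cbind(triads$gene_A, triads$gene_B, triads$gene_D)))
  mu_gene <- as.vector(t(mu))                 # A, B, D per triad, row-major
  meta <- sim_sample_meta(cfg)
  size <- 1 / cfg$nb_dispersion
  counts <- vapply(seq_len(nrow(meta)), function(i) {
    rnbinom(length(mu_gene), mu = mu_gene, size = size)
  }, numeric(length(mu_gene)))
  tpm <- apply(counts, 2, tpm_from_counts,
               effective_lengths = rep(1, length(mu_gene)))
  rownames(tpm) <- gene_ids
  colnames(tpm) <- meta$sample_id
  list(expr = expression_matrix(tpm, meta),
       triads = triads,
       truth = tibble::tibble(triad_id = triad_id, category = cats))
}

#' Simulate allele-specific counts for a reciprocal cross pair
#'
#' Per gene, cross direction, stage and replicate: total SNP-informative
#' reads are Poisson(`ase_depth_mean`) and maternal reads are binomial with
#' maternal probability `p` set by the tissue dosage for unimprinted genes
#' (0.5 in embryo, 2/3 in the triploid endosperm), `imprint_strength` for
#' planted MEGs and `1 - imprint_strength` for planted PEGs. `p` is defined
#' relative to the maternal allele, so although the parents swap roles
#' between the two cross directions, a planted MEG is maternal-biased in
#' both directions.
#'
#' @param config A [simulation_config()].
#' @return A list: `counts` (allele count tibble covering both cross
#'   directions) and `truth` (tibble `gene_id`, `status` in
#'   MEG/PEG/not_imprinted).
#' @export
simulate_allele_counts <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 202L)
  n <- cfg$n_genes_ase
  gene_id <- sprintf("aseg%05d", seq_len(n))
  n_meg <- round(cfg$frac_meg * n)
  n_peg <- round(cfg$frac_peg * n)
  status <- rep("not_imprinted", n)
  planted <- sample(n, n_meg + n_peg)
  status[planted[seq_len(n_meg)]] <- "MEG"
  if (n_peg > 0) status[planted[n_meg + seq_len(n_peg)]] <- "PEG"
  grid <- expand.grid(gene_idx = seq_len(n),
                      replicate = seq_len(cfg$n_replicates),
                      stage = cfg$stages,
                      cross = cfg$cross_pair,
                      stringsAsFactors = FALSE)
  tissue <- tissue_for_stage(grid$stage)
  base_p <- ifelse(tissue == "embryo", 0.5, 2 / 3)
  g_status <- status[grid$gene_idx]
  p <- ifelse(g_status == "MEG", cfg$imprint_strength,
              ifelse(g_status == "PEG", 1 - cfg$imprint_strength, base_p))
  total <- rpois(nrow(grid), cfg$ase_depth_mean)
  maternal <- rbinom(nrow(grid), total, p)
  counts <- tibble::tibble(gene_id = gene_id[grid$gene_idx],
                           cross = grid$cross,
                           stage = grid$stage,
                           tissue = tissue,
                           replicate = as.integer(grid$replicate),
                           maternal_reads = maternal,
                           paternal_reads = total - maternal)
  list(counts = validate_allele_counts(counts),
       truth = tibble::tibble(gene_id = gene_id, status = status))
}

rdirichlet_one <- function(k, conc) {
  g <- rgamma(k, shape = conc)
  while (sum(g) == 0) g <- rgamma(k, shape = conc)
  g / sum(g)
}

#' Simulate isoform quantifications with planted PSI shifts
#'
#' Genes carry 2-4 isoforms with baseline PSI from a symmetric Dirichlet.
#' For `n_das_isoforms` target isoforms (one per selected gene) the PSI is
#' shifted by `delta_psi_planted` in the second group — upward when there is
#' headroom, downward otherwise — and the gene's remaining isoforms are
#' renormalized, so their induced shifts are also recorded in the truth
#' table. Per-replicate isoform TPM is gene TPM x PSI x multiplicative
#' lognormal noise.
#'
#' @param config A [simulation_config()].
#' @return A list: `quant` (transcript quantification tibble over all
#'   samples of both groups, with `sample_id = "<cross>_r<rep>"`), `groups`
#'   (named list mapping each cross label to its sample ids), and `truth`
#'   (tibble `isoform_id`, `gene_id`, `planted_delta`, `is_target`).
#' @export
simulate_isoform_quants <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed + 303L)
  # Draw gene sizes (2-4 isoforms) until the isoform target is reached.
  sizes <- integer(0)
  while (sum(sizes) < cfg$n_isoforms) {
    sizes <- c(sizes, sample(2:4, 64, replace = TRUE))
  }
  sizes <- sizes[cumsum(sizes) - sizes < cfg$n_isoforms]
  n_genes <- length(sizes)
  gene_id <- sprintf("asgene%04d", seq_len(n_genes))
  psi1 <- lapply(sizes, rdirichlet_one, conc = cfg$dirichlet_conc)
  psi2 <- psi1
  if (cfg$n_das_isoforms > n_genes) {
    stop("n_das_isoforms exceeds the number of simulated genes", call. = FALSE)
  }
  das_genes <- sample(n_genes, cfg$n_das_isoforms)
  target_iso <- integer(n_genes)
  for (g in das_genes) {
    k <- sample(sizes[g], 1)
    target_iso[g] <- k
    old <- psi1[[g]][k]
    delta <- cfg$delta_psi_planted
    new <- if (old + delta <= 1) old + delta else old - delta
    if (new < 0 || new > 1) {   # reachable only for delta > 0.5
      warning("Planted PSI shift clipped for gene ", gene_id[g], call. = FALSE)
      new <- min(max(new, 0), 1)
    }
    v <- psi1[[g]]
    if (old < 1) {
      v <- v * (1 - new) / (1 - old)
    } else {
      v <- rep((1 - new) / (length(v) - 1), length(v))
    }
    v[k] <- new
    psi2[[g]] <- v
  }
  gene_tpm <- rlnorm(n_genes, meanlog = log(50), sdlog = 1)
  iso_gene <- rep(seq_len(n_genes), sizes)
  isoform_id <- paste0(gene_id[iso_gene], ".", unlist(lapply(sizes, seq_len)))
  efflen <- round(runif(length(isoform_id), 800, 3000))
  psi1_v <- unlist(psi1)
  psi2_v <- unlist(psi2)
  truth <- tibble::tibble(
    isoform_id = isoform_id,
    gene_id = gene_id[iso_gene],
    planted_delta = psi2_v - psi1_v,
    is_target = unlist(lapply(seq_len(n_genes), function(g) {
      seq_len(sizes[g]) == target_iso[g]
    })))
  groups <- lapply(cfg$cross_pair, function(cr) {
    paste0(cr, "_r", seq_len(cfg$n_replicates))
  })
  names(groups) <- cfg$cross_pair
  quant <- dplyr::bind_rows(lapply(cfg$cross_pair, function(cr) {
    psi_v <- if (cr == cfg$cross_pair[1]) psi1_v else psi2_v
    dplyr::bind_rows(lapply(seq_len(cfg$n_replicates), function(r) {
      noise <- exp(rnorm(length(isoform_id), 0, cfg$psi_noise_sdlog))
      tpm <- gene_tpm[iso_gene] * psi_v * noise
      tibble::tibble(transcript_id = isoform_id,
                     gene_id = gene_id[iso_gene],
                     length = efflen + 200,
                     effective_length = efflen,
                     tpm = tpm,
                     num_reads = tpm * efflen / 1000,
                     sample_id = paste0(cr, "_r", r))
    }))
  }))
  list(quant = quant, groups = groups, truth = truth)
}

#' Write every simulated table of a configuration to a directory
#'
#' Runs all three simulators and writes the tables in the package's TSV
#' dialects, together with `truth_*.tsv` ground-truth tables.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all_tables <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tri <- simulate_triads(config)
  ase <- simulate_allele_counts(config)
  iso <- simulate_isoform_quants(config)
  write_expression_matrix(tri$expr,
                          file.path(outdir, "expression.tsv"),
                          file.path(outdir, "samples.tsv"))
  write_triad_map(tri$triads, file.path(outdir, "triads.tsv"))
  write_tsv_na(tri$truth, file.path(outdir, "truth_triads.tsv"))
  write_allele_counts(ase$counts, file.path(outdir, "allele_counts.tsv"))
  write_tsv_na(ase$truth, file.path(outdir, "truth_imprinting.tsv"))
  for (s in unique(iso$quant$sample_id)) {
    write_transcript_quant(iso$quant[iso$quant$sample_id == s, ],
                           file.path(outdir, paste0("quant_", s, ".sf")),
                           file.path(outdir, "tx2gene.tsv"))
  }
  write_tsv_na(iso$truth, file.path(outdir, "truth_isoforms.tsv"))
  invisible(list(triads = tri, allele = ase, isoforms = iso))
}
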