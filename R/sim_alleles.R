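#' Parameters for the allele-count table simulator
#'
#' Emulates allele-specific counting in a female diploid line with a
#' transcriptionally silenced X: autosomal genes are biallelic (expected
#' a-allele proportion 0.5), X-inactivated genes are strongly skewed to the
#' active 'a' haplotype, and escape genes remain biallelic. A DNA
#' validation library is generated alongside, with a planted set of SNPs
#' whose allelic proportion is shifted (emulating genotyping/mapping
#' artifacts) so the SNP bias filter has known positives.
#'
#' @param n_genes named integer vector: genes per class
#'   (`autosome`, `x_inactivated`, `x_escape`).
#' @param mean_total_count mean allele-informative reads per gene and
#'   library.
#' @param dispersion negative-binomial dispersion of gene totals
#'   (`var = mu + dispersion * mu^2`).
#' @param p_a named numeric vector: expected 'a' proportion per class.
#' @param n_snps_per_gene SNPs per gene.
#' @param n_biased_snps SNPs (drawn across all genes) planted with a
#'   shifted DNA allelic proportion.
#' @param biased_shift absolute shift of the planted SNPs' DNA proportion
#'   away from 0.5 (alternating sign).
#' @param dna_depth reads per SNP in the DNA validation library.
#' @return list of class `allele_sim_params`.
#' @export
allele_sim_params <- function(n_genes = c(autosome = 200L,
                                          x_inactivated = 150L,
                                          x_escape = 4L),
                              mean_total_count = 200,
                              dispersion = 0.05,
                              p_a = c(autosome = 0.5,
                                      x_inactivated = 0.95,
                                      x_escape = 0.5),
                              n_snps_per_gene = 3L,
                              n_biased_snps = 20L,
                              biased_shift = 0.4,
                              dna_depth = 1000L) {
  stopifnot(all(n_genes >= 0), mean_total_count > 0, dispersion >= 0,
            all(p_a >= 0 & p_a <= 1), n_snps_per_gene >= 1,
            n_biased_snps >= 0, biased_shift >= 0, biased_shift <= 0.5,
            dna_depth >= 1)
  structure(list(n_genes = n_genes, mean_total_count = mean_total_count,
                 dispersion = dispersion, p_a = p_a,
                 n_snps_per_gene = as.integer(n_snps_per_gene),
                 n_biased_snps = as.integer(n_biased_snps),
                 biased_shift = biased_shift,
                 dna_depth = as.integer(dna_depth)),
            class = "allele_sim_params")
}

# gene universe shared by the DNA and expression tables
.allele_gene_map <- function(params) {
  classes <- rep(names(params$n_genes), params$n_genes)
  n <- length(classes)
  if (n == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      class = character(), p_a = numeric()))
  chrom <- ifelse(classes == "autosome",
                  paste0("chr", 1 + (seq_len(n) %% 7)), "chrX")
  data.frame(gene = sprintf("G%04d", seq_len(n)), chrom = chrom,
             class = classes, p_a = unname(params$p_a[classes]))
}

#' Simulate DNA-validation SNP counts and allele-count libraries
#'
#' The DNA table draws each SNP's a-count as binomial at proportion 0.5
#' (planted biased SNPs at `0.5 +/- biased_shift`). Each expression-like
#' library draws one negative-binomial total per gene, splits it uniformly
#' across the gene's SNPs (multinomial), and splits each SNP's reads into
#' a/b alleles binomially at the gene class proportion; the per-SNP counts
#' within a gene therefore sum exactly to the emitted gene total.
#'
#' @param params an [allele_sim_params()].
#' @param n_replicates libraries to generate.
#' @param seed integer seed.
#' @param condition condition label stored in the libraries.
#' @param assay assay label.
#' @param p_a_override optional named vector overriding class proportions
#'   (used e.g. to model reactivation in a perturbed condition).
#' @param reactivated_genes optional character vector of gene ids whose
#'   proportion is set to `p_a_reactivated` in this condition.
#' @param p_a_reactivated proportion used for `reactivated_genes`.
#' @return list: `genes` (gene map with ground-truth class and proportion),
#'   `dna` (per-SNP DNA counts with `is_biased` truth), `snp_counts` (long
#'   per-SNP per-library counts), `gene_totals` (long per-gene totals as
#'   emitted).
#' @export
sim_allele_tables <- function(params, n_replicates, seed = 1L,
                              condition = "control", assay = "RNA",
                              p_a_override = NULL,
                              reactivated_genes = NULL,
                              p_a_reactivated = 0.6) {
  stopifnot(inherits(params, "allele_sim_params"), n_replicates >= 0)
  set.seed(seed)
  genes <- .allele_gene_map(params)
  if (!is.null(p_a_override))
    genes$p_a <- unname(p_a_override[genes$class])
  if (!is.null(reactivated_genes))
    genes$p_a[genes$gene %in% reactivated_genes] <- p_a_reactivated

  nsnp <- params$n_snps_per_gene
  snps <- if (nrow(genes) == 0L)
    data.frame(chrom = character(), pos = integer(), gene = character())
  else
    data.frame(chrom = rep(genes$chrom, each = nsnp),
               pos = as.integer(seq_len(nrow(genes) * nsnp) * 1000L),
               gene = rep(genes$gene, each = nsnp))

  n_snps <- nrow(snps)
  is_biased <- rep(FALSE, n_snps)
  if (n_snps > 0L && params$n_biased_snps > 0L) {
    idx <- sample.int(n_snps, min(params$n_biased_snps, n_snps))
    is_biased[idx] <- TRUE
  }
  p_dna <- rep(0.5, n_snps)
  if (any(is_biased)) {
    sgn <- rep(c(1, -1), length.out = sum(is_biased))
    p_dna[is_biased] <- 0.5 + sgn * params$biased_shift
  }
  dna <- snps
  dna$a_count <- rbinom(n_snps, params$dna_depth, p_dna)
  dna$b_count <- params$dna_depth - dna$a_count
  dna$is_biased <- is_biased

  size <- if (params$dispersion > 0) 1 / params$dispersion else Inf
  snp_counts <- list()
  gene_totals <- list()
  for (r in seq_len(n_replicates)) {
    tot <- if (nrow(genes) == 0L) integer(0)
    else if (is.finite(size))
      rnbinom(nrow(genes), mu = params$mean_total_count, size = size)
    else rpois(nrow(genes), params$mean_total_count)
    sc <- snps
    sc$a_count <- numeric(nrow(sc))
    sc$b_count <- numeric(nrow(sc))
    for (g in seq_len(nrow(genes))) {
      rows <- seq.int((g - 1L) * nsnp + 1L, g * nsnp)
      per_snp <- as.integer(rmultinom(1L, tot[g], rep(1, nsnp)))
      a <- rbinom(nsnp, per_snp, genes$p_a[g])
      sc$a_count[rows] <- a
      sc$b_count[rows] <- per_snp - a
    }
    sc$assay <- rep(assay, nrow(sc))
    sc$condition <- rep(condition, nrow(sc))
    sc$replicate <- rep(r, nrow(sc))
    snp_counts[[r]] <- sc
    gene_totals[[r]] <- data.frame(gene = genes$gene, total = tot,
                                   condition = rep(condition, nrow(genes)),
                                   replicate = rep(r, nrow(genes)))
  }
  empty_counts <- snps[0, , drop = FALSE]
  empty_counts$a_count <- numeric(0)
  empty_counts$b_count <- numeric(0)
  empty_counts$assay <- character(0)
  empty_counts$condition <- character(0)
  empty_counts$replicate <- integer(0)
  list(genes = genes, dna = dna,
       snp_counts = if (length(snp_counts)) do.call(rbind, snp_counts)
       else empty_counts,
       gene_totals = if (length(gene_totals)) do.call(rbind, gene_totals)
       else data.frame(gene = character(), total = integer()))
}

#' Simulate a paired reactivation experiment
#'
#' Generates matched control and perturbed conditions from one gene
#' universe and one DNA library; a chosen number of X-inactivated genes are
#' "reactivated" in the perturbed condition (their a-proportion moves from
#' the silenced skew towards biallelic).
#'
#' @param params an [allele_sim_params()].
#' @param n_reactivated number of X-inactivated genes reactivated in the
#'   perturbed condition.
#' @param n_replicates libraries per condition.
#' @param seed integer seed.
#' @param p_a_reactivated perturbed-condition proportion of reactivated
#'   genes.
#' @return list: `genes`, `dna`, `control`, `perturbed` (long per-SNP count
#'   tables), `reactivated_genes` (ground truth).
#' @export
sim_reactivation_experiment <- function(params, n_reactivated = 0L,
                                        n_replicates = 2L, seed = 1L,
                                        p_a_reactivated = 0.6) {
  base <- sim_allele_tables(params, n_replicates, seed = seed,
                            condition = "control")
  xi_genes <- base$genes$gene[base$genes$class == "x_inactivated"]
  react <- head(xi_genes, n_reactivated)
  pert <- sim_allele_tables(params, n_replicates, seed = seed + 1L,
                            condition = "perturbed",
                            reactivated_genes = react,
                            p_a_reactivated = p_a_reactivated)
  list(genes = base$genes, dna = base$dna,
       control = base$snp_counts, perturbed = pert$snp_counts,
       reactivated_genes = react)
}
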