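#' Filter SNPs on DNA-validation counts
#'
#' Two-step filter on a per-SNP table of a/b read counts from a DNA
#' sequencing library: (1) drop SNPs with zero counts for either allele;
#' (2) compute each remaining SNP's allelic bias `a / (a + b)` and drop
#' SNPs whose bias deviates from the mean bias by more than one standard
#' deviation, with mean and SD computed over the zero-filtered set (sample
#' SD). With zero SD (all biases identical) nothing is removed at step 2.
#'
#' @param snps data.frame with columns `chrom`, `pos` (1-based), `gene`,
#'   `a_count`, `b_count`.
#' @return list of class `snp_filter`: `snps` (retained rows, with a `bias`
#'   column) and `report` (`n_input`, `n_removed_zero`, `n_removed_bias`,
#'   `n_retained`, `mean_bias`, `sd_bias`).
#' @export
filter_snps <- function(snps) {
  if (nrow(snps) == 0L) stop("empty SNP table")
  stopifnot(all(c("a_count", "b_count") %in% names(snps)),
            all(snps$a_count >= 0), all(snps$b_count >= 0))
  if (nrow(snps) < 2L) stop("need at least 2 SNPs for the SD filter")
  nz <- snps$a_count > 0 & snps$b_count > 0
  kept <- snps[nz, , drop = FALSE]
  kept$bias <- kept$a_count / (kept$a_count + kept$b_count)
  m <- mean(kept$bias)
  s <- sd(kept$bias)
  drop_bias <- if (is.na(s)) rep(FALSE, nrow(kept)) else
    abs(kept$bias - m) > s
  out <- kept[!drop_bias, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(
    snps = out,
    report = list(n_input = nrow(snps),
                  n_removed_zero = sum(!nz),
                  n_removed_bias = sum(drop_bias),
                  n_retained = nrow(out),
                  mean_bias = m, sd_bias = s)),
    class = "snp_filter")
}

#' Aggregate per-SNP allele counts to gene level
#'
#' Sums a- and b-allele counts of retained SNPs within each gene. SNPs not
#' in the retained set are ignored; SNPs mapped to no gene are counted in
#' the report and excluded; genes with no retained SNP are absent from the
#' output.
#'
#' @param snp_counts per-SNP counts for one library: data.frame with
#'   `chrom`, `pos`, `gene`, `a_count`, `b_count`.
#' @param retained a [filter_snps()] result, or a data.frame of retained
#'   SNPs with `chrom` and `pos`.
#' @param assay,condition,replicate library metadata copied onto the output.
#' @return gene-level data.frame (`gene`, `chrom`, `a_count`, `b_count`,
#'   `assay`, `condition`, `replicate`) with attribute `"n_unmapped"`.
#' @export
aggregate_to_genes <- function(snp_counts, retained,
                               assay = "RNA", condition = "control",
                               replicate = 1L) {
  if (inherits(retained, "snp_filter")) retained <- retained$snps
  key <- function(d) paste(d$chrom, d$pos)
  keep <- key(snp_counts) %in% key(retained)
  sub <- snp_counts[keep, , drop = FALSE]
  unmapped <- sum(is.na(sub$gene) | sub$gene == "")
  sub <- sub[!(is.na(sub$gene) | sub$gene == ""), , drop = FALSE]
  if (nrow(sub) == 0L) {
    out <- data.frame(gene = character(), chrom = character(),
                      a_count = numeric(), b_count = numeric())
  } else {
    a <- tapply(sub$a_count, sub$gene, sum)
    b <- tapply(sub$b_count, sub$gene, sum)
    chrom <- tapply(as.character(sub$chrom), sub$gene, function(x) x[1])
    g <- names(a)
    out <- data.frame(gene = g, chrom = as.character(chrom[g]),
                      a_count = as.numeric(a), b_count = as.numeric(b[g]))
  }
  out$assay <- assay
  out$condition <- condition
  out$replicate <- replicate
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  out
}

#' Filter genes on total allele-informative counts
#'
#' Keeps genes whose total count `a + b` strictly exceeds `min_total`
#' (default 10, the expression-library rule; a gene with exactly
#' `min_total` counts is removed).
#'
#' @param table gene-level data.frame with `a_count`, `b_count`.
#' @param min_total strict lower bound on `a + b`.
#' @return the filtered table.
#' @export
filter_genes <- function(table, min_total = 10) {
  out <- table[table$a_count + table$b_count > min_total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate-averaged a:b ratios per gene
#'
#' Computes per-library per-gene allelic proportions `a / (a + b)` and odds
#' `a / b` (infinite odds, from `b = 0`, are flagged and excluded from
#' averages), then averages across libraries within each condition. Genes
#' must pass [filter_genes()] in every contributing library.
#'
#' @param tables gene-level table (rows from one or more libraries, as
#'   produced by [aggregate_to_genes()], concatenated) with columns `gene`,
#'   `condition`, `replicate`, `a_count`, `b_count`.
#' @param min_total forwarded to [filter_genes()].
#' @return data.frame per gene x condition: `gene`, `chrom`, `condition`,
#'   `n_libraries`, `mean_prop` (mean of a/(a+b)), `mean_ratio` (mean of
#'   finite a/b), `n_infinite_ratio`.
#' @export
ab_ratios <- function(tables, min_total = 10) {
  stopifnot(all(c("gene", "condition", "replicate", "a_count", "b_count")
                %in% names(tables)))
  lib <- paste(tables$condition, tables$replicate)
  n_lib_total <- length(unique(lib))
  passed <- filter_genes(tables, min_total)
  # a gene contributes only if it passes the count filter in every library
  n_pass <- table(passed$gene)
  ok_genes <- names(n_pass)[n_pass == n_lib_total]
  sub <- passed[passed$gene %in% ok_genes, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(gene = character(), chrom = character(),
                      condition = character(), n_libraries = integer(),
                      mean_prop = numeric(), mean_ratio = numeric(),
                      n_infinite_ratio = integer()))
  sub$prop <- sub$a_count / (sub$a_count + sub$b_count)
  sub$ratio <- ifelse(sub$b_count == 0, Inf, sub$a_count / sub$b_count)
  keys <- unique(sub[, c("gene", "condition")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    rows <- sub[sub$gene == keys$gene[i] & sub$condition == keys$condition[i],
                , drop = FALSE]
    fin <- is.finite(rows$ratio)
    data.frame(gene = keys$gene[i],
               chrom = if ("chrom" %in% names(rows)) rows$chrom[1] else NA,
               condition = keys$condition[i],
               n_libraries = nrow(rows),
               mean_prop = mean(rows$prop),
               mean_ratio = if (any(fin)) mean(rows$ratio[fin]) else NA_real_,
               n_infinite_ratio = sum(!fin))
  }))
  rownames(out) <- NULL
  out
}

#' Subtract IgG background from antibody library counts
#'
#' Per gene, subtracts the IgG library's allele-specific counts from the
#' antibody library's (`a' = a_ab - a_igg`, `b' = b_ab - b_igg`); genes
#' missing from the IgG table are treated as IgG = 0. Genes are kept only
#' when both corrected alleles are non-negative and the corrected total
#' strictly exceeds `min_total` (default 5, the chromatin-profiling rule).
#'
#' @param antibody,igg gene-level tables with `gene`, `a_count`, `b_count`.
#' @param min_total strict lower bound on the corrected total.
#' @return corrected, filtered gene table.
#' @export
subtract_igg <- function(antibody, igg, min_total = 5) {
  m <- match(antibody$gene, igg$gene)
  a_bg <- ifelse(is.na(m), 0, igg$a_count[m])
  b_bg <- ifelse(is.na(m), 0, igg$b_count[m])
  out <- antibody
  out$a_count <- antibody$a_count - a_bg
  out$b_count <- antibody$b_count - b_bg
  keep <- out$a_count >= 0 & out$b_count >= 0 &
    (out$a_count + out$b_count) > min_total
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reactivation screen: per-gene allelic shift between two conditions
#'
#' For each X-linked gene present in both conditions, builds the pooled
#' 2x2 table of a/b counts by condition, reports the log2 fold-change of
#' the a:b odds between conditions (condition B over condition A; a
#' Haldane-Anscombe 0.5 correction is applied only when a zero count makes
#' the odds degenerate), a two-sided p-value from the conditional exact
#' test on the 2x2 table, and Benjamini-Hochberg FDR across tested genes.
#'
#' @param cond_a,cond_b gene-level tables (counts summed across libraries
#'   of each condition) with `gene`, `chrom`, `a_count`, `b_count`.
#' @param chrom_filter restrict to genes on this chromosome (default
#'   `"chrX"`; `NULL` tests every shared gene).
#' @return data.frame per tested gene: `gene`, counts, `log2fc_odds`,
#'   `p_value`, `fdr`; genes absent from one condition are reported in the
#'   `"n_excluded"` attribute.
#' @export
reactivation_screen <- function(cond_a, cond_b, chrom_filter = "chrX") {
  if (!is.null(chrom_filter)) {
    cond_a <- cond_a[cond_a$chrom == chrom_filter, , drop = FALSE]
    cond_b <- cond_b[cond_b$chrom == chrom_filter, , drop = FALSE]
  }
  shared <- intersect(cond_a$gene, cond_b$gene)
  n_excluded <- length(setdiff(union(cond_a$gene, cond_b$gene), shared))
  ia <- match(shared, cond_a$gene)
  ib <- match(shared, cond_b$gene)
  res <- data.frame(gene = shared,
                    a_A = cond_a$a_count[ia], b_A = cond_a$b_count[ia],
                    a_B = cond_b$a_count[ib], b_B = cond_b$b_count[ib])
  if (nrow(res) > 0L) {
    lfc <- p <- numeric(nrow(res))
    for (i in seq_len(nrow(res))) {
      m <- matrix(c(res$a_A[i], res$b_A[i], res$a_B[i], res$b_B[i]), 2)
      cc <- if (any(m == 0)) 0.5 else 0
      lfc[i] <- log2(((res$a_B[i] + cc) / (res$b_B[i] + cc)) /
                       ((res$a_A[i] + cc) / (res$b_A[i] + cc)))
      p[i] <- fisher.test(round(m))$p.value
    }
    res$log2fc_odds <- lfc
    res$p_value <- p
    res$fdr <- p.adjust(p, method = "BH")
  } else {
    res$log2fc_odds <- numeric(0)
    res$p_value <- numeric(0)
    res$fdr <- numeric(0)
  }
  attr(res, "n_excluded") <- n_excluded
  res
}
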