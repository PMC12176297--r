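#' Read SNP definitions from a VCF file
#'
#' Positions are 1-based in VCF convention and are preserved as such
#' throughout the package. Only biallelic sites are returned; the gene
#' column is left `NA` until [map_snps_to_genes()] is applied.
#'
#' @param path VCF file (plain or bgzipped).
#' @return data.frame: `chrom`, `pos` (1-based), `id`, `ref`, `alt`,
#'   `gene` (`NA`).
#' @export
snps_from_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    gene = NA_character_)
  multi <- grepl(",", out$alt, fixed = TRUE)
  out <- out[!multi, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Read a BED-like gene map
#'
#' BED intervals are 0-based half-open `[start, end)`; they are converted
#' here, explicitly and once, to 1-based inclusive coordinates so that a
#' VCF-convention SNP at position `p` falls in a gene iff
#' `start_1based <= p <= end_1based`.
#'
#' @param path tab-separated file with columns chrom, start (0-based),
#'   end (exclusive), gene name.
#' @return data.frame: `chrom`, `start`, `end` (both 1-based inclusive),
#'   `gene`.
#' @export
read_gene_bed <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[, 1:4]
  names(tab) <- c("chrom", "start", "end", "gene")
  if (any(tab$end <= tab$start)) stop("malformed interval (end <= start)")
  tab$start <- tab$start + 1L   # 0-based half-open -> 1-based inclusive
  tab$end <- as.integer(tab$end)
  tab
}

#' Assign SNPs to genes by genomic interval
#'
#' @param snps data.frame with `chrom`, `pos` (1-based).
#' @param genes data.frame from [read_gene_bed()] (1-based inclusive
#'   intervals).
#' @return `snps` with the `gene` column filled (`NA` where no interval
#'   contains the SNP; the first matching interval wins, with overlaps
#'   counted in the `"n_overlapping"` attribute).
#' @export
map_snps_to_genes <- function(snps, genes) {
  gene <- rep(NA_character_, nrow(snps))
  n_overlap <- 0L
  for (i in seq_len(nrow(snps))) {
    hit <- which(genes$chrom == snps$chrom[i] &
                   genes$start <= snps$pos[i] & snps$pos[i] <= genes$end)
    if (length(hit) > 1L) n_overlap <- n_overlap + 1L
    if (length(hit) >= 1L) gene[i] <- genes$gene[hit[1]]
  }
  snps$gene <- gene
  attr(snps, "n_overlapping") <- n_overlap
  snps
}
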