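test_that("SNP filter drops zero-count SNPs, then >1 SD bias outliers", {
  # worked example: biases 0.5, 0.5, 0.5, 0.9
  snps <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40), gene = "G1",
                     a_count = c(5, 50, 500, 9),
                     b_count = c(5, 50, 500, 1))
  fr <- filter_snps(snps)
  # independent recomputation: mean 0.6, sample SD 0.2; only |0.9 - 0.6| > SD
  expect_equal(fr$report$mean_bias, mean(c(0.5, 0.5, 0.5, 0.9)))
  expect_equal(fr$report$sd_bias, sd(c(0.5, 0.5, 0.5, 0.9)))
  expect_equal(fr$report$n_removed_bias, 1L)
  expect_equal(fr$report$n_removed_zero, 0L)
  expect_setequal(fr$snps$pos, c(10, 20, 30))

  # zero-count SNP removed at step 1, before the SD computation
  snps2 <- rbind(snps, data.frame(chrom = "chr1", pos = 50, gene = "G1",
                                  a_count = 100, b_count = 0))
  fr2 <- filter_snps(snps2)
  expect_equal(fr2$report$n_removed_zero, 1L)
  expect_equal(fr2$report$mean_bias, 0.6)  # unchanged by the zero SNP
})

test_that("identical biases remove nothing at the SD step", {
  snps <- data.frame(chrom = "chr1", pos = 1:5, gene = "G",
                     a_count = c(10, 20, 40, 80, 160),
                     b_count = c(10, 20, 40, 80, 160))
  fr <- filter_snps(snps)
  expect_equal(fr$report$n_removed_bias, 0L)
  expect_equal(nrow(fr$snps), 5L)
})

test_that("SNP filter is order-independent; the zero-count step is idempotent", {
  set.seed(3)
  snps <- data.frame(chrom = "chr1", pos = 1:60, gene = "G",
                     a_count = rbinom(60, 200, 0.5),
                     b_count = rbinom(60, 200, 0.5))
  snps$a_count[c(4, 9)] <- 0
  fr <- filter_snps(snps)
  # row order never changes the retained set
  perm <- snps[sample(nrow(snps)), ]
  expect_setequal(filter_snps(perm)$snps$pos, fr$snps$pos)
  # re-running removes nothing at the zero-count step (the SD step is not
  # idempotent in general: truncating the tails shrinks the SD, so a rerun
  # can flag further SNPs; mean/SD therefore always refer to one pass over
  # the zero-filtered input, as specified)
  again <- filter_snps(fr$snps[names(snps)])
  expect_equal(again$report$n_removed_zero, 0L)
  expect_error(filter_snps(snps[0, ]), "empty")
})

test_that("planted biased SNPs are the ones flagged by the filter", {
  pars <- allele_sim_params()
  sim <- sim_allele_tables(pars, 0, seed = 19)
  fr <- filter_snps(sim$dna)
  flagged <- setdiff(paste(sim$dna$chrom, sim$dna$pos),
                     paste(fr$snps$chrom, fr$snps$pos))
  planted <- paste(sim$dna$chrom, sim$dna$pos)[sim$dna$is_biased]
  expect_true(all(planted %in% flagged))
  # a planted shift of 0.4 is ~25 binomial SDs: strays are rare
  expect_lte(length(setdiff(flagged, planted)), 3L)
})

test_that("gene aggregation sums retained SNPs and matches group-by", {
  retained <- data.frame(chrom = "chr1", pos = c(1, 2, 5))
  counts <- data.frame(chrom = "chr1", pos = c(1, 2, 3, 5),
                       gene = c("A", "A", "A", "B"),
                       a_count = c(3, 2, 100, 7), b_count = c(1, 2, 100, 0))
  out <- aggregate_to_genes(counts, retained)
  expect_equal(out$a_count[out$gene == "A"], 5)  # SNP at pos 3 not retained
  expect_equal(out$b_count[out$gene == "A"], 3)
  expect_equal(out$a_count[out$gene == "B"], 7)

  # gene whose only SNP was filtered is absent
  retained2 <- data.frame(chrom = "chr1", pos = c(1, 2))
  out2 <- aggregate_to_genes(counts, retained2)
  expect_false("B" %in% out2$gene)

  # random table equals brute-force group-by sums
  set.seed(29)
  big <- data.frame(chrom = "chr1", pos = 1:200,
                    gene = sample(LETTERS[1:10], 200, replace = TRUE),
                    a_count = rpois(200, 5), b_count = rpois(200, 5))
  keep <- big[sample(200, 150), c("chrom", "pos")]
  got <- aggregate_to_genes(big, keep)
  sub <- big[paste(big$chrom, big$pos) %in% paste(keep$chrom, keep$pos), ]
  for (g in unique(sub$gene)) {
    expect_equal(got$a_count[got$gene == g], sum(sub$a_count[sub$gene == g]))
    expect_equal(got$b_count[got$gene == g], sum(sub$b_count[sub$gene == g]))
  }
})

test_that("gene count filter is strictly greater-than and monotone", {
  tab <- data.frame(gene = c("ten", "eleven"), a_count = c(6, 6),
                    b_count = c(4, 5))
  out <- filter_genes(tab, 10)
  expect_equal(out$gene, "eleven")  # total 10 removed, 11 kept

  set.seed(31)
  tab2 <- data.frame(gene = sprintf("g%03d", 1:100),
                     a_count = rpois(100, 8), b_count = rpois(100, 8))
  out2 <- filter_genes(tab2, 10)
  expect_equal(nrow(out2), sum(tab2$a_count + tab2$b_count > 10))
  # tightening the filter can only shrink the gene set
  sizes <- vapply(c(0, 5, 10, 20, 40), function(m)
    nrow(filter_genes(tab2, m)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(filter_genes(tab2, 20)$gene %in% filter_genes(tab2, 10)$gene))
})

test_that("a/b ratio tables report proportions and replicate means", {
  tab <- data.frame(gene = "G", chrom = "chr1", a_count = 50, b_count = 50,
                    assay = "RNA", condition = "control", replicate = 1)
  out <- ab_ratios(tab)
  expect_equal(out$mean_prop, 0.5)
  expect_equal(out$mean_ratio, 1.0)

  # b = 0 gives an infinite odds ratio, flagged and excluded from averages
  tab2 <- rbind(tab,
                transform(tab, b_count = 0, replicate = 2))
  out2 <- ab_ratios(tab2)
  expect_equal(out2$n_infinite_ratio, 1L)
  expect_equal(out2$mean_ratio, 1.0)
  expect_equal(out2$mean_prop, mean(c(0.5, 1)))
})

test_that("simulated classes recover their allelic proportions", {
  pars <- allele_sim_params(mean_total_count = 400)
  sim <- sim_allele_tables(pars, 4, seed = 37)
  fr <- filter_snps(sim$dna)
  libs <- do.call(rbind, lapply(1:4, function(r) {
    sub <- sim$snp_counts[sim$snp_counts$replicate == r, ]
    aggregate_to_genes(sub, fr, condition = "control", replicate = r)
  }))
  rat <- ab_ratios(libs)
  rat$class <- sim$genes$class[match(rat$gene, sim$genes$gene)]
  for (cls in c("autosome", "x_inactivated")) {
    p_true <- unname(pars$p_a[cls])
    props <- rat$mean_prop[rat$class == cls]
    se <- sd(props) / sqrt(length(props))
    expect_lt(abs(mean(props) - p_true), 3 * se + 0.01)
  }
  # generator invariant: per-SNP counts within a gene sum to emitted totals
  one <- sim$snp_counts[sim$snp_counts$replicate == 1, ]
  tot <- tapply(one$a_count + one$b_count, one$gene, sum)
  emitted <- sim$gene_totals[sim$gene_totals$replicate == 1, ]
  expect_equal(as.numeric(tot[emitted$gene]), as.numeric(emitted$total))
})

test_that("empty gene universe yields empty, well-formed tables", {
  pars <- allele_sim_params(n_genes = c(autosome = 0L, x_inactivated = 0L,
                                        x_escape = 0L), n_biased_snps = 0L)
  sim <- sim_allele_tables(pars, 2, seed = 1)
  expect_equal(nrow(sim$dna), 0L)
  expect_true(all(c("chrom", "pos", "gene") %in% names(sim$dna)))
  expect_equal(nrow(sim$snp_counts), 0L)
})

test_that("IgG subtraction follows the worked examples", {
  ab <- data.frame(gene = c("g1", "g2", "g3"),
                   a_count = c(10, 3, 4), b_count = c(8, 3, 3))
  igg <- data.frame(gene = c("g1", "g2", "g3"),
                    a_count = c(2, 4, 1), b_count = c(1, 0, 1))
  out <- subtract_igg(ab, igg)
  # g1: (8, 7), total 15 -> kept
  expect_equal(out$a_count[out$gene == "g1"], 8)
  expect_equal(out$b_count[out$gene == "g1"], 7)
  # g2: a' = -1 -> removed; g3: (3, 2), total 5 -> removed (strict > 5)
  expect_false("g2" %in% out$gene)
  expect_false("g3" %in% out$gene)

  # all-zero IgG is the identity up to the > 5-total filter
  igg0 <- data.frame(gene = "none", a_count = 0, b_count = 0)
  out0 <- subtract_igg(ab, igg0)
  expect_equal(out0, filter_genes(ab, 5))
})

test_that("the reactivation screen matches the exact-test oracle", {
  # identical counts: no shift, p = 1
  a <- data.frame(gene = "g", chrom = "chrX", a_count = 90, b_count = 10)
  out <- reactivation_screen(a, a)
  expect_equal(out$log2fc_odds, 0)
  expect_equal(out$p_value, 1)

  # (90, 10) vs (50, 50): odds ratio 9, p from hypergeometric enumeration
  b <- data.frame(gene = "g", chrom = "chrX", a_count = 50, b_count = 50)
  out2 <- reactivation_screen(a, b)
  expect_equal(2^(-out2$log2fc_odds), 9.0)
  expect_equal(out2$p_value, exact_p_bruteforce(90, 10, 50, 50),
               tolerance = 1e-12)

  # random tables against the oracle
  set.seed(43)
  for (i in 1:25) {
    x <- rbinom(2, 80, 0.6) + 1
    y <- rbinom(2, 80, 0.4) + 1
    ta <- data.frame(gene = "g", chrom = "chrX", a_count = x[1],
                     b_count = y[1])
    tb <- data.frame(gene = "g", chrom = "chrX", a_count = x[2],
                     b_count = y[2])
    got <- reactivation_screen(ta, tb)$p_value
    expect_equal(got, exact_p_bruteforce(x[1], y[1], x[2], y[2]),
                 tolerance = 1e-9)
  }

  # genes absent from one condition are excluded and reported
  a2 <- rbind(a, data.frame(gene = "only_a", chrom = "chrX",
                            a_count = 5, b_count = 5))
  out3 <- reactivation_screen(a2, b)
  expect_equal(nrow(out3), 1L)
  expect_equal(attr(out3, "n_excluded"), 1L)
})
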