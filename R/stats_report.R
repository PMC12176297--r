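#' Superplot summary: replicate-level statistics of per-cell values
#'
#' Summarizes per-cell measurements at the biological-replicate level, the
#' superplot convention: per genotype, the mean of each replicate, the
#' grand mean (mean of replicate means — it depends only on those means,
#' not on per-cell n), and the SD of the replicate means (`NA` with a
#' single replicate).
#'
#' @param data data.frame with columns `value`, `genotype`, `replicate`.
#' @return list: `replicates` (genotype, replicate, n_cells, mean) and
#'   `genotypes` (genotype, n_replicates, grand_mean, sd_replicate_means).
#'   Empty replicates are excluded with a warning.
#' @export
superplot_summary <- function(data) {
  stopifnot(all(c("value", "genotype", "replicate") %in% names(data)))
  bad <- is.na(data$value)
  if (any(bad)) {
    warning(sum(bad), " missing value(s) excluded")
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no values to summarize")
  key <- interaction(data$genotype, data$replicate, drop = TRUE)
  reps <- data.frame(
    genotype = tapply(as.character(data$genotype), key, `[`, 1L),
    replicate = tapply(as.character(data$replicate), key, `[`, 1L),
    n_cells = as.integer(tapply(data$value, key, length)),
    mean = as.numeric(tapply(data$value, key, mean)))
  rownames(reps) <- NULL
  reps <- reps[order(reps$genotype, reps$replicate), , drop = FALSE]
  gens <- do.call(rbind, lapply(unique(reps$genotype), function(g) {
    m <- reps$mean[reps$genotype == g]
    data.frame(genotype = g, n_replicates = length(m),
               grand_mean = mean(m),
               sd_replicate_means = if (length(m) >= 2L) sd(m) else NA_real_)
  }))
  rownames(gens) <- NULL
  list(replicates = reps, genotypes = gens)
}

#' One-way ANOVA with Tukey pairwise tests and Bonferroni correction
#'
#' Omnibus one-way ANOVA on per-cell values by genotype, followed by
#' all-pairs Tukey HSD (studentized-range distribution). Following the
#' source study's stated combination, the Tukey-adjusted p-values are
#' additionally multiplied by the number of pairwise comparisons
#' (Bonferroni), capped at 1; the plain Tukey p-values are also emitted,
#' labeled, since Tukey already controls the family-wise error rate.
#'
#' @param data data.frame with columns `value`, `genotype` (>= 2 groups,
#'   each with >= 2 values).
#' @return list: `anova` (F, df1, df2, p_value) and `pairwise` (comparison,
#'   diff, p_tukey, p_tukey_bonferroni, n_comparisons). With zero variance
#'   everywhere and equal means, F = 0 and p = 1.
#' @export
anova_tukey <- function(data) {
  stopifnot(all(c("value", "genotype") %in% names(data)))
  data$genotype <- factor(data$genotype)
  ng <- nlevels(data$genotype)
  if (ng < 2L) stop("need at least 2 groups")
  if (any(table(data$genotype) < 2L)) stop("each group needs >= 2 values")
  df1 <- ng - 1L
  df2 <- nrow(data) - ng
  if (var(data$value) == 0) {
    # all values identical: no between- or within-group variability
    prs <- t(combn(levels(data$genotype), 2L))
    pairwise <- data.frame(
      comparison = paste(prs[, 2], prs[, 1], sep = "-"),
      diff = 0, p_tukey = 1, p_tukey_bonferroni = 1,
      n_comparisons = nrow(prs))
    return(list(anova = data.frame(F = 0, df1 = df1, df2 = df2,
                                   p_value = 1),
                pairwise = pairwise))
  }
  fit <- aov(value ~ genotype, data = data)
  s <- summary(fit)[[1]]
  tuk <- TukeyHSD(fit)$genotype
  m <- nrow(tuk)
  pairwise <- data.frame(comparison = rownames(tuk),
                         diff = tuk[, "diff"],
                         p_tukey = tuk[, "p adj"],
                         p_tukey_bonferroni = pmin(1, tuk[, "p adj"] * m),
                         n_comparisons = m)
  rownames(pairwise) <- NULL
  list(anova = data.frame(F = s[1, "F value"], df1 = df1, df2 = df2,
                          p_value = s[1, "Pr(>F)"]),
       pairwise = pairwise)
}

#' Percent-positive scoring with replicate-level t-tests
#'
#' Converts per-cell binary scores into per-replicate percentages, then per
#' genotype a mean and SD across replicates, and unpaired two-sided
#' replicate-level t-tests (Welch by default) between all genotype pairs.
#'
#' @param data data.frame with columns `positive` (0/1 or logical),
#'   `genotype`, `replicate`.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return list: `replicates` (genotype, replicate, n, percent_positive),
#'   `genotypes` (genotype, mean_percent, sd_percent, n_replicates),
#'   `tests` (pairwise t-tests on replicate percentages; empty, with a
#'   message, when a genotype has fewer than 2 replicates).
#' @export
percent_positive <- function(data, pooled = FALSE) {
  stopifnot(all(c("positive", "genotype", "replicate") %in% names(data)))
  key <- interaction(data$genotype, data$replicate, drop = TRUE)
  reps <- data.frame(
    genotype = tapply(as.character(data$genotype), key, `[`, 1L),
    replicate = tapply(as.character(data$replicate), key, `[`, 1L),
    n = as.integer(tapply(data$positive, key, length)),
    percent_positive = as.numeric(tapply(data$positive, key,
                                         function(x) 100 * mean(as.numeric(x)))))
  rownames(reps) <- NULL
  reps <- reps[order(reps$genotype, reps$replicate), , drop = FALSE]
  gens <- do.call(rbind, lapply(unique(reps$genotype), function(g) {
    p <- reps$percent_positive[reps$genotype == g]
    data.frame(genotype = g, mean_percent = mean(p),
               sd_percent = if (length(p) >= 2L) sd(p) else NA_real_,
               n_replicates = length(p))
  }))
  rownames(gens) <- NULL
  tests <- NULL
  if (all(gens$n_replicates >= 2L) && nrow(gens) >= 2L) {
    prs <- t(combn(gens$genotype, 2L))
    tests <- do.call(rbind, lapply(seq_len(nrow(prs)), function(i) {
      x <- reps$percent_positive[reps$genotype == prs[i, 1]]
      y <- reps$percent_positive[reps$genotype == prs[i, 2]]
      if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
        # identical replicate percentages: no evidence of difference
        data.frame(group1 = prs[i, 1], group2 = prs[i, 2],
                   t = 0, p_value = 1)
      } else {
        tt <- t.test(x, y, var.equal = pooled)
        data.frame(group1 = prs[i, 1], group2 = prs[i, 2],
                   t = unname(tt$statistic), p_value = tt$p.value)
      }
    }))
  } else {
    message("fewer than 2 replicates in a genotype: t-tests skipped")
    tests <- data.frame(group1 = character(), group2 = character(),
                        t = numeric(), p_value = numeric())
  }
  list(replicates = reps, genotypes = gens, tests = tests)
}

#' Fold change of means with a bootstrap confidence interval
#'
#' `mean(b) / mean(a)` with a seeded nonparametric bootstrap percentile
#' interval (both samples resampled independently).
#'
#' @param a,b numeric samples (reference condition `a`; `mean(a)` must be
#'   positive).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional integer seed for the bootstrap (uses the current
#'   RNG stream when `NULL`).
#' @return list: `fold`, `ci` (length 2), `n_boot`, `conf`.
#' @export
fold_change <- function(a, b, n_boot = 10000L, conf = 0.95, seed = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  if (mean(a) == 0) stop("mean of the reference sample is zero")
  if (!is.null(seed)) set.seed(seed)
  fold <- mean(b) / mean(a)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(b, replace = TRUE)) / mean(sample(a, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(fold = fold,
       ci = unname(quantile(boots, c(alpha, 1 - alpha))),
       n_boot = n_boot, conf = conf)
}
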