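#' Count overlapping k-mers in a sequence set
#'
#' Overlapping window counts on the given strand only (these are RNA-side
#' motifs; set `reverse_complement = TRUE` to scan the other strand).
#' Windows containing non-ACGT letters are skipped; the number skipped is
#' reported in the `"n_skipped_windows"` attribute.
#'
#' @param sequences a `Biostrings::DNAStringSet`, a character vector, or a
#'   path to a FASTA file.
#' @param k k-mer length (>= 1; 5-8 is the usual range, hexamers the
#'   default elsewhere).
#' @param reverse_complement count on the reverse complement instead.
#' @return named integer vector of length `4^k` (all k-mers over ACGT).
#'   Total counts equal the number of clean windows,
#'   `sum(pmax(width - k + 1, 0))` minus skipped windows.
#' @export
count_kmers <- function(sequences, k = 6L, reverse_complement = FALSE) {
  if (k < 1) stop("k must be >= 1")
  x <- if (is.character(sequences) && length(sequences) == 1L &&
             file.exists(sequences))
    Biostrings::readDNAStringSet(sequences)
  else if (is.character(sequences)) Biostrings::DNAStringSet(sequences)
  else sequences
  if (reverse_complement) x <- Biostrings::reverseComplement(x)
  w <- Biostrings::width(x)
  if (all(w < k)) {
    warning("k is longer than every sequence: empty counts")
    counts <- setNames(integer(4^k),
                       Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
    attr(counts, "n_skipped_windows") <- 0L
    return(counts)
  }
  counts <- Biostrings::oligonucleotideFrequency(x, width = k,
                                                 simplify.as = "collapse")
  total_windows <- sum(pmax(w - k + 1L, 0L))
  attr(counts, "n_skipped_windows") <- total_windows - sum(counts)
  counts
}

#' K-mer enrichment scores between experimental and control sets
#'
#' For each k-mer the enrichment score is the log2 ratio of pseudocounted
#' position-normalized frequencies:
#' \deqn{score = \log_2 \frac{(c_{exp} + p) / (N_{exp} + p\,4^k)}
#'                          {(c_{ctrl} + p) / (N_{ctrl} + p\,4^k)}}
#' where `N` is the total window count of a set. Scores are finite for any
#' input when `pseudocount > 0`, are zero for identical sets, and negate
#' exactly when the sets are swapped.
#'
#' @param exp_counts,ctrl_counts named count vectors from [count_kmers()]
#'   at the same `k`.
#' @param pseudocount additive pseudocount `p` (default 1).
#' @return data.frame of class `kmer_table`, sorted by decreasing score:
#'   `kmer`, `c_exp`, `c_ctrl`, `f_exp`, `f_ctrl`, `score`.
#' @export
enrichment_table <- function(exp_counts, ctrl_counts, pseudocount = 1) {
  if (length(exp_counts) != length(ctrl_counts) ||
      !identical(names(exp_counts), names(ctrl_counts)))
    stop("experimental and control counts must come from the same k")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  nk <- length(exp_counts)
  n_exp <- sum(exp_counts)
  n_ctrl <- sum(ctrl_counts)
  f_exp <- (exp_counts + pseudocount) / (n_exp + pseudocount * nk)
  f_ctrl <- (ctrl_counts + pseudocount) / (n_ctrl + pseudocount * nk)
  out <- data.frame(kmer = names(exp_counts),
                    c_exp = as.integer(exp_counts),
                    c_ctrl = as.integer(ctrl_counts),
                    f_exp = as.numeric(f_exp),
                    f_ctrl = as.numeric(f_ctrl),
                    score = log2(as.numeric(f_exp) / as.numeric(f_ctrl)))
  out <- out[order(-out$score, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kmer_table", "data.frame")
  attr(out, "k") <- as.integer(round(log(nk, 4)))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Simulate experimental/control sequence sets with a planted motif
#'
#' Uniform-random ACGT sequences; a fixed fraction of the experimental
#' sequences receive one copy of the motif written at a random position.
#'
#' @param n_exp,n_ctrl sequence counts.
#' @param length sequence length (nt).
#' @param motif planted motif (ACGT only; must not exceed `length`).
#' @param planted_fraction fraction of experimental sequences carrying the
#'   motif.
#' @param seed integer seed.
#' @return list of two `Biostrings::DNAStringSet`s (`exp`, `ctrl`) plus
#'   `planted` (logical ground truth per experimental sequence).
#' @export
sim_sequences <- function(n_exp, n_ctrl, length = 100L, motif = "ACGTAC",
                          planted_fraction = 0.5, seed = 1L) {
  if (!grepl("^[ACGT]+$", motif))
    stop("motif must use the ACGT alphabet only")
  if (nchar(motif) > length) stop("motif longer than the sequences")
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            n_exp >= 0, n_ctrl >= 0)
  set.seed(seed)
  rand_seq <- function(n) {
    if (n == 0L) return(character(0))
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
  }
  ex <- rand_seq(n_exp)
  ct <- rand_seq(n_ctrl)
  n_plant <- round(planted_fraction * n_exp)
  planted <- rep(FALSE, n_exp)
  if (n_plant > 0L) {
    idx <- sample.int(n_exp, n_plant)
    planted[idx] <- TRUE
    for (i in idx) {
      pos <- sample.int(length - nchar(motif) + 1L, 1L)
      substr(ex[i], pos, pos + nchar(motif) - 1L) <- motif
    }
  }
  list(exp = Biostrings::DNAStringSet(ex),
       ctrl = Biostrings::DNAStringSet(ct),
       planted = planted)
}
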