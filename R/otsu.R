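#' Otsu threshold of an intensity histogram
#'
#' Returns the threshold maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all cut points of the
#' histogram, computed exactly over the observed intensity levels via
#' cumulative sums. Foreground is defined as intensities strictly greater
#' than the returned threshold.
#'
#' @param x either raw intensity observations (when `counts` is `NULL`) or
#'   the histogram bin values (sorted or not; they are sorted internally).
#' @param counts optional bin counts matching `x`.
#' @return the threshold value. For a single-valued histogram the sentinel
#'   is that value itself, so the foreground mask (`> threshold`) is empty.
#'   Ties in between-class variance are broken towards the lowest threshold
#'   (deterministic).
#' @examples
#' otsu_threshold(c(0, 10), c(50, 50))  # 0: foreground is intensity 10
#' @export
otsu_threshold <- function(x, counts = NULL) {
  if (is.null(counts)) {
    tab <- table(x)
    lev <- as.numeric(names(tab))
    counts <- as.numeric(tab)
  } else {
    if (length(x) != length(counts)) stop("x and counts length mismatch")
    keep <- counts > 0
    o <- order(x[keep])
    lev <- as.numeric(x[keep][o])
    counts <- as.numeric(counts[keep][o])
    if (anyDuplicated(lev)) {
      counts <- as.numeric(tapply(counts, lev, sum))
      lev <- sort(unique(lev))
    }
  }
  if (length(lev) == 0L) stop("empty histogram")
  if (length(lev) == 1L) return(lev)

  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(lev) - 1L)
  sig_b <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * (1 - w0[k]))
  sig_b[!is.finite(sig_b)] <- -Inf
  lev[which.max(sig_b)]
}

# Integer histogram of a (possibly large) volume: values are rounded to the
# nearest integer for histogramming; thresholds are applied to raw values.
.int_hist <- function(v) {
  vi <- as.integer(round(v))
  lo <- min(vi)
  cnt <- tabulate(vi - lo + 1L)
  keep <- cnt > 0L
  list(levels = (seq_along(cnt) - 1L + lo)[keep], counts = cnt[keep])
}
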