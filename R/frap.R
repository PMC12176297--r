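#' Parameters for the FRAP trace simulator
#'
#' Defaults follow the acquisition protocol used for the GFP-tagged protein:
#' 10 pre-bleach frames, one frame every 65 ms for 30 s after the bleach,
#' and the wild-type kinetics (half-time 2.58 s, immobile fraction 18%).
#'
#' @param t_half recovery half-time (s).
#' @param immobile_fraction fraction of fluorescence that never recovers,
#'   in `[0, 1]`.
#' @param bleach_depth normalized intensity of the first post-bleach frame
#'   `F0`, in `[0, 1)`.
#' @param n_prebleach number of pre-bleach frames.
#' @param frame_interval acquisition interval (s).
#' @param duration_post post-bleach acquisition time (s).
#' @param noise_sd SD of the Gaussian acquisition noise (normalized
#'   intensity units).
#' @return list of class `frap_sim_params`. The plateau
#'   `F_inf = F0 + (1 - immobile_fraction) * (1 - F0)` always lies in
#'   `[F0, 1]`.
#' @export
frap_sim_params <- function(t_half = 2.58, immobile_fraction = 0.18,
                            bleach_depth = 0.2, n_prebleach = 10L,
                            frame_interval = 0.065, duration_post = 30,
                            noise_sd = 0.02) {
  if (!is.finite(t_half) || t_half <= 0) stop("t_half must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  stopifnot(immobile_fraction >= 0, immobile_fraction <= 1,
            bleach_depth >= 0, bleach_depth < 1,
            n_prebleach >= 1, duration_post > 0, noise_sd >= 0)
  structure(list(t_half = t_half, immobile_fraction = immobile_fraction,
                 bleach_depth = bleach_depth,
                 n_prebleach = as.integer(n_prebleach),
                 frame_interval = frame_interval,
                 duration_post = duration_post, noise_sd = noise_sd),
            class = "frap_sim_params")
}

#' Construct a FRAP trace
#'
#' @param time frame times (s), strictly increasing; the bleach is taken to
#'   occur immediately before frame `n_prebleach + 1`.
#' @param intensity ROI intensities (arbitrary units).
#' @param n_prebleach number of pre-bleach frames.
#' @param background optional scalar or per-frame background.
#' @return data.frame of class `frap_trace` with columns `time`,
#'   `intensity` and attributes `n_prebleach`, `background`, `normalized`.
#' @export
frap_trace <- function(time, intensity, n_prebleach, background = NULL) {
  if (any(diff(time) <= 0)) stop("frame times must be strictly increasing")
  if (length(time) != length(intensity)) stop("time/intensity length mismatch")
  if (n_prebleach < 1 || length(time) <= n_prebleach)
    stop("need n_prebleach >= 1 and at least one post-bleach frame")
  structure(data.frame(time = time, intensity = intensity),
            n_prebleach = as.integer(n_prebleach),
            background = background, normalized = FALSE,
            class = c("frap_trace", "data.frame"))
}

#' Simulate FRAP traces with known kinetics
#'
#' Pre-bleach frames fluctuate around 1; post-bleach frames follow
#' \eqn{F(t) = F_\infty - (F_\infty - F_0) e^{-\ln 2 \, t / t_{1/2}}}
#' with `t` measured from the first post-bleach frame, plus Gaussian noise.
#'
#' @param params a [frap_sim_params()].
#' @param n_traces number of traces.
#' @param seed integer seed.
#' @return list of [frap_trace()] objects.
#' @export
sim_frap_traces <- function(params, n_traces, seed = 1L) {
  stopifnot(inherits(params, "frap_sim_params"), n_traces >= 1)
  set.seed(seed)
  dt <- params$frame_interval
  t_pre <- -rev(seq_len(params$n_prebleach)) * dt
  t_post <- seq(0, params$duration_post, by = dt)
  f0 <- params$bleach_depth
  f_inf <- f0 + (1 - params$immobile_fraction) * (1 - f0)
  model <- f_inf - (f_inf - f0) * exp(-log(2) * t_post / params$t_half)
  lapply(seq_len(n_traces), function(i) {
    y <- c(rep(1, length(t_pre)), model)
    if (params$noise_sd > 0)
      y <- y + rnorm(length(y), 0, params$noise_sd)
    frap_trace(c(t_pre, t_post), y, params$n_prebleach)
  })
}

#' Normalize a FRAP trace to its pre-bleach mean
#'
#' Optional background subtraction followed by division by the mean of the
#' pre-bleach frames, so the normalized pre-bleach mean is exactly 1.
#' Idempotent: normalizing a normalized trace changes nothing.
#'
#' @param trace a [frap_trace()].
#' @param background scalar or per-frame background; defaults to the
#'   trace's `background` attribute (if any).
#' @return the normalized [frap_trace()].
#' @export
normalize_trace <- function(trace, background = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  if (isTRUE(attr(trace, "normalized"))) return(trace)
  if (is.null(background)) background <- attr(trace, "background")
  y <- trace$intensity
  if (!is.null(background)) y <- y - background
  npre <- attr(trace, "n_prebleach")
  pre_mean <- mean(y[seq_len(npre)])
  if (!is.finite(pre_mean) || pre_mean <= 0)
    stop("pre-bleach mean must be positive after background subtraction")
  out <- frap_trace(trace$time, y / pre_mean, npre)
  attr(out, "normalized") <- TRUE
  out
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of
#' \eqn{F(t) = F_\infty - (F_\infty - F_0) e^{-k (t - t_{bleach})}} to the
#' post-bleach frames of a normalized trace, with `t_bleach` the first
#' post-bleach time. The initializer is deterministic: `F0` from the first
#' post-bleach point, `F_inf` from the mean of the last 10% of frames, `k`
#' from a log-linear fit of the fractional recovery; refinement by
#' Levenberg-Marquardt least squares.
#'
#' @param trace a [frap_trace()] (normalized internally if needed).
#' @return list of class `frap_fit`: `t_half` (s), `k` (1/s), `F0`,
#'   `F_inf`, `immobile_fraction` (clamped to `[0, 1]`), `resid_sd`,
#'   `converged`, `n_post`.
#' @export
fit_recovery <- function(trace) {
  trace <- normalize_trace(trace)
  npre <- attr(trace, "n_prebleach")
  tt <- trace$time[-seq_len(npre)]
  y <- trace$intensity[-seq_len(npre)]
  if (length(y) < 10L) stop("need at least 10 post-bleach frames")
  tt <- tt - tt[1]

  f0_i <- y[1]
  tail_n <- max(2L, ceiling(0.1 * length(y)))
  finf_i <- mean(y[seq.int(length(y) - tail_n + 1L, length(y))])

  out <- list(t_half = NA_real_, k = NA_real_, F0 = f0_i, F_inf = finf_i,
              immobile_fraction = NA_real_, resid_sd = NA_real_,
              converged = FALSE, n_post = length(y))
  class(out) <- "frap_fit"

  if (finf_i - f0_i < 1e-8 && sd(y) < 1e-8) {
    # no recovery at all: flat post-bleach trace
    out$F_inf <- f0_i
    out$immobile_fraction <- min(1, max(0, (1 - f0_i) / (1 - f0_i)))
    out$resid_sd <- 0
    out$converged <- TRUE
    return(out)
  }

  frac <- (finf_i - y) / max(finf_i - f0_i, 1e-12)
  use <- which(frac > 0.05)
  k_i <- if (length(use) >= 2L) {
    fit0 <- lm(log(frac[use]) ~ tt[use])
    max(-coef(fit0)[2], 1e-3)
  } else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ finf - (finf - f0) * exp(-k * tt),
                      start = list(finf = finf_i, f0 = f0_i, k = k_i),
                      lower = c(-Inf, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)  # flagged non-convergence, no silent defaults
  cf <- coef(fit)
  out$F0 <- unname(cf["f0"])
  out$F_inf <- unname(cf["finf"])
  out$k <- unname(cf["k"])
  out$t_half <- log(2) / out$k
  out$immobile_fraction <-
    min(1, max(0, (1 - out$F_inf) / (1 - out$F0)))
  out$resid_sd <- sd(residuals(fit))
  out$converged <- TRUE
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> t1/2 = %.3f s, immobile = %.1f%%, F0 = %.3f, Finf = %.3f (%s)\n",
    x$t_half, 100 * x$immobile_fraction, x$F0, x$F_inf,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Per-condition summary of FRAP fits
#'
#' @param fits list of [fit_recovery()] results.
#' @param conditions character vector, one condition label per fit.
#' @param traces optional list of the (normalized) traces matching `fits`;
#'   when given, a point-wise mean and SD recovery curve per condition is
#'   returned on the common time grid. Ragged time grids are resampled to
#'   the first trace's grid by linear interpolation, with a message.
#' @return list with `table` (per condition: n, mean/SD of `t_half` and
#'   `immobile_fraction`) and `curves` (or `NULL`).
#' @export
summarize_condition <- function(fits, conditions, traces = NULL) {
  stopifnot(length(fits) == length(conditions))
  if (any(table(conditions) < 2L))
    stop("need at least 2 cells per condition")
  th <- vapply(fits, function(f) f$t_half, numeric(1))
  im <- vapply(fits, function(f) f$immobile_fraction, numeric(1))
  conds <- unique(conditions)
  tab <- do.call(rbind, lapply(conds, function(cc) {
    i <- conditions == cc
    data.frame(condition = cc, n = sum(i),
               mean_t_half = mean(th[i]), sd_t_half = sd(th[i]),
               mean_immobile = mean(im[i]), sd_immobile = sd(im[i]))
  }))
  curves <- NULL
  if (!is.null(traces)) {
    traces <- lapply(traces, normalize_trace)
    grid <- traces[[1]]$time
    ragged <- any(!vapply(traces, function(tr)
      length(tr$time) == length(grid) && all(tr$time == grid), logical(1)))
    if (ragged)
      message("ragged time grids: resampling all traces to the first grid")
    ys <- vapply(traces, function(tr) {
      if (length(tr$time) == length(grid) && all(tr$time == grid))
        tr$intensity
      else approx(tr$time, tr$intensity, xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    curves <- do.call(rbind, lapply(conds, function(cc) {
      i <- conditions == cc
      data.frame(condition = cc, time = grid,
                 mean = rowMeans(ys[, i, drop = FALSE]),
                 sd = apply(ys[, i, drop = FALSE], 1L, sd))
    }))
  }
  list(table = tab, curves = curves)
}
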