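test_that("normalization divides by the pre-bleach mean and is idempotent", {
  tr <- frap_trace(time = c(-2, -1, 0, 1), intensity = c(90, 110, 50, 60),
                   n_prebleach = 2)
  nt <- normalize_trace(tr)
  expect_equal(mean(nt$intensity[1:2]), 1)
  expect_equal(nt$intensity[3], 0.5)
  expect_equal(normalize_trace(nt), nt)

  # constant trace with zero background -> all ones
  tr2 <- frap_trace(0:9, rep(100, 10), n_prebleach = 3)
  expect_true(all(normalize_trace(tr2)$intensity == 1))

  # background subtraction
  tr3 <- frap_trace(0:3, c(110, 90, 60, 60), n_prebleach = 2,
                    background = 10)
  expect_equal(normalize_trace(tr3)$intensity,
               c(100, 80, 50, 50) / 90)

  # zero pre-bleach mean after subtraction is an error
  tr4 <- frap_trace(0:2, c(10, 10, 5), n_prebleach = 2, background = 10)
  expect_error(normalize_trace(tr4), "positive")
})

test_that("simulated noise-free traces satisfy the model exactly", {
  p <- frap_sim_params(noise_sd = 0)
  tr <- sim_frap_traces(p, 1, seed = 1)[[1]]
  post <- tr$intensity[tr$time >= 0]
  tt <- tr$time[tr$time >= 0]
  f0 <- 0.2
  finf <- f0 + (1 - 0.18) * (1 - f0)
  expect_lt(max(abs(post - (finf - (finf - f0) * exp(-log(2) * tt / 2.58)))),
            1e-12)
  # half-time midpoint: F(t_half) = (F0 + F_inf) / 2 = 0.528
  i <- which.min(abs(tt - 2.58))
  expect_equal(tt[i], 2.58, tolerance = 0.033)
  expect_equal((f0 + finf) / 2, 0.528)
  # plateau limit at the last frame (30 s >> t_half)
  expect_equal(post[length(post)], finf, tolerance = 1e-3)
})

test_that("no-recovery parameters give flat post-bleach frames at F0", {
  p <- frap_sim_params(noise_sd = 0, immobile_fraction = 1)
  tr <- sim_frap_traces(p, 1, seed = 1)[[1]]
  expect_true(all(tr$intensity[tr$time >= 0] == 0.2))
  fit <- fit_recovery(tr)
  expect_equal(fit$immobile_fraction, 1)
  expect_true(fit$converged)
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(frap_sim_params(t_half = 0), "t_half")
  expect_error(frap_sim_params(t_half = -1), "t_half")
  expect_error(frap_sim_params(frame_interval = 0), "frame_interval")
})

test_that("the fitter inverts the simulator exactly on noise-free data", {
  for (pars in list(c(2.58, 0.18, 0.2), c(2.0, 0.10, 0.35),
                    c(0.8, 0.45, 0.1))) {
    p <- frap_sim_params(t_half = pars[1], immobile_fraction = pars[2],
                         bleach_depth = pars[3], noise_sd = 0)
    fit <- fit_recovery(sim_frap_traces(p, 1, seed = 1)[[1]])
    expect_true(fit$converged)
    expect_lt(abs(fit$t_half - pars[1]), 1e-6)
    expect_lt(abs(fit$immobile_fraction - pars[2]), 1e-6)
    expect_lt(abs(fit$F0 - pars[3]), 1e-6)
  }
})

test_that("mean fitted half-time over 25 noisy traces is within 5% of truth", {
  p <- frap_sim_params(noise_sd = 0.03)
  fits <- lapply(sim_frap_traces(p, 25, seed = 77), fit_recovery)
  th <- vapply(fits, function(f) f$t_half, numeric(1))
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  expect_lt(abs(mean(th) - 2.58) / 2.58, 0.05)
})

test_that("immobile fraction is invariant to rescaling raw intensities", {
  p <- frap_sim_params(noise_sd = 0.02)
  tr <- sim_frap_traces(p, 1, seed = 3)[[1]]
  for (gain in c(7, 1200)) {
    tr2 <- frap_trace(tr$time, tr$intensity * gain, attr(tr, "n_prebleach"))
    expect_equal(fit_recovery(tr2)$immobile_fraction,
                 fit_recovery(tr)$immobile_fraction, tolerance = 1e-9)
  }
})

test_that("condition summaries report means, SDs and averaged curves", {
  mk_fit <- function(th) structure(list(t_half = th, immobile_fraction = 0.2,
                                        converged = TRUE),
                                   class = "frap_fit")
  sm <- summarize_condition(list(mk_fit(2), mk_fit(3)), c("a", "a"))
  expect_equal(sm$table$mean_t_half, 2.5)
  expect_equal(sm$table$sd_t_half, 0.7071, tolerance = 1e-4)
  # identical fits: SD 0
  sm2 <- summarize_condition(list(mk_fit(2), mk_fit(2)), c("a", "a"))
  expect_equal(sm2$table$sd_t_half, 0)
  expect_error(summarize_condition(list(mk_fit(2)), "a"), "at least 2")
})

test_that("wt and faster-mutant conditions order correctly and curves average", {
  p_wt <- frap_sim_params(t_half = 2.58, noise_sd = 0.03)
  p_mut <- frap_sim_params(t_half = 2.0, noise_sd = 0.03)
  tr <- c(sim_frap_traces(p_wt, 10, seed = 5),
          sim_frap_traces(p_mut, 10, seed = 6))
  fits <- lapply(tr, fit_recovery)
  conds <- rep(c("wt", "mut"), each = 10)
  sm <- summarize_condition(fits, conds, traces = tr)
  tab <- sm$table
  expect_gt(tab$mean_t_half[tab$condition == "wt"],
            tab$mean_t_half[tab$condition == "mut"])
  expect_equal(sort(unique(sm$curves$condition)), c("mut", "wt"))
  # curve rows span the full common grid per condition
  expect_equal(nrow(sm$curves), 2L * length(tr[[1]]$time))
})

test_that("ragged time grids are resampled with a message", {
  p <- frap_sim_params(noise_sd = 0)
  tr1 <- sim_frap_traces(p, 1, seed = 1)[[1]]
  tr2 <- tr1
  tr2$time <- tr2$time * 1.001
  fits <- lapply(list(tr1, tr2), fit_recovery)
  expect_message(summarize_condition(fits, c("a", "a"),
                                     traces = list(tr1, tr2)),
                 "resampling")
})
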