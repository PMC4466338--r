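test_that("triggered-average bins are half-open 0.1 s bins around each lag", {
  # one trigger; signal values equal the frame index so bin contents are
  # directly readable
  n <- 400
  sig <- navlnp:::new_deriv_signal(seq_len(n) / 14 - 1 / 14, seq_len(n), 14)
  ti <- 200
  ev <- navlnp:::events_rows(1L, "turn", sig$t_s[ti], sig$t_s[ti] + 1)
  ev$parent_turn_id <- 1L
  tta <- triggered_average(ev, sig, "turn", window = c(-2, 2))
  # the -1 s bin collects lags in (-1.05, -0.95]: only the frame 14 steps
  # back (lag -1.000 s); frames 13 and 15 back fall outside
  expect_equal(tta$mean[tta$lag_s == -1], ti - 14)
  # the -0.5 s bin collects lags -0.5 (frame -7): (-0.55, -0.45]
  expect_equal(tta$mean[tta$lag_s == -0.5], ti - 7)
  # a two-frame bin: lags -1/14 and -2/14 are both in (-0.15, -0.05]
  expect_equal(tta$mean[tta$lag_s == -0.1], mean(c(ti - 1, ti - 2)))
})

test_that("triggers independent of the stimulus give a flat triggered average", {
  sig <- white_sig(21, 20000)
  set.seed(77)
  trig_t <- sort(runif(800, 6, sig$t_s[20000] - 6))
  ev <- navlnp:::events_rows(1L, "turn", trig_t, trig_t + 0.1)
  tta <- triggered_average(ev, sig)
  expect_true(all(abs(tta$mean) < 3.6 * tta$se))
  expect_gt(mean(abs(tta$mean) < 3 * tta$se), 0.95)
})

test_that("edge triggers are dropped and counted, none usable is an error", {
  sig <- white_sig(3, 300)
  tt <- c(1, 10, sig$t_s[300] - 1)  # first and last lack the 5 s window
  ev <- navlnp:::events_rows(1L, "turn", tt, tt + 0.1)
  tta <- triggered_average(ev, sig)
  expect_equal(attr(tta, "n_triggers"), 1)
  expect_equal(attr(tta, "n_dropped"), 2)
  ev2 <- navlnp:::events_rows(1L, "turn", 1, 1.1)
  expect_error(triggered_average(ev2, sig), class = "navlnp_empty_result")
  expect_error(triggered_average(ev2[0, ], sig), class = "navlnp_empty_result")
})

test_that("negative-lag TTA recovers the simulated kernel shape", {
  sim <- uni_big_fix()
  tta <- triggered_average(sim$ev, sim$sig)
  expect_gt(attr(tta, "n_triggers"), 5000)
  neg <- tta[tta$lag_s < 0, ]
  truth <- stats::approx(default_kernel()$lag_s, default_kernel()$weight,
                         xout = -neg$lag_s, rule = 2)$y
  expect_gt(cor(neg$mean, truth), 0.95)
})

test_that("kernel smoothing fits the negative lags only and recovers known shapes", {
  lags <- seq(-5, 5, by = 0.1)
  truth <- function(t) 0.9 * t * exp(-t / 0.6) * cos(1.2 * t - 0.3)
  y <- ifelse(lags < 0, truth(-lags), 0)
  set.seed(8)
  noise <- rnorm(length(lags), 0, 0.1 * max(abs(y)))
  tta <- tibble::tibble(lag_s = lags, mean = y + noise,
                        se = 0.05, n_samples = 100)
  kf <- fit_kernel(tta)
  expect_true(kf$converged)
  expect_gt(cor(kf$kernel$weight, truth(kf$kernel$lag_s)), 0.99)

  # positive lags (the causality control) never affect the kernel
  tta2 <- tta
  tta2$mean[tta2$lag_s >= 0] <- 5 * sin(tta2$lag_s[tta2$lag_s >= 0])
  kf2 <- fit_kernel(tta2)
  expect_equal(kf2$kernel$weight, kf$kernel$weight)

  # all-zero input gives the zero kernel
  tta0 <- tibble::tibble(lag_s = lags, mean = 0, se = 0, n_samples = 1)
  expect_true(all(fit_kernel(tta0)$kernel$weight == 0))
})

test_that("filtering normalizes to unit variance and flags incomplete support", {
  k <- default_kernel()
  for (seed in 1:4) {
    f <- apply_filter(k, white_sig(seed, 3000))
    expect_equal(var(f$x[f$valid]), 1, tolerance = 1e-6)
    expect_equal(sum(!f$valid), nrow(k))
  }
  # one-tap kernel: output is the (shifted) input, normalized
  sig <- white_sig(9, 1000)
  d1 <- lnp_kernel(c(2.5))
  f1 <- apply_filter(d1, sig)
  expect_equal(f1$x[f1$valid],
               (sig$value / sd(sig$value[-1000]))[-1000],
               tolerance = 1e-9)
  # zero signal: zero output with a warning, not an error
  zs <- navlnp:::new_deriv_signal(seq_len(500) / 14, rep(0, 500), 14)
  expect_warning(fz <- apply_filter(k, zs), "zero variance")
  expect_true(all(fz$x[fz$valid] == 0))
  expect_error(apply_filter(k, white_sig(1, 50)), class = "navlnp_invalid_argument")
})

test_that("binned turn rate is flat for homogeneous turns, with counting errors", {
  m <- lnp_model("unimodal", default_kernel(), rog_nl(0.1, 0, 1))
  sig <- white_sig(41, 33600)
  ev <- simulate_turn_process(m, list(x = sig), poisson_config(20, seed = 5))
  f <- apply_filter(m$kernels$x, sig)
  nl <- binned_turn_rate(f, ev)
  busy <- nl[nl$n_turn >= 20, ]
  expect_gt(nrow(busy), 8)
  expect_true(all(abs(busy$rate - 0.1) < 3 * busy$se))
  # the printed standard-error convention
  expect_equal(nl$se, sqrt(nl$n_turn) / (nl$n_all / 14))
  # exposure bookkeeping: total exposure equals total run time in the
  # valid window
  ef <- navlnp:::exposure_frames(ev, f$t_s)
  expect_equal(sum(nl$n_all), sum(f$valid[ef$run_idx]))
})

test_that("binned rate traces the ratio-of-Gaussians ground truth", {
  sim <- uni_big_fix()
  f <- apply_filter(sim$m$kernels$x, sim$sig)
  nl <- binned_turn_rate(f, sim$ev)
  busy <- nl[nl$n_all > 2000 & nl$n_turn >= 5, ]
  truth <- rog_rate(busy$x, sim$m$nl)
  expect_gt(mean(abs(busy$rate - truth) < 2 * busy$se), 0.9)
})

test_that("moment fit recovers ratio-of-Gaussians parameters", {
  sim <- uni_big_fix()
  f <- apply_filter(sim$m$kernels$x, sim$sig)
  rg <- fit_rog(f, sim$ev)
  expect_equal(rg$nl$rbar, 0.05, tolerance = 0.05)
  expect_equal(rg$nl$mu, 1, tolerance = 0.05)
  expect_equal(rg$nl$sigma, 0.8, tolerance = 0.05)
  # rbar is exactly N_turn / run time
  expect_equal(rg$nl$rbar, rg$n_turn / rg$run_time_s)
  # identity case: a standard-normal turn ensemble gives a constant rate
  expect_equal(rog_rate(seq(-2, 2, 0.5), rog_nl(rg$nl$rbar, 0, 1)),
               rep(rg$nl$rbar, 9))
  expect_error(fit_rog(f, sim$ev[sim$ev$event_type == "run", ]),
               class = "navlnp_empty_result")
})

test_that("split halves of a stationary simulation agree within joint errors", {
  sim <- uni_big_fix()
  tr <- range(sim$ev$t_start_s)
  mid <- mean(tr)
  f <- apply_filter(sim$m$kernels$x, sim$sig)
  r1 <- fit_rog(f, filter_events_window(sim$ev, c(tr[1], mid)))
  r2 <- fit_rog(f, filter_events_window(sim$ev, c(mid, tr[2] + 1)))
  se_mu <- sqrt(r1$nl$sigma^2 / r1$n_turn + r2$nl$sigma^2 / r2$n_turn)
  expect_lt(abs(r1$nl$mu - r2$nl$mu), 2 * se_mu)
  # the joint error on rbar includes the realization variance of the
  # tail-weighted mean rate across stimulus halves, which the counting
  # error alone understates; 3 counting errors is the working bound
  se_rbar <- sqrt(r1$n_turn / r1$run_time_s^2 + r2$n_turn / r2$run_time_s^2)
  expect_lt(abs(r1$nl$rbar - r2$nl$rbar), 3 * se_rbar)
  se_sig <- sqrt(r1$nl$sigma^2 / (2 * r1$n_turn) + r2$nl$sigma^2 / (2 * r2$n_turn))
  expect_lt(abs(r1$nl$sigma - r2$nl$sigma), 2 * se_sig)
})

test_that("step-response prediction is periodic with the closed form at rest", {
  sig <- brown_sig(51, 1200)
  k <- calibrate_kernel(default_kernel(), sig)
  nl <- rog_nl(0.1, 1, 0.8)
  # constant stimulus: rate is rbar exp(-mu^2/(2 sigma^2))/sigma everywhere
  const <- square_stimulus(20, 0.5, 127, 127, n_cycles = 2)
  pc <- predict_step_response(k, nl, const)
  expect_equal(unique(round(pc$rate, 12)),
               0.1 * exp(-1 / (2 * 0.8^2)) / 0.8)
  # prediction is exactly one period and independent of the cycle count
  sq1 <- square_stimulus(20, 0.5, 107, 147, n_cycles = 2)
  sq2 <- square_stimulus(20, 0.5, 107, 147, n_cycles = 5)
  p1 <- predict_step_response(k, nl, sq1)
  p2 <- predict_step_response(k, nl, sq2)
  expect_equal(nrow(p1), 20 * 14)
  expect_equal(p1$rate, p2$rate)
  expect_error(predict_step_response(k, nl, square_stimulus(20.03, 0.5)),
               class = "navlnp_invalid_argument")
})
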