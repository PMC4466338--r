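test_that("ensemble bookkeeping: one pair per turn, unit-variance channels", {
  fx <- lin_fix()
  expect_equal(nrow(fx$ens$turn), fx$ens$n_turn)
  expect_gt(fx$ens$n_turn, 5000)
  # the full filtered ensembles have unit variance by construction; the
  # run-frame reference sample inherits it here (no refractory exclusion)
  expect_equal(var(fx$ens$ref$x_O), 1, tolerance = 0.01)
  expect_equal(var(fx$ens$ref$x_L), 1, tolerance = 0.01)
  ev0 <- fx$ev[fx$ev$event_type == "run", ]
  f <- apply_filter(default_kernel(), white_sig(61, 67200))
  expect_error(build_ensemble(ev0, f, f), class = "navlnp_empty_result")
})

test_that("cross moment: single pair, linear closed form", {
  ens1 <- structure(list(turn = tibble::tibble(x_O = 0.3, x_L = -2)),
                    class = "turn_ensemble")
  expect_equal(cross_moment(ens1), -0.6)

  fx <- lin_fix()
  cm <- cross_moment(fx$ens)
  closed <- cos(33 * pi / 180) * sin(33 * pi / 180) * (0.8^2 + 1^2 - 1)
  prod_se <- sd(fx$ens$turn$x_O * fx$ens$turn$x_L) / sqrt(fx$ens$n_turn)
  # Monte-Carlo error includes the finite-stimulus realization term, which
  # for this tail-weighted moment is comparable to the sampling term
  expect_lt(abs(cm - closed), 4 * prod_se + 0.05)
})

test_that("point-process log-likelihood matches its closed forms", {
  ens <- structure(list(
    turn = tibble::tibble(x_O = rnorm(50), x_L = rnorm(50)),
    ref = tibble::tibble(x_O = rnorm(3000), x_L = rnorm(3000)),
    dt = 1 / 14, n_turn = 50, run_time_s = 3000 / 14),
    class = "turn_ensemble")
  r0 <- 0.2
  ll <- lnp_loglik(function(xo, xl) rep(r0, length(xo)), ens)
  expect_equal(as.numeric(ll), 50 * log(r0 / 14) - r0 * 3000 / 14)
  # doubling dt only adds N log 2
  ll2 <- lnp_loglik(function(xo, xl) rep(r0, length(xo)), ens, dt = 2 / 14)
  expect_equal(as.numeric(ll2) - as.numeric(ll),
               50 * log(2) - r0 * 3000 / 14)
  # zero rate at a turn: -Inf with a diagnostic, not an exception
  llz <- lnp_loglik(function(xo, xl) ifelse(xo > 0, 0, r0), ens)
  expect_identical(as.numeric(llz), -Inf)
  expect_gt(attr(llz, "n_zero_rate_turns"), 0)
})

test_that("the true model attains the higher likelihood on large data", {
  fx <- lin_fix()
  true_rate <- function(xo, xl) {
    u <- cos(33 * pi / 180) * xo + sin(33 * pi / 180) * xl
    rog_rate(u, rog_nl(0.05, 1, 0.8))
  }
  wrong_rate <- function(xo, xl) {
    rog_rate(xo, rog_nl(0.025, 1, 0.8)) + rog_rate(xl, rog_nl(0.025, 1, 0.8))
  }
  expect_gt(as.numeric(lnp_loglik(true_rate, fx$ens)),
            as.numeric(lnp_loglik(wrong_rate, fx$ens)))
})

test_that("maximum-likelihood fits recover the generating model", {
  fx <- lin_fix()
  flin <- fit_linear_combination(fx$ens, seed = 3)
  expect_equal(flin$k, 4L)
  expect_equal(flin$params$theta_deg, 33, tolerance = 5 / 33)
  expect_equal(flin$params$rbar, 0.05, tolerance = 0.05)
  expect_equal(flin$params$mu, 1, tolerance = 0.05)
  expect_equal(flin$params$sigma, 0.8, tolerance = 0.05)

  find <- fit_independent(fx$ens, seed = 3)
  expect_equal(find$k, 6L)
  expect_gt(flin$loglik, find$loglik)

  # MLE beats the moment-route fit on the same data (its own criterion)
  th <- flin$params$theta_deg * pi / 180
  u_t <- cos(th) * fx$ens$turn$x_O + sin(th) * fx$ens$turn$x_L
  mom <- rog_nl(fx$ens$n_turn / fx$ens$run_time_s, mean(u_t),
                sqrt(mean((u_t - mean(u_t))^2)))
  ll_mom <- lnp_loglik(function(xo, xl) rog_rate(cos(th) * xo + sin(th) * xl, mom),
                       fx$ens)
  expect_gte(flin$loglik, as.numeric(ll_mom))
})

test_that("a theta = 0 linear model reduces to the single-channel model", {
  sO <- white_sig(71, 33600)
  sL <- white_sig(72, 33600)
  m <- linear_model(theta_deg = 0)
  ev <- simulate_turn_process(m, list(O = sO, L = sL),
                              poisson_config(20, seed = 19))
  fO <- apply_filter(m$kernels$O, sO)
  fL <- apply_filter(m$kernels$L, sL)
  ens <- build_ensemble(ev, fO, fL)
  flin <- fit_linear_combination(ens, seed = 2)
  expect_lt(flin$params$theta_deg, 3)
  # odor-only rate with the fitted (rbar, mu, sigma) attains essentially the
  # same likelihood: the nested model boundary
  p <- flin$params
  ll0 <- lnp_loglik(function(xo, xl) rog_rate(xo, rog_nl(p$rbar, p$mu, p$sigma)),
                    ens)
  expect_lt(abs(flin$loglik - as.numeric(ll0)), 5)
})

test_that("Akaike relative likelihood follows the definition", {
  mk <- function(ll, k, fp) {
    structure(list(loglik = ll, k = k, aic = 2 * k - 2 * ll,
                   data_fingerprint = fp), class = "lnp_fit")
  }
  expect_equal(aic_compare(mk(-100, 4, 1), mk(-100, 4, 1)), 1)
  # delta AIC of 2 in a's favour: evidence ratio e^-1 against b
  expect_equal(aic_compare(mk(-100, 4, 1), mk(-100, 5, 1)), exp(1))
  expect_equal(aic_compare(mk(-101, 4, 1), mk(-100, 4, 1)), exp(-1))
  expect_error(aic_compare(mk(-100, 4, 1), mk(-100, 4, 2)),
               class = "navlnp_invalid_argument")
})

test_that("coordinate rotation is the exact isometry with the stated convention", {
  df <- tibble::tibble(x_O = c(1, -0.5, 2), x_L = c(0.3, 1.2, -1))
  r0 <- rotate_filtered(df, 0)
  expect_equal(r0$u, df$x_O)
  expect_equal(r0$v, df$x_L)
  r90 <- rotate_filtered(df, 90)
  expect_equal(r90$u, df$x_L)
  expect_equal(r90$v, -df$x_O)
  for (th in c(12, 33, 57)) {
    r <- rotate_filtered(df, th)
    expect_equal(r$u^2 + r$v^2, df$x_O^2 + df$x_L^2)
  }
})

test_that("raw-input rotation negates the red derivative and normalizes", {
  red <- navlnp:::new_stim_trace(c(100, 110, 105), 14, "red")
  blue <- navlnp:::new_stim_trace(c(50, 48, 60), 14, "blue")
  rr <- rotate_raw(red, blue, theta_deg = 0, Ir0 = 2, Ib0 = 4)
  expect_equal(rr$O, -c(10, -5) * 14 / 2)
  expect_equal(rr$L, c(-2, 12) * 14 / 4)
  expect_equal(rr$mu, rr$O)  # theta = 0
  expect_equal(rr$nu, rr$L)
  expect_error(rotate_raw(red, blue, 33, 0, 1), class = "navlnp_invalid_argument")
})

test_that("KL estimators agree with closed forms and are affine invariant", {
  set.seed(10)
  p <- rnorm(4000); q <- rnorm(4000, 1)
  k1 <- kl_divergence(p, q, "knn")
  expect_equal(k1$value, 0.5, tolerance = 0.15)
  g1 <- kl_divergence(p, q, "gaussian_analytic")
  hand <- 0.5 * (log(var(q) / var(p)) +
                   (var(p) + (mean(p) - mean(q))^2) / var(q) - 1)
  expect_equal(g1$value, hand)
  # 2D analytic against the quadratic-form formula
  P <- cbind(rnorm(2000), rnorm(2000, 0.5))
  Q <- cbind(rnorm(2000, 0.2), rnorm(2000))
  g2 <- kl_divergence(P, Q, "gaussian_analytic")
  Sp <- cov(P); Sq <- cov(Q); dm <- colMeans(P) - colMeans(Q)
  hand2 <- 0.5 * (sum(diag(solve(Sq) %*% Sp)) +
                    drop(t(dm) %*% solve(Sq) %*% dm) - 2 +
                    log(det(Sq) / det(Sp)))
  expect_equal(g2$value, hand2)
  # knn estimate is exactly invariant to a common affine rescaling
  k2 <- kl_divergence(3 * p - 7, 3 * q - 7, "knn")
  expect_equal(k2$value, k1$value)
  # near-zero divergence for identical distributions
  k0 <- kl_divergence(rnorm(3000), rnorm(3000), "knn")
  expect_lt(abs(k0$value), 0.05)
  expect_error(kl_divergence(p, cbind(q, q), "knn"),
               class = "navlnp_invalid_argument")
  expect_warning(kl_divergence(rep(c(1, 2), 50), rep(c(1.5, 2.5), 50), "knn"),
                 "jitter")
})

test_that("quadrant assignment follows the sign convention, ties positive", {
  # hand-built events: four turns, one per quadrant, each with a first sweep
  n <- 200
  tgrid <- seq_len(n) / 14 - 1 / 14
  mk_f <- function(vals) {
    tibble::tibble(t_s = tgrid, x = vals, valid = TRUE)
  }
  xO <- rep(0, n); xL <- rep(0, n)
  turn_t <- tgrid[c(30, 60, 90, 120)]
  xO[c(30, 60, 90, 120)] <- c(1, -1, -1, 1)
  xL[c(30, 60, 90, 120)] <- c(1, 1, -1, -1)
  ev <- dplyr::bind_rows(
    navlnp:::events_rows(1L, "turn", turn_t, turn_t + 0.5,
                         parent_turn_id = 1:4),
    navlnp:::events_rows(1L, "headsweep", turn_t, turn_t + 0.5,
                         accepted = c(TRUE, FALSE, TRUE, FALSE),
                         sweep_index = 1L, parent_turn_id = 1:4))
  sig <- navlnp:::new_deriv_signal(tgrid, rnorm(n), 14)
  qa <- quadrant_attention(ev, mk_f(xO), mk_f(xL), list(ch = sig))
  got <- qa[!is.na(qa$n_accepted) | !is.na(qa$n_rejected), ]
  expect_setequal(got$quadrant, c("I", "II", "III", "IV"))
  # quadrant II is unfavorable light with favorable odor: xO < 0, xL >= 0
  expect_equal(sum(qa$quadrant == "II" & !is.na(qa$n_rejected) &
                     qa$n_rejected == 1), 1)
  # a tie (x exactly 0) goes to the positive side
  xO2 <- xO; xO2[30] <- 0
  qa2 <- quadrant_attention(ev, mk_f(xO2), mk_f(xL), list(ch = sig))
  expect_true("I" %in% qa2$quadrant[!is.na(qa2$n_accepted) & qa2$n_accepted > 0])
})
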