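#' Build the turn-triggered ensemble
#'
#' Collects the pair of unit-variance filtered-signal values (x_O, x_L) at
#' every turn start, together with the reference sample of pairs over all
#' run (exposure) frames. These two samples are the basis of the cross-moment
#' diagnostic, the maximum-likelihood model fits and the KL-divergence
#' information measures.
#'
#' @param events Event table.
#' @param filtered_O,filtered_L [apply_filter()] outputs for the odor and
#'   light channels on a shared frame grid.
#' @param dt Frame period in seconds (default 1/14).
#' @param ref_max Maximum reference-sample size. Exposure sets larger than
#'   this are thinned deterministically (every k-th run frame) and the
#'   thinning factor recorded as `ref_weight`, which [lnp_loglik()] and the
#'   model fits use to scale the no-turn sum back to the full exposure.
#' @return A `turn_ensemble`: list with tibbles `turn` and `ref` (columns
#'   `x_O`, `x_L`), plus `dt`, `n_turn`, `run_time_s`, `ref_weight`.
#' @export
build_ensemble <- function(events, filtered_O, filtered_L, dt = 1 / 14,
                           ref_max = Inf) {
  valid <- filtered_O$valid & filtered_L$valid
  ef <- exposure_frames(events, filtered_O$t_s)
  run_idx <- ef$run_idx[valid[ef$run_idx]]
  turn_idx <- ef$turn_idx[valid[ef$turn_idx]]
  if (!length(turn_idx)) abort("No turns in the valid signal range.", class = "navlnp_empty_result")
  n_run <- length(run_idx)
  if (n_run > ref_max) {
    run_idx <- run_idx[unique(round(seq(1, n_run, length.out = ref_max)))]
  }
  structure(list(
    turn = tibble(x_O = filtered_O$x[turn_idx], x_L = filtered_L$x[turn_idx]),
    ref = tibble(x_O = filtered_O$x[run_idx], x_L = filtered_L$x[run_idx]),
    dt = dt, n_turn = length(turn_idx), run_time_s = n_run * dt,
    ref_weight = n_run / length(run_idx)),
    class = "turn_ensemble")
}

#' @export
print.turn_ensemble <- function(x, ...) {
  cat(sprintf("<turn_ensemble> %d turns, %.0f s run time\n",
              x$n_turn, x$run_time_s))
  invisible(x)
}

#' Turn-triggered cross moment
#'
#' The sample mean of `x_O * x_L` over the turn-triggered ensemble. For an
#' independent-pathways turn rate this moment is identically zero (the mixed
#' partial of the rate vanishes); a nonzero value indicates interaction
#' between the channels. For the early-linear-combination model with angle
#' theta and ratio-of-Gaussians parameters (mu, sigma), its expectation is
#' `cos(theta) sin(theta) (sigma^2 + mu^2 - 1)`.
#'
#' @param ens A [build_ensemble()] result.
#' @return Scalar cross moment.
#' @export
cross_moment <- function(ens) {
  if (!nrow(ens$turn)) abort("Empty turn-triggered ensemble.", class = "navlnp_empty_result")
  mean(ens$turn$x_O * ens$turn$x_L)
}

#' Point-process log-likelihood of a turn-rate model
#'
#' `loglik = sum over turns of log(r Delta_t) - sum over run frames of
#' r Delta_t`: the turn term uses the short-interval limit of the Poisson
#' hazard and the no-turn sum runs over run (exposure) frames only. A rate
#' of zero at an observed turn yields `-Inf` with a diagnostic attribute
#' `n_zero_rate_turns` rather than an error.
#'
#' @param rate_fn Function of two vectors `(x_O, x_L)` returning the rate in
#'   turns/s.
#' @param ens A [build_ensemble()] result.
#' @param dt Frame period in seconds.
#' @return Log-likelihood in nats.
#' @export
lnp_loglik <- function(rate_fn, ens, dt = ens$dt) {
  w <- ens$ref_weight %||% 1
  r_turn <- rate_fn(ens$turn$x_O, ens$turn$x_L)
  r_run <- rate_fn(ens$ref$x_O, ens$ref$x_L)
  n_zero <- sum(r_turn <= 0)
  ll <- if (n_zero > 0) -Inf else sum(log(r_turn * dt)) - w * sum(r_run * dt)
  structure(ll, n_zero_rate_turns = n_zero)
}

rate_independent <- function(xO, xL, p) {
  p$rbar_O * exp(-(xO - p$mu_O)^2 / (2 * p$sigma_O^2) + xO^2 / 2) / p$sigma_O +
    p$rbar_L * exp(-(xL - p$mu_L)^2 / (2 * p$sigma_L^2) + xL^2 / 2) / p$sigma_L
}

rate_linear <- function(xO, xL, p) {
  th <- deg2rad(p$theta_deg)
  u <- cos(th) * xO + sin(th) * xL
  p$rbar * exp(-(u - p$mu)^2 / (2 * p$sigma^2) + u^2 / 2) / p$sigma
}

#' Maximum-likelihood fits of the two multisensory integration models
#'
#' `fit_independent()` fits the 6-parameter independent-pathways model (sum
#' of two single-channel ratio-of-Gaussians rates, parameters `rbar_O`,
#' `mu_O`, `sigma_O`, `rbar_L`, `mu_L`, `sigma_L`);
#' `fit_linear_combination()` fits the 4-parameter early-linear-combination
#' model (single ratio-of-Gaussians rate applied to
#' `u = cos(theta) x_O + sin(theta) x_L`, parameters `rbar`, `mu`, `sigma`,
#' `theta`). Both maximize the point-process log-likelihood
#' ([lnp_loglik()]) by bounded quasi-Newton optimization from multiple
#' starts (a moment-based start plus random perturbations); rates are kept
#' positive and `theta` is constrained to \[0, 90\] degrees.
#'
#' @param ens A [build_ensemble()] result.
#' @param dt Frame period in seconds.
#' @param n_starts Number of optimizer starts (>= 1; first is moment-based).
#' @param seed Seed for the random perturbation of starts.
#' @return An `lnp_fit`: list with `mode`, `params`, `loglik`, `k`, `aic`,
#'   `convergence`, `n_turn`, `run_time_s`.
#' @export
fit_linear_combination <- function(ens, dt = ens$dt, n_starts = 5, seed = 1) {
  if (ens$n_turn < 50) warn("Fewer than 50 turns; fit may be poorly identified.")
  xo_t <- ens$turn$x_O; xl_t <- ens$turn$x_L
  xo_r <- ens$ref$x_O; xl_r <- ens$ref$x_L
  w <- ens$ref_weight %||% 1
  n_run <- length(xo_r) * w
  negll <- function(par) {
    th <- par[4]
    u_t <- cos(th) * xo_t + sin(th) * xl_t
    u_r <- cos(th) * xo_r + sin(th) * xl_r
    mu <- par[2]; sig <- exp(par[3])
    lr_t <- par[1] - (u_t - mu)^2 / (2 * sig^2) + u_t^2 / 2 - par[3]
    r_r <- exp(par[1] - (u_r - mu)^2 / (2 * sig^2) + u_r^2 / 2 - par[3])
    -(sum(lr_t) + length(u_t) * log(dt) - w * dt * sum(r_r))
  }
  negll_gr <- function(par) {
    th <- par[4]
    u_t <- cos(th) * xo_t + sin(th) * xl_t
    u_r <- cos(th) * xo_r + sin(th) * xl_r
    v_t <- -sin(th) * xo_t + cos(th) * xl_t
    v_r <- -sin(th) * xo_r + cos(th) * xl_r
    mu <- par[2]; sig2 <- exp(2 * par[3])
    r_r <- exp(par[1] - (u_r - mu)^2 / (2 * sig2) + u_r^2 / 2 - par[3])
    dl_t <- -(u_t - mu) / sig2 + u_t  # d log r / d u
    dl_r <- -(u_r - mu) / sig2 + u_r
    R <- w * dt * sum(r_r)
    c(-length(u_t) + R,
      -sum((u_t - mu)) / sig2 + w * dt * sum(r_r * (u_r - mu)) / sig2,
      -sum((u_t - mu)^2 / sig2 - 1) +
        w * dt * sum(r_r * ((u_r - mu)^2 / sig2 - 1)),
      -sum(dl_t * v_t) + w * dt * sum(r_r * dl_r * v_r))
  }
  # moment-based start: direction of the turn-triggered mean
  th0 <- atan2(max(mean(xl_t), 0), max(mean(xo_t), 0))
  if (!is.finite(th0)) th0 <- pi / 4
  th0 <- min(max(th0, 0.02), pi / 2 - 0.02)
  u0 <- cos(th0) * xo_t + sin(th0) * xl_t
  start0 <- c(log(length(u0) / (n_run * dt)), mean(u0),
              log(max(sd(u0), 0.05)), th0)
  lower <- c(-20, -5, log(0.05), 0)
  upper <- c(5, 5, log(3), pi / 2)
  best <- multistart_optim(negll, start0, lower, upper, n_starts, seed,
                           gr = negll_gr)
  params <- list(rbar = exp(best$par[1]), mu = best$par[2],
                 sigma = exp(best$par[3]), theta_deg = rad2deg(best$par[4]))
  new_lnp_fit("early_linear_combination", params, -best$value, k = 4L,
              ens = ens, convergence = best$convergence)
}

#' @rdname fit_linear_combination
#' @export
fit_independent <- function(ens, dt = ens$dt, n_starts = 5, seed = 1) {
  if (ens$n_turn < 50) warn("Fewer than 50 turns; fit may be poorly identified.")
  xo_t <- ens$turn$x_O; xl_t <- ens$turn$x_L
  xo_r <- ens$ref$x_O; xl_r <- ens$ref$x_L
  w <- ens$ref_weight %||% 1
  n_run <- length(xo_r) * w
  parts <- function(par) {
    rOt <- exp(par[1] - (xo_t - par[2])^2 / (2 * exp(2 * par[3])) +
                 xo_t^2 / 2 - par[3])
    rLt <- exp(par[4] - (xl_t - par[5])^2 / (2 * exp(2 * par[6])) +
                 xl_t^2 / 2 - par[6])
    rOr <- exp(par[1] - (xo_r - par[2])^2 / (2 * exp(2 * par[3])) +
                 xo_r^2 / 2 - par[3])
    rLr <- exp(par[4] - (xl_r - par[5])^2 / (2 * exp(2 * par[6])) +
                 xl_r^2 / 2 - par[6])
    list(rOt = rOt, rLt = rLt, rOr = rOr, rLr = rLr)
  }
  negll <- function(par) {
    p <- parts(par)
    r_t <- p$rOt + p$rLt
    if (any(r_t <= 0)) return(1e10)
    -(sum(log(r_t * dt)) - w * dt * sum(p$rOr + p$rLr))
  }
  negll_gr <- function(par) {
    p <- parts(par)
    r_t <- p$rOt + p$rLt
    wO <- p$rOt / r_t; wL <- p$rLt / r_t
    sO2 <- exp(2 * par[3]); sL2 <- exp(2 * par[6])
    gO_t <- (xo_t - par[2]) / sO2; gO_r <- (xo_r - par[2]) / sO2
    gL_t <- (xl_t - par[5]) / sL2; gL_r <- (xl_r - par[5]) / sL2
    hO_t <- (xo_t - par[2])^2 / sO2 - 1; hO_r <- (xo_r - par[2])^2 / sO2 - 1
    hL_t <- (xl_t - par[5])^2 / sL2 - 1; hL_r <- (xl_r - par[5])^2 / sL2 - 1
    c(-sum(wO) + w * dt * sum(p$rOr),
      -sum(wO * gO_t) + w * dt * sum(p$rOr * gO_r),
      -sum(wO * hO_t) + w * dt * sum(p$rOr * hO_r),
      -sum(wL) + w * dt * sum(p$rLr),
      -sum(wL * gL_t) + w * dt * sum(p$rLr * gL_r),
      -sum(wL * hL_t) + w * dt * sum(p$rLr * hL_r))
  }
  rtot <- length(xo_t) / (n_run * dt)
  start0 <- c(log(rtot / 2), mean(xo_t), log(max(sd(xo_t), 0.05)),
              log(rtot / 2), mean(xl_t), log(max(sd(xl_t), 0.05)))
  lower <- c(-20, -5, log(0.05), -20, -5, log(0.05))
  upper <- c(5, 5, log(3), 5, 5, log(3))
  best <- multistart_optim(negll, start0, lower, upper, n_starts, seed,
                           gr = negll_gr)
  params <- list(rbar_O = exp(best$par[1]), mu_O = best$par[2],
                 sigma_O = exp(best$par[3]),
                 rbar_L = exp(best$par[4]), mu_L = best$par[5],
                 sigma_L = exp(best$par[6]))
  new_lnp_fit("independent_pathways", params, -best$value, k = 6L,
              ens = ens, convergence = best$convergence)
}

multistart_optim <- function(negll, start0, lower, upper, n_starts, seed,
                             gr = NULL) {
  old <- local_seed(child_seed(seed, 7))
  on.exit(restore_seed(old), add = TRUE)
  starts <- list(start0)
  while (length(starts) < n_starts) {
    pert <- start0 + rnorm(length(start0), 0, 0.3)
    starts[[length(starts) + 1L]] <- pmin(pmax(pert, lower), upper)
  }
  fits <- lapply(starts, function(st) {
    tryCatch(
      optim(st, negll, gr = gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) list(value = Inf, par = st, convergence = 99L))
  })
  vals <- vapply(fits, function(f) f$value, 1)
  if (all(!is.finite(vals))) {
    abort("All optimizer starts failed.", class = "navlnp_fit_failure")
  }
  fits[[which.min(vals)]]
}

new_lnp_fit <- function(mode, params, loglik, k, ens, convergence) {
  structure(list(mode = mode, params = params, loglik = loglik,
                 k = k, aic = 2 * k - 2 * loglik,
                 n_turn = ens$n_turn, run_time_s = ens$run_time_s,
                 convergence = convergence,
                 data_fingerprint = ensemble_fingerprint(ens)),
            class = "lnp_fit")
}

ensemble_fingerprint <- function(ens) {
  signif(c(ens$n_turn, nrow(ens$ref),
           sum(ens$turn$x_O), sum(ens$turn$x_L)), 10)
}

#' @export
print.lnp_fit <- function(x, ...) {
  cat(sprintf("<lnp_fit> %s: loglik %.2f, k = %d, AIC %.2f (%d turns)\n",
              x$mode, x$loglik, x$k, x$aic, x$n_turn))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Akaike relative likelihood of two model fits
#'
#' `exp((AIC_b - AIC_a) / 2)`: the evidence for model `fit_a` relative to
#' model `fit_b`. Values below 1 favour `fit_b`. Both fits must be on
#' identical data (checked by fingerprint).
#'
#' @param fit_a,fit_b `lnp_fit` objects fitted to the same ensemble.
#' @return Scalar relative likelihood of `fit_a` versus `fit_b`.
#' @export
aic_compare <- function(fit_a, fit_b) {
  if (!isTRUE(all.equal(fit_a$data_fingerprint, fit_b$data_fingerprint))) {
    abort("Fits were made on different data.", class = "navlnp_invalid_argument")
  }
  exp((fit_b$aic - fit_a$aic) / 2)
}

#' Rotate filtered-signal coordinates
#'
#' Applies the 2D rotation `u = cos(theta) x_O + sin(theta) x_L`,
#' `v = -sin(theta) x_O + cos(theta) x_L` to every `(x_O, x_L)` pair. Under
#' the early-linear-combination model, `u` carries all the information about
#' the decision to turn and `v` none.
#'
#' @param data A tibble with columns `x_O`, `x_L`, or a `turn_ensemble`
#'   (both its `turn` and `ref` tables are rotated).
#' @param theta_deg Rotation angle in degrees.
#' @return Input with columns `u`, `v` added.
#' @export
rotate_filtered <- function(data, theta_deg) {
  if (inherits(data, "turn_ensemble")) {
    data$turn <- rotate_filtered(data$turn, theta_deg)
    data$ref <- rotate_filtered(data$ref, theta_deg)
    return(data)
  }
  stopifnot_cols(data, c("x_O", "x_L"))
  th <- deg2rad(theta_deg)
  data$u <- cos(th) * data$x_O + sin(th) * data$x_L
  data$v <- -sin(th) * data$x_O + cos(th) * data$x_L
  data
}

#' Rotate raw stimulus derivatives
#'
#' Applies the same combination rule to the raw (unfiltered) inputs: the
#' odor signal is the *negated* normalized red-light derivative
#' `O(t) = -dI_red/dt / Ir0` (a decrease in red light is the excitatory
#' direction for fictive odor) and the light signal is
#' `L(t) = dI_blue/dt / Ib0`; then `mu = cos(theta) O + sin(theta) L`,
#' `nu = -sin(theta) O + cos(theta) L`.
#'
#' @param red,blue `stim_trace`s on a shared clock.
#' @param theta_deg Combination angle in degrees (typically the angle fitted
#'   by [fit_linear_combination()]).
#' @param Ir0,Ib0 Positive normalization divisors (the factors that give the
#'   filtered signals unit variance).
#' @return Tibble `t_s`, `O`, `L`, `mu`, `nu` on the derivative grid.
#' @export
rotate_raw <- function(red, blue, theta_deg, Ir0, Ib0) {
  if (Ir0 <= 0 || Ib0 <= 0) abort("`Ir0` and `Ib0` must be > 0.", class = "navlnp_invalid_argument")
  dO <- stim_derivative(red, normalization = Ir0, sign = -1)
  dL <- stim_derivative(blue, normalization = Ib0, sign = 1)
  n <- min(nrow(dO), nrow(dL))
  th <- deg2rad(theta_deg)
  tibble(t_s = dO$t_s[seq_len(n)],
         O = dO$value[seq_len(n)], L = dL$value[seq_len(n)]) |>
    mutate(mu = cos(th) * .data$O + sin(th) * .data$L,
           nu = -sin(th) * .data$O + cos(th) * .data$L)
}

#' Quadrant-wise attention analysis of head-sweep acceptance
#'
#' Assigns every turn to a quadrant by the signs of its filtered-signal pair
#' `(x_O, x_L)` at turn start (ties to the positive side): I both channels
#' unfavorable (both stimulated turning), II light only, III neither, IV
#' odor only. Within each quadrant and for each stimulus channel it
#' computes the difference between rejected and accepted first head sweeps
#' in the mean rate of intensity change over the mean head-sweep duration
#' (1.25 s). If acceptance is driven by a single shared combination of the
#' channels, these differences are the same in every quadrant (no
#' attentional shift between channels).
#'
#' @param events Event table with turns and head sweeps.
#' @param filtered_O,filtered_L [apply_filter()] outputs defining the
#'   quadrants.
#' @param signals Named list of `deriv_signal`s (behaviour clock) to measure
#'   within-sweep change on; typically the normalized raw channel
#'   derivatives (odor sign convention already applied).
#' @param theta_deg If non-`NULL`, also reports the rotated combinations `u`
#'   and `v` of the first two signals.
#' @param mean_sweep_s Averaging window after sweep start (default 1.25 s).
#' @return Tibble `quadrant`, `channel`, `diff` (rejected minus accepted
#'   mean change rate), `se`, `n_accepted`, `n_rejected`. Quadrant/channel
#'   combinations with an empty side carry `NA` differences.
#' @export
quadrant_attention <- function(events, filtered_O, filtered_L, signals,
                               theta_deg = NULL, mean_sweep_s = 1.25) {
  turns <- events[events$event_type == "turn", ]
  sweeps <- events[events$event_type == "headsweep" &
                     events$sweep_index == 1L &
                     !is.na(events$accepted), ]
  if (!nrow(sweeps)) abort("No first head sweeps with accept/reject labels.", class = "navlnp_empty_result")
  sw <- dplyr::inner_join(
    sweeps |> select("t_start_s", "accepted", "parent_turn_id"),
    turns |> select("parent_turn_id", turn_t = "t_start_s"),
    by = "parent_turn_id")
  ti <- frame_index(sw$turn_t, filtered_O$t_s)
  ok <- filtered_O$valid[ti] & filtered_L$valid[ti]
  sw <- sw[ok, ]; ti <- ti[ok]
  xO <- filtered_O$x[ti]; xL <- filtered_L$x[ti]
  sw$quadrant <- dplyr::case_when(
    xO >= 0 & xL >= 0 ~ "I",
    xO < 0 & xL >= 0 ~ "II",
    xO < 0 & xL < 0 ~ "III",
    TRUE ~ "IV")

  if (!is.null(theta_deg) && length(signals) >= 2) {
    th <- deg2rad(theta_deg)
    s1 <- signals[[1]]; s2 <- signals[[2]]
    n <- min(nrow(s1), nrow(s2))
    signals$u <- new_deriv_signal(s1$t_s[seq_len(n)],
                                  cos(th) * s1$value[seq_len(n)] +
                                    sin(th) * s2$value[seq_len(n)],
                                  attr(s1, "sample_rate"), channel = "u")
    signals$v <- new_deriv_signal(s1$t_s[seq_len(n)],
                                  -sin(th) * s1$value[seq_len(n)] +
                                    cos(th) * s2$value[seq_len(n)],
                                  attr(s1, "sample_rate"), channel = "v")
  }

  purrr::imap(signals, function(sig, ch) {
    i0 <- frame_index(sw$t_start_s, sig$t_s)
    i1 <- frame_index(sw$t_start_s + mean_sweep_s, sig$t_s)
    chg <- vapply(seq_along(i0),
                  function(j) mean(sig$value[i0[j]:i1[j]]), 1)
    tibble(quadrant = sw$quadrant, accepted = sw$accepted, chg = chg) |>
      group_by(.data$quadrant) |>
      summarise(
        channel = ch,
        diff = mean(.data$chg[!.data$accepted]) - mean(.data$chg[.data$accepted]),
        se = sqrt(var(.data$chg[!.data$accepted]) / sum(!.data$accepted) +
                    var(.data$chg[.data$accepted]) / sum(.data$accepted)),
        n_accepted = sum(.data$accepted),
        n_rejected = sum(!.data$accepted),
        .groups = "drop")
  }) |>
    bind_rows() |>
    tidyr::complete(quadrant = c("I", "II", "III", "IV"),
                    channel = names(signals)) |>
    arrange(.data$channel, .data$quadrant)
}
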