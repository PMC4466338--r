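#' Triggered average of a stimulus derivative
#'
#' Averages the stimulus derivative at lags relative to behavioural triggers
#' (reverse correlation). Bins are 0.1 s wide and half-open on the left: the
#' bin centred at -1 s collects samples with lags in (-1.05, -0.95] s.
#' For Gaussian white derivative input, the negative-lag portion of the
#' turn-triggered average is proportional to the LNP kernel (reversed in
#' lag); positive lags are a causality control and should be statistically
#' zero for turn triggers.
#'
#' Trigger kinds:
#' * `"turn"` — all turn starts;
#' * `"turn_large"` / `"turn_small"` — turns with |heading change| above /
#'   below the rms heading change of all turns;
#' * `"sweep_accepted"` / `"sweep_rejected"` — starts of first head sweeps
#'   (later sweeps of a turn are ignored) by accepted flag.
#'
#' @param events Event table.
#' @param signal A `deriv_signal` on the behaviour clock (or any tibble with
#'   `t_s` and `value`).
#' @param trigger Trigger kind (see Details).
#' @param window Two-element lag window in seconds, default `c(-5, 5)`.
#' @param bin Lag bin width in seconds (default 0.1).
#' @return A `tta` tibble: `lag_s`, `mean`, `se`, `n_samples`, with
#'   attributes `n_triggers`, `n_dropped`, `trigger`, `channel`.
#'   Standard errors are across triggers of the per-trigger bin average.
#' @export
triggered_average <- function(events, signal,
                              trigger = c("turn", "turn_large", "turn_small",
                                          "sweep_accepted", "sweep_rejected"),
                              window = c(-5, 5), bin = 0.1) {
  trigger <- match.arg(trigger)
  stopifnot_cols(signal, c("t_s", "value"), "signal")
  t_grid <- signal$t_s
  dt <- t_grid[2] - t_grid[1]
  trig_t <- trigger_times(events, trigger)
  if (!length(trig_t)) {
    abort(sprintf("No '%s' triggers in the event table.", trigger),
          class = "navlnp_empty_result")
  }
  idx <- frame_index(trig_t, t_grid)
  offs <- seq(ceiling(window[1] / dt), floor(window[2] / dt))
  usable <- idx + offs[1] >= 1 & idx + offs[length(offs)] <= length(t_grid)
  n_dropped <- sum(!usable)
  idx <- idx[usable]
  if (!length(idx)) {
    abort("All triggers fall too close to the signal edges.",
          class = "navlnp_empty_result")
  }
  V <- matrix(signal$value[outer(offs, idx, "+")], nrow = length(offs))
  lag <- offs * dt
  bin_c <- bin * ceiling(lag / bin - 0.5)  # (c - bin/2, c + bin/2]
  M <- rowsum(V, group = bin_c, reorder = TRUE) /
    as.vector(table(bin_c))  # per-trigger bin means
  mean_v <- unname(rowMeans(M))
  se_v <- unname(apply(M, 1, sd)) / sqrt(ncol(M))
  out <- tibble(lag_s = as.numeric(rownames(M)),
                mean = mean_v, se = se_v,
                n_samples = as.vector(table(bin_c)) * ncol(M))
  structure(out, class = c("tta", class(out)),
            n_triggers = length(idx), n_dropped = n_dropped,
            trigger = trigger, channel = signal$channel[1] %||% "x",
            bin = bin)
}

trigger_times <- function(events, trigger) {
  if (trigger %in% c("turn", "turn_large", "turn_small")) {
    turns <- events[events$event_type == "turn", ]
    if (trigger == "turn") return(turns$t_start_s)
    hc <- abs(turns$heading_change_deg)
    rms <- sqrt(mean(hc^2, na.rm = TRUE))
    if (trigger == "turn_large") turns$t_start_s[!is.na(hc) & hc > rms]
    else turns$t_start_s[!is.na(hc) & hc <= rms]
  } else {
    sw <- events[events$event_type == "headsweep" & events$sweep_index == 1L, ]
    if (trigger == "sweep_accepted") sw$t_start_s[sw$accepted %in% TRUE]
    else sw$t_start_s[sw$accepted %in% FALSE]
  }
}

#' Smooth a triggered average into a convolution kernel
#'
#' Fits the negative-lag portion of a turn-triggered average to the impulse
#' response of a third-order linear system and samples the fit on the
#' behaviour-clock lag grid. Two parameterizations are tried and the one
#' with the lower residual kept: a damped cosine `c * t * exp(-t/tau) *
#' cos(w t + phi)` and the critically damped form `c * t^2 * exp(-t/tau)`.
#' The fit is used only to smooth the triggered average; positive lags (the
#' causality control) never enter. If neither family converges the empirical
#' average is lightly smoothed (Gaussian, sigma 0.2 s) and the fit flagged.
#'
#' @param tta A [triggered_average()] result with negative-lag support.
#' @param support_s Kernel support in seconds (default 5).
#' @param dt Output lag step (default 1/14 s).
#' @return A `kernel_fit`: list with `kernel` ([lnp_kernel()]), `params`,
#'   `family`, `sse`, `converged`.
#' @export
fit_kernel <- function(tta, support_s = 5, dt = 1 / 14) {
  neg <- tta[tta$lag_s < 0 & tta$lag_s >= -support_s, ]
  if (!nrow(neg)) abort("Triggered average has no negative-lag support.", class = "navlnp_invalid_argument")
  tau_grid <- -neg$lag_s   # kernel lag = time before trigger
  y <- neg$mean
  out_t <- seq(dt, support_s, by = dt)
  if (all(y == 0)) {
    return(new_kernel_fit(lnp_kernel(rep(0, length(out_t)), dt = dt),
                          params = NULL, family = "zero", sse = 0,
                          converged = TRUE))
  }
  df <- tibble(t = tau_grid, y = y)
  peak_t <- df$t[which.max(abs(df$y))]
  peak_y <- df$y[which.max(abs(df$y))]

  fits <- list()
  # damped cosine: c t exp(-t/tau) cos(w t + phi)
  fits$damped_cos <- try_nls(
    y ~ c0 * t * exp(-t / tau) * cos(w * t + phi), df,
    starts = list(
      list(c0 = peak_y * exp(1) / peak_t, tau = peak_t, w = 1, phi = 0),
      list(c0 = peak_y * exp(1) / peak_t, tau = peak_t, w = 2, phi = 0),
      list(c0 = peak_y * exp(1) / peak_t, tau = peak_t / 2, w = 0.5, phi = 0)),
    lower = c(-Inf, 1e-3, 0, -pi), upper = c(Inf, Inf, 10, pi))
  # critically damped third order: c t^2 exp(-t/tau)
  fits$crit_damp <- try_nls(
    y ~ c0 * t^2 * exp(-t / tau), df,
    starts = list(list(c0 = peak_y * exp(2) / peak_t^2 * 2, tau = peak_t / 2),
                  list(c0 = peak_y, tau = peak_t)),
    lower = c(-Inf, 1e-3), upper = c(Inf, Inf))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits)) {
    sses <- vapply(fits, function(f) sum(stats::resid(f)^2), 1)
    best <- fits[[which.min(sses)]]
    family <- names(fits)[which.min(sses)]
    w <- stats::predict(best, newdata = tibble(t = out_t))
    return(new_kernel_fit(lnp_kernel(w, dt = dt),
                          params = as.list(stats::coef(best)),
                          family = family, sse = min(sses), converged = TRUE))
  }
  # fallback: lightly smoothed empirical average, linearly interpolated
  sm <- gauss_smooth(df$y, sd_samples = 0.2 / (df$t[2] - df$t[1]))
  w <- stats::approx(df$t, sm, xout = out_t, rule = 2)$y
  new_kernel_fit(lnp_kernel(w, dt = dt), params = NULL,
                 family = "smoothed_empirical",
                 sse = NA_real_, converged = FALSE)
}

try_nls <- function(formula, data, starts, lower, upper) {
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f)) return(f)
  }
  NULL
}

gauss_smooth <- function(y, sd_samples) {
  if (sd_samples <= 0) return(y)
  half <- ceiling(3 * sd_samples)
  k <- dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

new_kernel_fit <- function(kernel, params, family, sse, converged) {
  structure(list(kernel = kernel, params = params, family = family,
                 sse = sse, converged = converged),
            class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("<kernel_fit> family %s, sse %.4g, converged %s\n",
              x$family, x$sse, x$converged))
  invisible(x)
}

#' Filter a stimulus derivative with a kernel
#'
#' Discrete causal convolution of the derivative signal with the kernel
#' (lags one sample to the kernel support — the sample covering the frame of
#' the output itself is *not* included, so decisions never see the change
#' occurring during their own frame). By default the kernel is rescaled so
#' that the filtered signal has unit variance over the whole stimulus
#' history; `rescale = FALSE` reuses the kernel's stored `scale` (needed
#' when applying a calibrated kernel to a different stimulus, e.g. a square
#' wave). Frames with incomplete kernel support are flagged invalid.
#'
#' @param kernel An [lnp_kernel()].
#' @param signal A `deriv_signal` on the matching clock.
#' @param rescale If `TRUE` (default), set the scale from this signal.
#' @return Tibble with `t_s`, `x` (filtered value) and `valid`; attribute
#'   `scale` records the divisor used.
#' @export
apply_filter <- function(kernel, signal, rescale = TRUE) {
  stopifnot_cols(signal, c("t_s", "value"), "signal")
  L <- nrow(kernel)
  s <- signal$value
  if (length(s) <= L) abort("Signal shorter than kernel support.", class = "navlnp_invalid_argument")
  f <- as.numeric(stats::filter(s, kernel$weight, sides = 1))
  # shift by one: x_i = sum_j k_j s_{i-j}, lags start at one sample
  x_raw <- c(NA_real_, f[-length(f)])
  valid <- !is.na(x_raw)
  if (rescale) {
    scale <- sd(x_raw[valid])
    if (!is.finite(scale) || scale == 0) {
      scale <- 1
      warn("Filtered signal has zero variance; scale left at 1.")
    }
  } else {
    scale <- attr(kernel, "scale")
  }
  x <- x_raw / scale
  out <- tibble(t_s = signal$t_s, x = x, valid = valid)
  structure(out, scale = scale, class = c("filtered_signal", class(out)))
}

#' Set a kernel's normalization from a reference stimulus
#'
#' Stores in the kernel the scale that gives unit filtered variance on
#' `signal`, so the same calibration can be reused on other stimuli.
#'
#' @inheritParams apply_filter
#' @return The kernel with its `scale` attribute set.
#' @export
calibrate_kernel <- function(kernel, signal) {
  f <- apply_filter(kernel, signal, rescale = TRUE)
  attr(kernel, "scale") <- attr(f, "scale")
  kernel
}

#' Binned turn rate versus filtered signal
#'
#' Estimates the static nonlinearity: for each filtered-signal bin (width
#' 0.25), `rate = N_turn / (N_all * dt)` where `N_turn` counts turns starting
#' with the filtered signal in the bin and `N_all` counts run frames
#' (exposure) in the bin. The standard error is the counting-statistics
#' error `sqrt(N_turn) / (N_all * dt)`. Bins with no exposure are absent
#' from the result, not zero.
#'
#' @param filtered [apply_filter()] output (tibble with `t_s`, `x`, `valid`).
#' @param events Event table.
#' @param bin Filtered-signal bin width (default 0.25).
#' @param dt Frame period in seconds (default 1/14).
#' @return A `nl_estimate` tibble: `x`, `rate`, `se`, `n_turn`, `n_all`.
#' @export
binned_turn_rate <- function(filtered, events, bin = 0.25, dt = 1 / 14) {
  ef <- exposure_frames(events, filtered$t_s)
  run_idx <- ef$run_idx[filtered$valid[ef$run_idx]]
  turn_idx <- ef$turn_idx[filtered$valid[ef$turn_idx]]
  if (!length(run_idx)) abort("No run frames within the valid signal range.", class = "navlnp_empty_result")
  bx <- function(i) bin * round(filtered$x[i] / bin)
  all_tab <- table(bx(run_idx))
  turn_tab <- table(bx(turn_idx))
  xs <- sort(as.numeric(names(all_tab)))
  n_all <- as.numeric(all_tab[as.character(xs)])
  n_turn <- as.numeric(turn_tab[as.character(xs)])
  n_turn[is.na(n_turn)] <- 0
  out <- tibble(x = xs,
                rate = n_turn / (n_all * dt),
                se = sqrt(n_turn) / (n_all * dt),
                n_turn = n_turn, n_all = n_all)
  structure(out, class = c("nl_estimate", class(out)), dt = dt, bin = bin)
}

#' Moment fit of the ratio-of-Gaussians nonlinearity
#'
#' Direct moment estimates: `rbar = N_turn / T` with `T` the total run
#' (exposure) time, `mu` the mean and `sigma` the sd of the filtered signal
#' over the turn-triggered ensemble (population denominator). No iterative
#' fitting is involved.
#'
#' @inheritParams binned_turn_rate
#' @return A `rog_fit`: list with `nl` ([rog_nl()]), `n_turn`, `run_time_s`.
#' @export
fit_rog <- function(filtered, events, dt = 1 / 14) {
  ef <- exposure_frames(events, filtered$t_s)
  run_idx <- ef$run_idx[filtered$valid[ef$run_idx]]
  turn_idx <- ef$turn_idx[filtered$valid[ef$turn_idx]]
  if (length(turn_idx) < 2) abort("Need at least 2 turns.", class = "navlnp_empty_result")
  if (!length(run_idx)) abort("No run time in the valid signal range.", class = "navlnp_empty_result")
  xt <- filtered$x[turn_idx]
  T_run <- length(run_idx) * dt
  mu <- mean(xt)
  sigma <- sqrt(mean((xt - mu)^2))
  structure(list(nl = rog_nl(length(xt) / T_run, mu, sigma),
                 n_turn = length(xt), run_time_s = T_run),
            class = "rog_fit")
}

#' @export
print.rog_fit <- function(x, ...) {
  cat(sprintf("<rog_fit> rbar %.4g /s, mu %.3f, sigma %.3f (%d turns, %.0f s run time)\n",
              x$nl$rbar, x$nl$mu, x$nl$sigma, x$n_turn, x$run_time_s))
  invisible(x)
}

#' Predict the cyclic turn-rate response to a square-wave stimulus
#'
#' Applies the LNP model deterministically to a periodic stimulus: the
#' square wave's derivative is filtered with the calibrated kernel (stored
#' scale — the unit-variance normalization from the reverse-correlation
#' stimulus) cyclically, and the ratio-of-Gaussians rate evaluated at every
#' cycle phase. The prediction is exactly periodic: the lag range \[-2, 0) s
#' is identical to \[period - 2, period).
#'
#' @param kernel Calibrated [lnp_kernel()] (see [calibrate_kernel()]).
#' @param nl A [rog_nl()].
#' @param square A square-wave `stim_trace`.
#' @param frame_rate Behaviour clock (Hz); the period must be an integer
#'   number of frames.
#' @param sign Sign convention of the analysed derivative (`-1` for fictive
#'   odor channels).
#' @return Tibble `cycle_t_s`, `x`, `rate`.
#' @export
predict_step_response <- function(kernel, nl, square, frame_rate = 14,
                                  sign = 1) {
  meta <- attr(square, "meta")
  period_s <- meta$period_s
  P <- period_s * frame_rate
  if (abs(P - round(P)) > 1e-8) {
    abort("Square-wave period must be an integer number of frames.", class = "navlnp_invalid_argument")
  }
  P <- as.integer(round(P))
  sig <- resample_to_frames(stim_derivative(square, sign = sign), frame_rate)
  s1 <- sig$value[seq_len(min(P, nrow(sig)))]
  if (length(s1) < P) s1 <- rep_len(s1, P)
  s3 <- rep(s1, 3)  # steady state after one wrap
  f <- as.numeric(stats::filter(s3, kernel$weight, sides = 1))
  x_raw <- c(NA_real_, f[-length(f)])
  x <- (x_raw / attr(kernel, "scale"))[(2 * P + 1):(3 * P)]
  tibble(cycle_t_s = (seq_len(P) - 1) / frame_rate,
         x = x, rate = rog_rate(x, nl))
}

#' Observed cyclic turn rate on a periodic stimulus
#'
#' Bins turn starts and run-frame exposure by cycle phase and forms the
#' counting-statistics rate estimate per phase bin.
#'
#' @param events Event table.
#' @param t_grid Frame time grid the events live on.
#' @param period_s Stimulus period in seconds.
#' @param bin Phase bin width in seconds (default 0.5).
#' @param dt Frame period (default 1/14 s).
#' @return Tibble `cycle_t_s` (bin centre), `rate`, `se`, `n_turn`, `n_all`.
#' @export
observed_step_response <- function(events, t_grid, period_s, bin = 0.5,
                                   dt = 1 / 14) {
  ef <- exposure_frames(events, t_grid)
  phase <- function(i) (t_grid[i] %% period_s)
  pb <- function(i) bin * (floor(phase(i) / bin) + 0.5)
  all_tab <- table(pb(ef$run_idx))
  turn_tab <- table(pb(ef$turn_idx))
  ph <- sort(as.numeric(names(all_tab)))
  n_all <- as.numeric(all_tab[as.character(ph)])
  n_turn <- as.numeric(turn_tab[as.character(ph)])
  n_turn[is.na(n_turn)] <- 0
  tibble(cycle_t_s = ph,
         rate = n_turn / (n_all * dt),
         se = sqrt(n_turn) / (n_all * dt),
         n_turn = n_turn, n_all = n_all)
}
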