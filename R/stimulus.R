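#' Generate a Brownian light-intensity stimulus
#'
#' Light levels follow a reflecting random walk on the integer range
#' \[0, 255\]: each proposal adds a Gaussian increment `N(0, sigma)` to the
#' previous level, out-of-range proposals are reflected back into range
#' (`I -> -I` below 0, `I -> 510 - I` above 255, applied iteratively), and
#' the whole real-valued sequence is rounded to the nearest integer at the
#' end. The derivative of such a walk is white on all time scales, which is
#' what makes it suitable for reverse correlation. At the defaults
#' (`sigma = 3`, 112 Hz) the walk has diffusion constant
#' `sigma^2 * update_rate / 2 = 504` (levels)^2/s.
#'
#' @param duration_s Trace duration in seconds. The trace has
#'   `round(duration_s * update_rate)` steps after the initial level.
#' @param sigma Standard deviation of the per-update Gaussian increment, in
#'   intensity levels. Must be >= 0.
#' @param i0 Initial intensity level in \[0, 255\].
#' @param update_rate Stimulus update rate in Hz (default 112, eight updates
#'   per 14 Hz camera frame).
#' @param seed Integer seed; recorded in the trace attributes.
#' @param channel Channel label (e.g. `"red"`, `"blue"`).
#' @param reflect If `FALSE`, the boundary reflection is skipped and levels
#'   are returned unrounded and unbounded (useful for diffusion-constant
#'   checks where the reflecting boundary would bend the MSD curve).
#'
#' @return A `stim_trace`: a tibble with columns `t_s`, `channel`, `level`
#'   and attributes `update_rate`, `sigma`, `i0`, `seed`.
#' @examples
#' s <- brownian_stimulus(10, sigma = 3, seed = 1)
#' range(s$level)
#' @export
brownian_stimulus <- function(duration_s, sigma = 3, i0 = 127,
                              update_rate = 112, seed = NULL,
                              channel = "red", reflect = TRUE) {
  n_steps <- round(duration_s * update_rate)
  if (n_steps < 0) abort("`duration_s` must be non-negative.", class = "navlnp_invalid_argument")
  if (sigma < 0) abort("`sigma` must be >= 0.", class = "navlnp_invalid_argument")
  if (i0 < 0 || i0 > 255) abort("`i0` must lie in [0, 255].", class = "navlnp_invalid_argument")
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  inc <- rnorm(n_steps, 0, sigma)
  if (!reflect) {
    levels <- c(i0, i0 + cumsum(inc))
  } else {
    levels <- reflected_walk(i0, inc)
    levels <- round(levels)  # rounding once, after the walk is complete
  }
  new_stim_trace(levels, update_rate, channel,
                 sigma = sigma, i0 = i0, seed = seed)
}

# Reflecting random walk on [0, 255]. Block-wise: reflections are rare away
# from the boundaries, so each block is a plain cumsum re-run from the first
# boundary violation.
reflected_walk <- function(i0, inc) {
  n <- length(inc)
  out <- numeric(n + 1L)
  out[1L] <- i0
  cur <- i0
  j <- 1L
  block <- 8192L
  while (j <= n) {
    k <- min(j + block - 1L, n)
    prop <- cur + cumsum(inc[j:k])
    bad <- which(prop < 0 | prop > 255)
    if (length(bad) == 0L) {
      out[(j + 1L):(k + 1L)] <- prop
      cur <- prop[length(prop)]
      j <- k + 1L
    } else {
      b <- bad[1L]
      if (b > 1L) out[(j + 1L):(j + b - 1L)] <- prop[seq_len(b - 1L)]
      v <- prop[b]
      while (v < 0 || v > 255) {  # iterative reflection for extreme proposals
        if (v < 0) v <- -v
        if (v > 255) v <- 510 - v
      }
      out[j + b] <- v
      cur <- v
      j <- j + b
    }
  }
  out
}

#' Generate a square-wave stimulus
#'
#' Alternating high/low intensity levels on the stimulus update grid,
#' starting with the high phase (a step up at t = 0).
#'
#' @param period_s Cycle period in seconds (default 20 s).
#' @param duty Fraction of the cycle spent at `high` (default 0.5).
#' @param low,high Intensity levels in \[0, 255\], `low <= high`.
#' @param n_cycles Number of full cycles.
#' @param update_rate Update rate in Hz.
#' @inheritParams brownian_stimulus
#' @return A `stim_trace` tibble.
#' @examples
#' sq <- square_stimulus(20, 0.5, low = 107, high = 147, n_cycles = 3)
#' @export
square_stimulus <- function(period_s = 20, duty = 0.5, low = 107, high = 147,
                            n_cycles = 1, update_rate = 112,
                            channel = "red") {
  if (duty <= 0 || duty >= 1) abort("`duty` must lie strictly in (0, 1).", class = "navlnp_invalid_argument")
  if (low > high) abort("`low` must be <= `high`.", class = "navlnp_invalid_argument")
  if (any(c(low, high) < 0) || any(c(low, high) > 255)) {
    abort("`low` and `high` must lie in [0, 255].", class = "navlnp_invalid_argument")
  }
  n_per_cycle <- round(period_s * update_rate)
  n_high <- round(duty * n_per_cycle)
  cyc <- c(rep(high, n_high), rep(low, n_per_cycle - n_high))
  new_stim_trace(rep(cyc, n_cycles), update_rate, channel,
                 period_s = period_s, duty = duty)
}

new_stim_trace <- function(levels, update_rate, channel, ...) {
  out <- tibble(
    t_s = seq_along(levels) / update_rate - 1 / update_rate,
    channel = channel,
    level = as.numeric(levels)
  )
  structure(out,
            class = c("stim_trace", class(out)),
            update_rate = update_rate,
            meta = list(...))
}

#' Differentiate a stimulus trace
#'
#' Forward finite difference assigned to the left endpoint: value `i` is
#' `(level[i+1] - level[i]) * update_rate / normalization`, so the signal has
#' one fewer sample than the trace and units of levels/s (divided by the
#' normalization). All triggered averages in the package use this grid
#' convention.
#'
#' @param stim A `stim_trace` (tibble with `t_s`, `channel`, `level`).
#' @param normalization Scalar divisor applied to the raw rate of change
#'   (default 1). Must be non-zero.
#' @param sign Multiplier applied after normalization; use `-1` for channels
#'   where a *decrease* in intensity is the excitatory direction (fictive
#'   odor: the analysed odor signal is the negated normalized red-light
#'   derivative).
#' @return A `deriv_signal`: tibble with `t_s`, `channel`, `value` and
#'   attributes `sample_rate`, `normalization`.
#' @export
stim_derivative <- function(stim, normalization = 1, sign = 1) {
  if (nrow(stim) < 2) abort("Trace must have at least 2 levels.", class = "navlnp_invalid_argument")
  if (normalization == 0) abort("`normalization` must be non-zero.", class = "navlnp_invalid_argument")
  rate <- attr(stim, "update_rate")
  vals <- sign * diff(stim$level) * rate / normalization
  new_deriv_signal(stim$t_s[-nrow(stim)], vals, rate,
                   channel = stim$channel[1], normalization = normalization)
}

new_deriv_signal <- function(t_s, values, sample_rate, channel = "x",
                             normalization = 1) {
  out <- tibble(t_s = t_s, channel = channel, value = as.numeric(values))
  structure(out,
            class = c("deriv_signal", class(out)),
            sample_rate = sample_rate,
            normalization = normalization)
}

#' Resample a derivative signal to the behaviour clock
#'
#' The stimulus updates an integer number of times per camera frame (8 at the
#' 112 Hz / 14 Hz defaults). Resampling block-averages each frame's updates,
#' which preserves the total integrated intensity change.
#'
#' @param signal A `deriv_signal`.
#' @param frame_rate Target rate in Hz (default 14). The signal's sample rate
#'   must be an integer multiple of it.
#' @return A `deriv_signal` at `frame_rate`.
#' @export
resample_to_frames <- function(signal, frame_rate = 14) {
  sr <- attr(signal, "sample_rate")
  ratio <- sr / frame_rate
  if (abs(ratio - round(ratio)) > 1e-8) {
    abort("Sample rate must be an integer multiple of `frame_rate`.", class = "navlnp_invalid_argument")
  }
  ratio <- as.integer(round(ratio))
  n_frames <- length(signal$value) %/% ratio
  v <- signal$value[seq_len(n_frames * ratio)]
  frame_vals <- colMeans(matrix(v, nrow = ratio))
  new_deriv_signal(seq_len(n_frames) / frame_rate - 1 / frame_rate,
                   frame_vals, frame_rate,
                   channel = signal$channel[1],
                   normalization = attr(signal, "normalization"))
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("<stim_trace> channel %s, %d levels at %g Hz (%.1f s)\n",
              x$channel[1], nrow(x), attr(x, "update_rate"),
              nrow(x) / attr(x, "update_rate")))
  NextMethod()
}
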