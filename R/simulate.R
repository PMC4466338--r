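#' Ratio-of-Gaussians nonlinearity
#'
#' Static nonlinearity of the LNP cascade. If the stimulus ensemble of the
#' unit-variance filtered signal is standard normal and the turn-triggered
#' ensemble is Gaussian with mean `mu` and sd `sigma`, the turn rate as a
#' function of filter output x is
#' `r(x) = rbar * exp(-(x - mu)^2 / (2 sigma^2)) / (sigma * exp(-x^2 / 2))`.
#' `rbar` is the overall turn rate (turns per second of run time), `mu` the
#' turn-triggered mean and `sigma` the turn-triggered sd.
#'
#' @param rbar Baseline turn rate in turns/s (> 0).
#' @param mu Turn-triggered mean of the unit-variance filtered signal.
#' @param sigma Turn-triggered standard deviation (> 0).
#' @return An object of class `rog_nl`.
#' @examples
#' nl <- rog_nl(0.1, 1, 0.8)
#' rog_rate(c(-1, 0, 1), nl)
#' @export
rog_nl <- function(rbar, mu, sigma) {
  if (rbar <= 0) abort("`rbar` must be > 0.", class = "navlnp_invalid_argument")
  if (sigma <= 0) abort("`sigma` must be > 0.", class = "navlnp_invalid_argument")
  structure(list(rbar = rbar, mu = mu, sigma = sigma), class = "rog_nl")
}

#' @rdname rog_nl
#' @param x Filtered-signal values.
#' @param nl A `rog_nl` object.
#' @export
rog_rate <- function(x, nl) {
  nl$rbar * exp(-(x - nl$mu)^2 / (2 * nl$sigma^2) + x^2 / 2) / nl$sigma
}

#' Convolution kernel
#'
#' A kernel is a tibble with columns `lag_s` and `weight` on a uniform lag
#' grid starting at one sample, plus a `scale` attribute: filtering divides
#' the raw convolution by `scale` so that the filtered signal has unit
#' variance over the stimulus ensemble (see [apply_filter()]).
#'
#' `default_kernel()` is the simulator's ground-truth shape: the impulse
#' response of a third-order low-pass cascade, `k(t) = (t/tau)^2 exp(-t/tau)`,
#' peaking at `2 * tau` seconds (0.7 s by default, matching the sub-second
#' salience the triggered averages are designed to resolve).
#'
#' @param weights Kernel weights per lag.
#' @param dt Lag step in seconds (default 1/14).
#' @param scale Normalization divisor (default 1; set by [apply_filter()]).
#' @return A `lnp_kernel` tibble.
#' @export
lnp_kernel <- function(weights, dt = 1 / 14, scale = 1) {
  if (scale <= 0) abort("`scale` must be > 0.", class = "navlnp_invalid_argument")
  out <- tibble(lag_s = seq_along(weights) * dt, weight = as.numeric(weights))
  structure(out, class = c("lnp_kernel", class(out)), dt = dt, scale = scale)
}

#' @rdname lnp_kernel
#' @param support_s Kernel support in seconds (default 5).
#' @param peak_s Lag of the kernel peak in seconds (default 0.7).
#' @export
default_kernel <- function(support_s = 5, dt = 1 / 14, peak_s = 0.7) {
  tt <- seq(dt, support_s, by = dt)
  tau <- peak_s / 2
  lnp_kernel((tt / tau)^2 * exp(-tt / tau), dt = dt)
}

#' LNP model specification
#'
#' Bundles the linear filter(s) and nonlinearity of a Linear-Nonlinear-Poisson
#' turn-initiation model.
#'
#' Modes:
#' * `"unimodal"` — one channel, one kernel, rate `rog_rate(x)`.
#' * `"independent_pathways"` — two channels, rate is the *sum* of two
#'   single-channel ratio-of-Gaussians rates (`nl` is a named list with one
#'   `rog_nl` per channel).
#' * `"early_linear_combination"` — two channels combined linearly before the
#'   nonlinearity: `u = cos(theta) x_1 + sin(theta) x_2`, rate `rog_rate(u)`.
#'   `theta = 0` means only the first channel matters, `theta = 90` only the
#'   second.
#'
#' @param mode One of `"unimodal"`, `"independent_pathways"`,
#'   `"early_linear_combination"`.
#' @param kernels Named list of `lnp_kernel`s, one per channel. Channel order
#'   defines the (x_1, x_2) order used by `theta`.
#' @param nl A `rog_nl` (unimodal / early linear combination) or a named list
#'   of `rog_nl`s per channel (independent pathways).
#' @param theta_deg Combination angle in degrees, in \[0, 90\]
#'   (early linear combination only).
#' @return An object of class `lnp_model`.
#' @export
lnp_model <- function(mode = c("unimodal", "independent_pathways",
                               "early_linear_combination"),
                      kernels, nl, theta_deg = NULL) {
  mode <- match.arg(mode)
  if (inherits(kernels, "lnp_kernel")) kernels <- list(x = kernels)
  n_chan <- length(kernels)
  if (mode == "unimodal" && n_chan != 1) {
    abort("Unimodal model needs exactly one kernel.", class = "navlnp_invalid_argument")
  }
  if (mode != "unimodal" && n_chan != 2) {
    abort(sprintf("Mode '%s' needs exactly two kernels.", mode), class = "navlnp_invalid_argument")
  }
  if (mode == "independent_pathways") {
    ok <- is.list(nl) && length(nl) == 2 && all(vapply(nl, inherits, TRUE, "rog_nl"))
    if (!ok) abort("Independent-pathways model needs a list of two `rog_nl`s.", class = "navlnp_invalid_argument")
  } else if (!inherits(nl, "rog_nl")) {
    abort("`nl` must be a `rog_nl`.", class = "navlnp_invalid_argument")
  }
  if (mode == "early_linear_combination") {
    if (is.null(theta_deg) || theta_deg < 0 || theta_deg > 90) {
      abort("`theta_deg` must lie in [0, 90].", class = "navlnp_invalid_argument")
    }
  }
  structure(list(mode = mode, kernels = kernels, nl = nl,
                 theta_deg = theta_deg),
            class = "lnp_model")
}

#' Behavioural simulation configuration
#'
#' Parameters of the virtual larva that are not part of the LNP turn-rate
#' model: clocks, track structure, turn durations, the turn-size rule, and
#' the head-sweep acceptance rule. Defaults emulate the published study
#' conditions: 14 Hz behaviour sampling, 50 tracks over a 20-min stimulus,
#' ~2 s turns, 1.25 s mean head-sweep duration.
#'
#' The size and acceptance rules are the simulator's own (the field has
#' demonstrated both effects without publishing a quantitative form):
#' * size rule — probability of a "large" turn is
#'   `plogis(gain * (slow - offset))` where `slow` is the mean unfavorable
#'   drive over the `window_s` (12 s) preceding the turn; magnitudes are
#'   drawn from overlapping Gaussians (folded), sign uniform.
#' * accept rule — a head sweep is accepted with probability
#'   `plogis(gain * fav + offset)` where `fav` is minus the mean unfavorable
#'   drive during the sweep (favorable changes make acceptance more likely).
#'
#' @param frame_rate Behaviour sampling rate in Hz.
#' @param n_tracks Number of simultaneously tracked animals.
#' @param stagger_s Tracks enter uniformly within `stagger_s` of the window
#'   start and leave within `stagger_s` of its end (0 = all tracks span the
#'   full window).
#' @param turn_meanlog,turn_sdlog Lognormal parameters of the provisional
#'   turn duration (defaults give mean ~2 s).
#' @param sweep_shape,sweep_mean_s Gamma shape and mean (s) of head-sweep
#'   durations (mean 1.25 s).
#' @param sweep_cap Maximum head sweeps per turn; the last is force-accepted.
#' @param size_rule List with `gain`, `offset`, `window_s`, `small_mean`,
#'   `small_sd`, `large_mean`, `large_sd` (degrees).
#' @param accept_rule List with `gain` and `offset` (log-odds units).
#' @param seed Integer seed for all simulator randomness.
#' @return A list of class `behavior_config`.
#' @export
behavior_config <- function(frame_rate = 14,
                            n_tracks = 50,
                            stagger_s = 0,
                            turn_meanlog = log(2) - 0.4^2 / 2,
                            turn_sdlog = 0.4,
                            sweep_shape = 4,
                            sweep_mean_s = 1.25,
                            sweep_cap = 4,
                            size_rule = list(gain = 3, offset = 0,
                                             window_s = 12,
                                             small_mean = 45, small_sd = 15,
                                             large_mean = 105, large_sd = 25),
                            accept_rule = list(gain = 1.5, offset = 0.5),
                            seed = 1L) {
  if (sweep_mean_s <= 0 || sweep_shape <= 0) {
    abort("Sweep duration parameters must be > 0.", class = "navlnp_invalid_argument")
  }
  structure(list(frame_rate = frame_rate, n_tracks = n_tracks,
                 stagger_s = stagger_s,
                 turn_meanlog = turn_meanlog, turn_sdlog = turn_sdlog,
                 sweep_shape = sweep_shape, sweep_mean_s = sweep_mean_s,
                 sweep_cap = sweep_cap,
                 size_rule = size_rule, accept_rule = accept_rule,
                 seed = seed),
            class = "behavior_config")
}

#' Compute the model's turning drive from stimulus signals
#'
#' Filters each channel's derivative signal with the model's kernel
#' (normalized to unit variance over the supplied stimulus), and combines
#' channels according to the model mode. Returns the per-frame drive table
#' used by the simulator and by downstream estimators.
#'
#' @param model An [lnp_model()].
#' @param signals Named list of `deriv_signal`s (behaviour clock), names
#'   matching the model's kernel names. Signals at a higher rate are
#'   resampled with [resample_to_frames()].
#' @param frame_rate Behaviour clock in Hz.
#' @return A tibble with `t_s`, one unit-variance filtered column `x_<chan>`
#'   per channel, the per-frame rate `rate`, and a `valid` flag (FALSE while
#'   the kernel support is incomplete).
#' @export
compute_drive <- function(model, signals, frame_rate = 14) {
  if (inherits(signals, "deriv_signal")) signals <- list(x = signals)
  chans <- names(model$kernels)
  if (!all(chans %in% names(signals))) {
    abort(sprintf("Missing signal for channel(s): %s",
                  paste(setdiff(chans, names(signals)), collapse = ", ")),
          class = "navlnp_invalid_argument")
  }
  xs <- lapply(chans, function(ch) {
    sig <- signals[[ch]]
    if (abs(attr(sig, "sample_rate") - frame_rate) > 1e-9) {
      sig <- resample_to_frames(sig, frame_rate)
    }
    apply_filter(model$kernels[[ch]], sig)
  })
  n <- min(vapply(xs, nrow, 1L))
  drive <- tibble(t_s = xs[[1]]$t_s[seq_len(n)])
  valid <- rep(TRUE, n)
  for (i in seq_along(chans)) {
    drive[[paste0("x_", chans[i])]] <- xs[[i]]$x[seq_len(n)]
    valid <- valid & xs[[i]]$valid[seq_len(n)]
  }
  drive$valid <- valid
  drive$rate <- model_rate(model, drive, chans)
  drive
}

model_rate <- function(model, drive, chans = names(model$kernels)) {
  x1 <- drive[[paste0("x_", chans[1])]]
  switch(model$mode,
    unimodal = rog_rate(x1, model$nl),
    independent_pathways = {
      x2 <- drive[[paste0("x_", chans[2])]]
      rog_rate(x1, model$nl[[chans[1]]]) + rog_rate(x2, model$nl[[chans[2]]])
    },
    early_linear_combination = {
      x2 <- drive[[paste0("x_", chans[2])]]
      th <- deg2rad(model$theta_deg)
      rog_rate(cos(th) * x1 + sin(th) * x2, model$nl)
    })
}

# The scalar drive whose *positive* values are unfavorable and push the
# larva toward turning; used by the size and acceptance rules.
scalar_drive <- function(model, drive, chans = names(model$kernels)) {
  x1 <- drive[[paste0("x_", chans[1])]]
  switch(model$mode,
    unimodal = x1,
    independent_pathways = {
      # equal-weight combination; shared-salience rules are only meaningful
      # for the early-linear model, but a defined value is needed here
      (x1 + drive[[paste0("x_", chans[2])]]) / sqrt(2)
    },
    early_linear_combination = {
      th <- deg2rad(model$theta_deg)
      cos(th) * x1 + sin(th) * drive[[paste0("x_", chans[2])]]
    })
}

#' Simulate Poisson turn initiation
#'
#' Draws turn starts frame-by-frame from the inhomogeneous Poisson hazard:
#' the probability of initiating a turn in a frame of length `dt` with rate
#' `r` is `1 - exp(-r dt)`. A turn occupies a lognormal duration during which
#' no further turn can start; runs fill the gaps. Tracks are independent
#' realizations sharing the same stimulus.
#'
#' @inheritParams compute_drive
#' @param config A [behavior_config()].
#' @param drive Optional precomputed [compute_drive()] table (computed from
#'   `signals` if omitted).
#' @return An event table: tibble with columns `track_id`, `event_type`
#'   (`run`/`turn`), `t_start_s`, `t_end_s`, `heading_change_deg`,
#'   `accepted`, `sweep_index`, `parent_turn_id`.
#' @export
simulate_turn_process <- function(model, signals, config = behavior_config(),
                                  drive = NULL) {
  if (is.null(drive)) drive <- compute_drive(model, signals, config$frame_rate)
  dt <- 1 / config$frame_rate
  ok <- which(drive$valid)
  if (!length(ok)) abort("No valid frames (stimulus shorter than kernel support).", class = "navlnp_invalid_argument")
  t_f <- drive$t_s[ok]
  p <- 1 - exp(-pmax(drive$rate[ok], 0) * dt)

  old <- local_seed(child_seed(config$seed, 1))
  on.exit(restore_seed(old), add = TRUE)

  w0 <- t_f[1]; w1 <- t_f[length(t_f)] + dt
  out <- vector("list", config$n_tracks)
  turn_counter <- 0L
  for (tr in seq_len(config$n_tracks)) {
    if (config$stagger_s > 0) {
      a <- w0 + runif(1, 0, config$stagger_s)
      b <- w1 - runif(1, 0, config$stagger_s)
    } else {
      a <- w0; b <- w1
    }
    in_win <- t_f >= a & t_f < b
    cand <- which(in_win & runif(length(t_f)) < p)
    turns <- list()
    t_free <- -Inf
    for (i in cand) {
      ts <- t_f[i]
      if (ts < t_free) next
      dur <- rlnorm(1, config$turn_meanlog, config$turn_sdlog)
      te <- min(ts + dur, b)
      turns[[length(turns) + 1L]] <- c(ts, te)
      t_free <- te
    }
    ev <- build_track_events(tr, turns, a, b)
    if (!is.null(ev) && any(ev$event_type == "turn")) {
      nt <- sum(ev$event_type == "turn")
      ev$parent_turn_id[ev$event_type == "turn"] <- turn_counter + seq_len(nt)
      turn_counter <- turn_counter + nt
    }
    out[[tr]] <- ev
  }
  bind_rows(out)
}

# Turn intervals -> full run/turn event table for one track. Vectorized:
# runs fill the gaps between consecutive turn intervals.
build_track_events <- function(track_id, turns, a, b) {
  if (length(turns) == 0) {
    return(events_rows(track_id, "run", a, b))
  }
  tm <- do.call(rbind, turns)
  ts <- tm[, 1]; te <- tm[, 2]
  run_start <- c(a, te)
  run_end <- c(ts, b)
  keep <- run_end > run_start + 1e-12
  ev <- bind_rows(
    events_rows(track_id, "run", run_start[keep], run_end[keep]),
    events_rows(track_id, "turn", ts, te))
  ev[order(ev$t_start_s), ]
}

events_rows <- function(track_id, type, t0, t1, heading = NA_real_,
                        accepted = NA, sweep_index = NA_integer_,
                        parent_turn_id = NA_integer_) {
  n <- length(t0)
  tibble(track_id = rep(as.integer(track_id), length.out = n),
         event_type = rep(type, length.out = n),
         t_start_s = t0, t_end_s = t1,
         heading_change_deg = rep(heading, length.out = n),
         accepted = rep(accepted, length.out = n),
         sweep_index = rep(as.integer(sweep_index), length.out = n),
         parent_turn_id = rep(as.integer(parent_turn_id), length.out = n))
}

#' Assign turn sizes from slow stimulus drift
#'
#' Turn magnitude is decided from the slow (default 12 s) history of the
#' unfavorable drive before the turn: sustained unfavorable drift raises the
#' probability of a "large" turn (see [behavior_config()] for the rule).
#' Heading-change sign is uniform.
#'
#' @param events Event table with turns.
#' @param drive [compute_drive()] table (its [scalar_drive()] combination is
#'   used).
#' @inheritParams simulate_turn_process
#' @return The event table with `heading_change_deg` filled in on turn rows.
#' @export
assign_turn_sizes <- function(events, drive, model, config = behavior_config()) {
  sr <- config$size_rule
  it <- which(events$event_type == "turn")
  if (!length(it)) return(events)
  old <- local_seed(child_seed(config$seed, 2))
  on.exit(restore_seed(old), add = TRUE)
  u <- scalar_drive(model, drive)
  dt <- 1 / config$frame_rate
  wlen <- max(1L, round(sr$window_s / dt))
  # rolling mean of the drive over the window ending at each frame
  cs <- cumsum(ifelse(is.na(u), 0, u))
  nmat <- seq_along(u)
  lo <- pmax(nmat - wlen, 0L)
  roll <- (cs - c(0, cs)[lo + 1L]) / (nmat - lo)
  idx <- pmin(pmax(frame_index(events$t_start_s[it], drive$t_s), 1L), length(u))
  slow <- roll[idx]
  p_large <- plogis(sr$gain * (slow - sr$offset))
  is_large <- runif(length(it)) < p_large
  mag <- ifelse(is_large,
                abs(rnorm(length(it), sr$large_mean, sr$large_sd)),
                abs(rnorm(length(it), sr$small_mean, sr$small_sd)))
  sgn <- sample(c(-1, 1), length(it), replace = TRUE)
  events$heading_change_deg[it] <- sgn * mag
  events
}

#' Simulate head sweeps within turns
#'
#' Each turn is composed of one or more head sweeps drawn sequentially:
#' sweep durations are Gamma with mean `sweep_mean_s` (1.25 s); a sweep is
#' accepted with probability `plogis(gain * fav + offset)` where `fav` is
#' minus the mean unfavorable drive during the sweep. A rejected sweep
#' spawns another, up to `sweep_cap` (the last is force-accepted). The turn's
#' end time is reset to the end of its final sweep (truncated at the next
#' turn) and run intervals are rebuilt.
#'
#' @inheritParams assign_turn_sizes
#' @return Event table including `headsweep` rows with `accepted`,
#'   `sweep_index` and `parent_turn_id`.
#' @export
simulate_headsweeps <- function(events, drive, model, config = behavior_config()) {
  it <- which(events$event_type == "turn")
  if (!length(it)) return(events)
  old <- local_seed(child_seed(config$seed, 3))
  on.exit(restore_seed(old), add = TRUE)
  u <- scalar_drive(model, drive)
  t_grid <- drive$t_s
  dt <- 1 / config$frame_rate

  turns <- events[it, ] |> arrange(.data$track_id, .data$t_start_s)
  next_start <- turns |>
    group_by(.data$track_id) |>
    mutate(nxt = lead(.data$t_start_s)) |>
    dplyr::pull(.data$nxt)
  cap <- config$sweep_cap
  nmax <- nrow(turns) * cap
  sw_track <- integer(nmax); sw_t0 <- sw_t1 <- numeric(nmax)
  sw_acc <- logical(nmax); sw_idx <- integer(nmax); sw_parent <- integer(nmax)
  n_sw <- 0L
  ucs <- cumsum(ifelse(is.na(u), 0, u))  # for fast within-sweep means
  mean_u <- function(i0, i1) (ucs[i1] - c(0, ucs)[i0]) / (i1 - i0 + 1L)
  new_end <- turns$t_end_s
  t_max <- max(t_grid) + dt
  for (i in seq_len(nrow(turns))) {
    cap_t <- if (is.na(next_start[i])) Inf else next_start[i]
    limit <- min(cap_t, t_max)
    t0 <- turns$t_start_s[i]
    for (k in seq_len(cap)) {
      dur <- rgamma(1, shape = config$sweep_shape,
                    scale = config$sweep_mean_s / config$sweep_shape)
      t1 <- min(t0 + dur, limit)
      i0 <- frame_index(t0, t_grid); i1 <- max(frame_index(t1, t_grid), i0)
      fav <- -mean_u(i0, i1)
      acc <- (k == cap) || t1 >= limit ||
        runif(1) < plogis(config$accept_rule$gain * fav + config$accept_rule$offset)
      n_sw <- n_sw + 1L
      sw_track[n_sw] <- turns$track_id[i]
      sw_t0[n_sw] <- t0; sw_t1[n_sw] <- t1
      sw_acc[n_sw] <- acc; sw_idx[n_sw] <- k
      sw_parent[n_sw] <- turns$parent_turn_id[i]
      t0 <- t1
      if (acc) break
    }
    new_end[i] <- t0
  }
  keep <- seq_len(n_sw)
  sweep_tbl <- tibble(track_id = sw_track[keep], event_type = "headsweep",
                      t_start_s = sw_t0[keep], t_end_s = sw_t1[keep],
                      heading_change_deg = NA_real_, accepted = sw_acc[keep],
                      sweep_index = sw_idx[keep],
                      parent_turn_id = sw_parent[keep])
  turns$t_end_s <- new_end

  # rebuild runs per track around the updated turn intervals
  rebuilt <- events |>
    filter(.data$event_type != "headsweep") |>
    group_by(.data$track_id) |>
    dplyr::group_map(function(df, key) {
      a <- min(df$t_start_s); b <- max(df$t_end_s)
      tt <- turns[turns$track_id == key$track_id, , drop = FALSE]
      tt <- tt[order(tt$t_start_s), ]
      ev <- build_track_events(key$track_id,
                               lapply(seq_len(nrow(tt)),
                                      function(j) c(tt$t_start_s[j], tt$t_end_s[j])),
                               a, b)
      iturn <- which(ev$event_type == "turn")
      ev$heading_change_deg[iturn] <- tt$heading_change_deg
      ev$parent_turn_id[iturn] <- tt$parent_turn_id
      ev
    }) |>
    bind_rows()
  bind_rows(rebuilt, sweep_tbl) |>
    arrange(.data$track_id, .data$t_start_s, .data$event_type)
}

#' Simulate a full virtual-larva experiment
#'
#' Convenience wrapper chaining [compute_drive()], [simulate_turn_process()],
#' [assign_turn_sizes()] and [simulate_headsweeps()].
#'
#' @inheritParams simulate_turn_process
#' @return A list of class `larva_sim` with elements `events`, `drive`,
#'   `model`, `config`.
#' @examples
#' stim <- brownian_stimulus(120, seed = 1)
#' sig <- resample_to_frames(stim_derivative(stim, sign = -1))
#' m <- lnp_model("unimodal", default_kernel(), rog_nl(0.2, 1, 0.8))
#' sim <- simulate_larva(m, list(x = sig), behavior_config(n_tracks = 2, seed = 1))
#' @export
simulate_larva <- function(model, signals, config = behavior_config()) {
  drive <- compute_drive(model, signals, config$frame_rate)
  events <- simulate_turn_process(model, signals, config, drive = drive)
  events <- assign_turn_sizes(events, drive, model, config)
  events <- simulate_headsweeps(events, drive, model, config)
  structure(list(events = events, drive = drive, model = model,
                 config = config),
            class = "larva_sim")
}

#' @export
print.larva_sim <- function(x, ...) {
  nt <- sum(x$events$event_type == "turn")
  ns <- sum(x$events$event_type == "headsweep")
  cat(sprintf("<larva_sim> %s model: %d tracks, %d turns, %d head sweeps\n",
              x$model$mode, length(unique(x$events$track_id)), nt, ns))
  invisible(x)
}

# nearest frame index of time t on grid t_grid (uniform)
frame_index <- function(t, t_grid) {
  dt <- t_grid[2] - t_grid[1]
  pmin(pmax(as.integer(round((t - t_grid[1]) / dt)) + 1L, 1L), length(t_grid))
}

#' Per-frame exposure bookkeeping
#'
#' Maps an event table onto a frame grid: which frames (with multiplicity
#' across tracks) were run frames — exposure during which a turn could have
#' started — and at which frames turns actually started. The frame at a turn
#' start counts as exposed-and-turned; frames inside turns are not exposed.
#'
#' @param events Event table.
#' @param t_grid Uniform frame-time grid (e.g. `drive$t_s`).
#' @return List with integer vectors `run_idx` (exposure frames, with
#'   multiplicity; excludes turn-start frames) and `turn_idx` (turn starts).
#' @export
exposure_frames <- function(events, t_grid) {
  dt <- t_grid[2] - t_grid[1]
  runs <- events[events$event_type == "run", ]
  turn_t <- events$t_start_s[events$event_type == "turn"]
  turn_idx <- frame_index(turn_t, t_grid)
  run_idx <- integer(0)
  if (nrow(runs)) {
    i0 <- frame_index(runs$t_start_s, t_grid)
    # half-open [t_start, t_end): last exposed frame strictly before t_end
    i1 <- frame_index(runs$t_end_s - dt / 2, t_grid)
    lens <- pmax(i1 - i0 + 1L, 0L)
    run_idx <- sequence(lens, from = i0)
  }
  list(run_idx = run_idx, turn_idx = turn_idx)
}
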