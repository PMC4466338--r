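# Shared builders for simulated fixtures. Everything is generated in code at
# test time; nothing is read from disk.

# iid standard-normal derivative signal on the 14 Hz behaviour clock: the
# ideal white-derivative stimulus (what a Brownian intensity walk without
# boundary reflections would produce, already normalized).
white_sig <- function(seed, n_frames, channel = "x") {
  set.seed(seed)
  navlnp:::new_deriv_signal(seq_len(n_frames) / 14 - 1 / 14,
                            rnorm(n_frames), 14, channel = channel)
}

# Brownian light stimulus -> normalized derivative on the behaviour clock.
brown_sig <- function(seed, dur_s, sign = 1, channel = "red") {
  stim <- brownian_stimulus(dur_s, sigma = 3, seed = seed, channel = channel)
  resample_to_frames(stim_derivative(stim, sign = sign))
}

# Configuration for pure Poisson sampling of the turn process: turn
# durations far below one frame, so there is effectively no refractory and
# the run ensemble equals the stimulus ensemble (the regime in which the
# Gaussian closed forms for the turn-triggered ensemble are exact).
poisson_config <- function(n_tracks, seed, ...) {
  behavior_config(n_tracks = n_tracks, seed = seed,
                  turn_meanlog = log(0.05), turn_sdlog = 1e-3, ...)
}

# Standard two-channel early-linear-combination model (study conditions).
linear_model <- function(theta_deg = 33, rbar = 0.05, mu = 1, sigma = 0.8) {
  lnp_model("early_linear_combination",
            list(O = default_kernel(), L = default_kernel()),
            rog_nl(rbar, mu, sigma), theta_deg = theta_deg)
}

independent_model <- function(rbar = 0.025, mu = 1, sigma = 0.8) {
  lnp_model("independent_pathways",
            list(O = default_kernel(), L = default_kernel()),
            list(O = rog_nl(rbar, mu, sigma), L = rog_nl(rbar, mu, sigma)))
}

# Lazily computed fixtures shared across tests in one run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# a small full simulation (runs + turns + sweeps) for structural tests
uni_small_fix <- function() {
  fixture("uni_small", {
    m <- lnp_model("unimodal", default_kernel(), rog_nl(0.1, 1, 0.8))
    simulate_larva(m, list(x = white_sig(5, 16800)),
                   behavior_config(n_tracks = 5, seed = 9, stagger_s = 60))
  })
}

# a large Poisson-sampled unimodal dataset for estimator recovery tests
uni_big_fix <- function() {
  fixture("uni_big", {
    m <- lnp_model("unimodal", default_kernel(), rog_nl(0.05, 1, 0.8))
    sig <- white_sig(31, 33600)
    list(m = m, sig = sig,
         ev = simulate_turn_process(m, list(x = sig),
                                    poisson_config(52, seed = 13)))
  })
}

# two-channel early-linear ground truth at theta = 33 degrees, Poisson
# sampling regime (negligible turn occupancy, where the Gaussian closed
# forms for the turn-triggered ensemble are exact)
lin_fix <- function() {
  fixture("lin_poisson", {
    sO <- white_sig(61, 67200)  # 80 min
    sL <- white_sig(62, 67200)
    m <- linear_model(theta_deg = 33)
    ev <- simulate_turn_process(m, list(O = sO, L = sL),
                                poisson_config(25, seed = 17))
    fO <- apply_filter(m$kernels$O, sO)
    fL <- apply_filter(m$kernels$L, sL)
    list(m = m, ens = build_ensemble(ev, fO, fL), ev = ev)
  })
}
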