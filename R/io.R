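#' Read and write stimulus traces
#'
#' Stimulus CSV has columns `t_s, channel, level` (one row per update); a
#' JSON sidecar (`<path>.json`) stores `update_rate`, plus any generator
#' metadata (`sigma`, `i0`, `seed`). Levels outside \[0, 255\] are a
#' validation error reporting the offending rows.
#'
#' @param stim A `stim_trace`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `read_stimulus()` returns a `stim_trace`; `write_stimulus()`
#'   returns `path` invisibly.
#' @export
write_stimulus <- function(stim, path) {
  readr::write_csv(as_tibble(stim)[, c("t_s", "channel", "level")], path)
  meta <- c(list(update_rate = attr(stim, "update_rate")),
            attr(stim, "meta"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          t_s = readr::col_double(),
                          channel = readr::col_character(),
                          level = readr::col_double()))
  bad <- which(df$level < 0 | df$level > 255 | !is.finite(df$level))
  if (length(bad)) {
    abort(sprintf("Stimulus levels outside [0, 255] at row(s): %s",
                  paste(head(bad, 10), collapse = ", ")),
          class = "navlnp_validation_error")
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  rate <- meta$update_rate %||%
    (1 / stats::median(diff(df$t_s)))
  out <- structure(df, class = c("stim_trace", class(df)),
                   update_rate = rate,
                   meta = meta[setdiff(names(meta), "update_rate")])
  out
}

#' Read, write and validate event tables
#'
#' Event CSV columns: `track_id, event_type, t_start_s, t_end_s,
#' heading_change_deg, accepted, sweep_index, parent_turn_id`. Validation
#' checks (with offending row numbers): known event types, `t_end >=
#' t_start`, time-ordered non-overlapping run/turn intervals within each
#' track, and a parent turn for every head sweep.
#'
#' @param events Event table tibble.
#' @param path CSV path.
#' @return `read_events()` returns a validated tibble; `write_events()`
#'   returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          track_id = readr::col_integer(),
                          event_type = readr::col_character(),
                          t_start_s = readr::col_double(),
                          t_end_s = readr::col_double(),
                          heading_change_deg = readr::col_double(),
                          accepted = readr::col_logical(),
                          sweep_index = readr::col_integer(),
                          parent_turn_id = readr::col_integer()))
  validate_events(df)
}

#' @rdname write_events
#' @export
validate_events <- function(events) {
  stopifnot_cols(events, c("track_id", "event_type", "t_start_s", "t_end_s"),
                 "event table")
  offenders <- function(ok, msg) {
    if (all(ok)) return(NULL)
    sprintf("%s at row(s): %s", msg,
            paste(head(which(!ok), 10), collapse = ", "))
  }
  probs <- c(
    offenders(events$event_type %in% c("run", "turn", "headsweep"),
              "unknown event_type"),
    offenders(events$t_end_s >= events$t_start_s, "t_end_s < t_start_s"))
  # run/turn state intervals must tile without overlap within a track
  st <- events[events$event_type %in% c("run", "turn"), ] |>
    arrange(.data$track_id, .data$t_start_s) |>
    group_by(.data$track_id) |>
    mutate(overlap = .data$t_start_s < lag(.data$t_end_s, default = -Inf) - 1e-9) |>
    ungroup()
  if (any(st$overlap)) {
    probs <- c(probs, sprintf(
      "overlapping run/turn intervals (track %s near t = %.2f s)",
      st$track_id[which(st$overlap)[1]],
      st$t_start_s[which(st$overlap)[1]]))
  }
  hs <- events[events$event_type == "headsweep", ]
  if (nrow(hs) && anyNA(hs$parent_turn_id)) {
    probs <- c(probs, "head sweep(s) without parent_turn_id")
  }
  if (length(probs)) {
    abort(paste(c("Event table validation failed:", probs), collapse = "\n"),
          class = "navlnp_validation_error")
  }
  events
}

#' Restrict an event table to a time window
#'
#' Keeps turns and head sweeps starting inside `[t0, t1)` and clips run
#' intervals to the window (used for split-half stability analyses).
#'
#' @param events Event table.
#' @param window Two-element numeric `c(t0, t1)`.
#' @return Filtered event table.
#' @export
filter_events_window <- function(events, window) {
  ev <- events |>
    filter(!(.data$t_end_s <= window[1] | .data$t_start_s >= window[2]))
  runs <- ev$event_type == "run"
  ev$t_start_s[runs] <- pmax(ev$t_start_s[runs], window[1])
  ev$t_end_s[runs] <- pmin(ev$t_end_s[runs], window[2])
  ev |> filter(.data$event_type == "run" |
                 (.data$t_start_s >= window[1] & .data$t_start_s < window[2]))
}

#' Run the full reverse-correlation pipeline
#'
#' Orchestrates the analysis end to end from an experiment manifest:
#' read stimuli and events, differentiate and resample the stimuli, compute
#' per-channel turn-triggered averages, smooth them into kernels, filter the
#' signals, and estimate the nonlinearity (unimodal) or fit and compare the
#' two integration models plus KL information measures (multimodal). All
#' numeric outputs are deterministic given the manifest seeds.
#'
#' The manifest is a list (or path to a JSON file) with fields:
#' `stimuli` (named list channel -> CSV path), `events` (CSV path),
#' `frame_rate` (default 14), `channel_signs` (named, +1/-1; -1 negates the
#' derivative, the fictive-odor convention), `kernel_support_s` (default 5),
#' `mode` (`"unimodal"` or `"multimodal"`), `split_half` (logical), `seed`.
#'
#' @param manifest List or JSON path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects; writes CSV/JSON
#'   files into `out_dir`.
#' @export
run_pipeline <- function(manifest, out_dir) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fr <- manifest$frame_rate %||% 14
  supp <- manifest$kernel_support_s %||% 5
  mode <- manifest$mode %||% "unimodal"
  seed <- manifest$seed %||% 1

  chans <- names(manifest$stimuli)
  if (mode == "unimodal" && length(chans) != 1) {
    abort("Unimodal pipeline expects exactly one stimulus channel.",
          class = "navlnp_invalid_argument")
  }
  if (mode == "multimodal" && length(chans) != 2) {
    abort("Multimodal pipeline expects exactly two stimulus channels.",
          class = "navlnp_invalid_argument")
  }
  signs <- manifest$channel_signs %||% setNames(rep(1, length(chans)), chans)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "navlnp_pipeline_error")
    })
  }
  signals <- stage("read_stimulus", lapply(setNames(chans, chans), function(ch) {
    resample_to_frames(
      stim_derivative(read_stimulus(manifest$stimuli[[ch]]),
                      sign = signs[[ch]] %||% 1), fr)
  }))
  events <- stage("read_events", read_events(manifest$events))

  analyse <- function(ev, tag) {
    res <- list()
    for (ch in chans) {
      tta <- triggered_average(ev, signals[[ch]])
      kf <- fit_kernel(tta, support_s = supp, dt = 1 / fr)
      readr::write_csv(as_tibble(tta),
                       file.path(out_dir, sprintf("tta_%s%s.csv", ch, tag)))
      readr::write_csv(as_tibble(kf$kernel),
                       file.path(out_dir, sprintf("kernel_%s%s.csv", ch, tag)))
      res[[ch]] <- list(tta = tta, kernel_fit = kf,
                        filtered = apply_filter(kf$kernel, signals[[ch]]))
    }
    if (mode == "unimodal") {
      if (length(chans) != 1) {
        abort("Unimodal pipeline expects exactly one stimulus channel.",
              class = "navlnp_invalid_argument")
      }
      f1 <- res[[chans[1]]]$filtered
      nl_est <- binned_turn_rate(f1, ev, dt = 1 / fr)
      rog <- fit_rog(f1, ev, dt = 1 / fr)
      readr::write_csv(as_tibble(nl_est),
                       file.path(out_dir, sprintf("nl_%s%s.csv", chans[1], tag)))
      res$rog <- rog
      res$summary <- list(mode = mode, rog = tidy(rog),
                          n_turn = rog$n_turn, run_time_s = rog$run_time_s)
    } else {
      if (length(chans) != 2) {
        abort("Multimodal pipeline expects exactly two stimulus channels.",
              class = "navlnp_invalid_argument")
      }
      ens <- build_ensemble(ev, res[[chans[1]]]$filtered,
                            res[[chans[2]]]$filtered, dt = 1 / fr)
      fit_lin <- fit_linear_combination(ens, seed = seed)
      fit_ind <- fit_independent(ens, seed = seed)
      rot <- rotate_filtered(ens, fit_lin$params$theta_deg)
      kl <- list(
        pair = kl_divergence(ens$turn, ens$ref, "knn", seed = seed),
        u = kl_divergence(rot$turn$u, rot$ref$u, "knn", seed = seed),
        v = kl_divergence(rot$turn$v, rot$ref$v, "knn", seed = seed))
      res$ensemble <- ens
      res$fits <- list(linear = fit_lin, independent = fit_ind)
      res$summary <- list(
        mode = mode,
        cross_moment = cross_moment(ens),
        linear = fit_lin$params, independent = fit_ind$params,
        loglik = c(linear = fit_lin$loglik, independent = fit_ind$loglik),
        aic = c(linear = fit_lin$aic, independent = fit_ind$aic),
        relative_likelihood_independent_vs_linear =
          aic_compare(fit_ind, fit_lin),
        kl_nats = lapply(kl, function(z) z$value),
        n_turn = ens$n_turn, run_time_s = ens$run_time_s)
    }
    res
  }

  if (isTRUE(manifest$split_half)) {
    tr <- range(events$t_start_s)
    mid <- mean(tr)
    res <- list(
      first = analyse(filter_events_window(events, c(tr[1], mid)), "_h1"),
      second = analyse(filter_events_window(events, c(mid, tr[2] + 1)), "_h2"))
    summary <- list(split_half = TRUE,
                    first = res$first$summary, second = res$second$summary)
  } else {
    res <- analyse(events, "")
    summary <- res$summary
  }
  summary$provenance <- list(
    package_version = as.character(utils::packageVersion("navlnp")),
    inputs = lapply(c(manifest$stimuli, list(events = manifest$events)),
                    function(p) unname(tools::md5sum(p))),
    seed = seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}
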