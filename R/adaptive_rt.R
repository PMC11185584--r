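#' Build a compressed binned DIA reference map
#'
#' Compresses a DIA run into the reference used for real-time retention-time
#' alignment: per wide isolation window, fragment intensities are binned to
#' `bin_width` Thomson, resampled onto a uniform retention-time grid, and
#' each (window, grid point) vector is L2-normalized. Compression here is
#' binning plus normalization; the serialized container is documented in
#' [save_reference()].
#'
#' @param run a `dia_run` (see [generate_warped_run()]), typically replayed
#'   with the identity warp from a prior acquisition.
#' @param bin_width fragment m/z bin width, Thomson.
#' @param rt_step grid spacing, seconds; defaults to the run's cycle period
#'   (which itself defaults to peak width / 3.5, the cadence of the
#'   real-time target-list updates).
#' @return a `reference_map`: list with `dia_windows`, `rt_grid` (minutes),
#'   `bin_width`, `frag_range`, `spectra` (one `n_bins x n_rt` matrix per
#'   window, columns L2-normalized) and `version`.
#' @export
build_reference <- function(run, bin_width = 1, rt_step = NULL) {
  stopifnot(inherits(run, "dia_run"))
  if (!nrow(run$events))
    stop_prmflow("cannot build a reference from a run with no spectra",
                 class = "empty_run")
  if (is.null(rt_step)) rt_step <- run$rt_step
  rt_grid <- seq(0, run$gradient_length, by = sec_to_min(rt_step))
  n_bins <- as.integer(ceiling(diff(run$frag_range) / bin_width))
  n_win <- nrow(run$dia_windows)
  spectra <- vector("list", n_win)
  ev <- run$events
  ev$bin <- pmin(n_bins,
                 as.integer(floor((ev$mz - run$frag_range[1]) / bin_width)) + 1L)
  for (w in seq_len(n_win)) {
    e <- ev[ev$window == w, , drop = FALSE]
    M <- matrix(0, n_bins, length(run$times))
    if (nrow(e)) {
      agg <- tapply(e$intensity, list(e$bin, e$cycle), sum)
      M[cbind(as.integer(rep(rownames(agg), ncol(agg))),
              as.integer(rep(colnames(agg), each = nrow(agg))))] <-
        ifelse(is.na(as.numeric(agg)), 0, as.numeric(agg))
    }
    R <- matrix(0, n_bins, length(rt_grid))
    nz <- which(rowSums(M) > 0)
    for (b in nz)
      R[b, ] <- stats::approx(run$times, M[b, ], xout = rt_grid,
                              yleft = 0, yright = 0)$y
    nrm <- sqrt(colSums(R^2))
    pos <- nrm > 0
    R[, pos] <- sweep(R[, pos, drop = FALSE], 2, nrm[pos], "/")
    spectra[[w]] <- R
  }
  structure(list(dia_windows = run$dia_windows, rt_grid = rt_grid,
                 bin_width = bin_width, frag_range = run$frag_range,
                 spectra = spectra, version = 1L),
            class = "reference_map")
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf(
    "<reference_map> v%d: %d DIA windows x %d RT points (%.2f s step), %d bins of %.2g Th\n",
    x$version, nrow(x$dia_windows), length(x$rt_grid),
    min_to_sec(if (length(x$rt_grid) > 1) diff(x$rt_grid[1:2]) else 0),
    nrow(x$spectra[[1]]), x$bin_width))
  invisible(x)
}

#' Bin one observed DIA cycle like a reference map
#'
#' @param run a `dia_run`.
#' @param cycle cycle index into `run$times`.
#' @param ref the `reference_map` whose binning to match.
#' @return a `dia_cycle`: list with `t_obs` (minutes) and `vectors`, an
#'   `n_bins x n_windows` matrix of raw binned intensities.
#' @export
observed_cycle <- function(run, cycle, ref) {
  e <- run$events[run$events$cycle == cycle, , drop = FALSE]
  n_bins <- nrow(ref$spectra[[1]])
  n_win <- length(ref$spectra)
  V <- matrix(0, n_bins, n_win)
  if (nrow(e)) {
    b <- pmin(n_bins,
              as.integer(floor((e$mz - ref$frag_range[1]) / ref$bin_width)) + 1L)
    for (r in seq_len(nrow(e)))
      V[b[r], e$window[r]] <- V[b[r], e$window[r]] + e$intensity[r]
  }
  structure(list(t_obs = run$times[cycle], vectors = V), class = "dia_cycle")
}

#' Alignment state for real-time retention-time estimation
#'
#' Holds the anchor pairs (reference time, observed time) accumulated
#' during a run and exposes the current monotone reference-to-observed time
#' mapping. The mapping is a linear interpolation through the anchors after
#' a weighted isotonic (pool-adjacent-violators) fit, with the shift held
#' constant beyond the outermost anchors; with no anchors it is the
#' identity. Anchors are exponentially down-weighted with observed-time age
#' over `horizon` minutes so the mapping can follow nonlinear, irregular
#' drift.
#'
#' @param update_period target-list refresh period, seconds; by convention
#'   the peak width divided by 3.5.
#' @param search_band half-width of the candidate reference-time search
#'   band, minutes.
#' @param horizon age scale for anchor down-weighting, minutes.
#' @param score_floor minimum mean cosine similarity for an anchor to be
#'   accepted.
#' @return an `alignment_state`.
#' @export
alignment_state <- function(update_period, search_band = 2, horizon = 5,
                            score_floor = 0.2) {
  stopifnot(update_period > 0, search_band > 0, horizon > 0)
  structure(list(anchors = data.frame(t_ref = numeric(), t_obs = numeric()),
                 fitted = data.frame(t_ref = numeric(), t_obs = numeric()),
                 update_period = update_period, search_band = search_band,
                 horizon = horizon, score_floor = score_floor,
                 last_update = -Inf, n_rejected = 0L),
            class = "alignment_state")
}

#' @export
print.alignment_state <- function(x, ...) {
  cat(sprintf("<alignment_state> %d anchors (%d rejected), update period %.2f s\n",
              nrow(x$anchors), x$n_rejected, x$update_period))
  if (nrow(x$fitted))
    cat(sprintf("  current shift at last anchor: %+.3f min\n",
                x$fitted$t_obs[nrow(x$fitted)] -
                x$fitted$t_ref[nrow(x$fitted)]))
  invisible(x)
}

refit_anchors <- function(state) {
  a <- state$anchors
  if (!nrow(a)) {
    state$fitted <- a
    return(state)
  }
  now <- max(a$t_obs)
  w <- exp(-(now - a$t_obs) / state$horizon)
  o <- order(a$t_ref)
  fit <- pava(a$t_obs[o], w[o])
  f <- data.frame(t_ref = a$t_ref[o], t_obs = fit)
  ## collapse duplicated reference times to their fitted mean
  f <- stats::aggregate(t_obs ~ t_ref, f, mean)
  state$fitted <- f[order(f$t_ref), , drop = FALSE]
  state
}

#' Map reference time to observed time under the current alignment
#'
#' @param state an `alignment_state`.
#' @param t reference time(s), minutes.
#' @return predicted observed time(s), monotone nondecreasing in `t`.
#' @export
warp_time <- function(state, t) {
  f <- state$fitted
  if (nrow(f) < 1) return(t)
  if (nrow(f) == 1) return(t + (f$t_obs - f$t_ref))
  shift <- stats::approx(f$t_ref, f$t_obs - f$t_ref, xout = t, rule = 2,
                         ties = mean)$y
  t + shift
}

#' Estimated retention-time shift at a reference time
#' @inheritParams warp_time
#' @return `warp_time(state, t) - t`, minutes.
#' @export
rt_shift <- function(state, t) warp_time(state, t) - t

## inverse of warp_time: observed -> reference
invert_warp <- function(state, t_obs) {
  f <- state$fitted
  if (nrow(f) < 1) return(t_obs)
  if (nrow(f) == 1) return(t_obs - (f$t_obs - f$t_ref))
  shift <- stats::approx(f$t_obs, f$t_obs - f$t_ref, xout = t_obs, rule = 2,
                         ties = mean)$y
  t_obs - shift
}

#' Estimate the retention-time shift from one observed DIA cycle
#'
#' Compares the observed binned spectra against the reference map at every
#' grid point within `search_band` of the currently predicted reference
#' position, scoring each candidate by the mean cosine similarity across
#' DIA windows (windows empty in either side are skipped). The best
#' candidate becomes a new anchor (reference time, observed time) unless
#' its score falls below the floor, in which case the state is returned
#' unchanged apart from a rejection count. The anchor set is refit with a
#' weighted isotonic regression so the mapping stays monotone.
#'
#' @param ref a `reference_map`.
#' @param cycle a `dia_cycle` from [observed_cycle()], binned identically to
#'   `ref`.
#' @param state an `alignment_state`.
#' @return the updated `alignment_state`.
#' @export
estimate_shift <- function(ref, cycle, state) {
  stopifnot(inherits(ref, "reference_map"), inherits(cycle, "dia_cycle"),
            inherits(state, "alignment_state"))
  t_pred <- invert_warp(state, cycle$t_obs)
  cand <- which(abs(ref$rt_grid - t_pred) <= state$search_band)
  if (!length(cand)) return(state)
  obs <- cycle$vectors
  obs_nrm <- sqrt(colSums(obs^2))
  scores <- rep(0, length(cand))
  n_used <- rep(0L, length(cand))
  for (w in seq_len(ncol(obs))) {
    if (obs_nrm[w] == 0) next
    R <- ref$spectra[[w]][, cand, drop = FALSE]
    ref_nrm <- sqrt(colSums(R^2))     # 1 where defined, 0 where empty
    cs <- as.numeric(crossprod(obs[, w], R)) / obs_nrm[w]
    use <- ref_nrm > 0
    scores[use] <- scores[use] + cs[use]
    n_used[use] <- n_used[use] + 1L
  }
  ok <- n_used > 0
  if (!any(ok)) return(state)
  scores[ok] <- scores[ok] / n_used[ok]
  scores[!ok] <- -Inf
  top <- max(scores)
  if (top < state$score_floor) {
    state$n_rejected <- state$n_rejected + 1L
    return(state)
  }
  ## near-ties (e.g. a lone precursor, whose normalized pattern is the same
  ## at every point of its elution) resolve to the candidate nearest the
  ## predicted position
  near <- which(scores >= top - 1e-3)
  best <- cand[near[which.min(abs(ref$rt_grid[cand[near]] - t_pred))]]
  state$anchors <- rbind(state$anchors,
                         data.frame(t_ref = ref$rt_grid[best],
                                    t_obs = cycle$t_obs))
  refit_anchors(state)
}

#' Active target set at a time point
#'
#' A target is active when the current moment falls inside its scheduling
#' window mapped through the alignment warp. During acquisition this set is
#' recomputed every `update_period` seconds (3.5 times per peak width);
#' [simulate_run()] enforces that cadence, this function just evaluates the
#' set.
#'
#' @param plan a `schedule_plan`.
#' @param state an `alignment_state` (identity mapping when it has no
#'   anchors).
#' @param now current observed time, minutes.
#' @param injection injection index.
#' @return character vector of active precursor keys.
#' @export
update_active_targets <- function(plan, state, now, injection = 1L) {
  e <- plan$entries[plan$entries$injection == injection, , drop = FALSE]
  ws <- warp_time(state, e$window_start)
  we <- warp_time(state, e$window_end)
  e$key[now >= ws & now <= we]
}

#' Simulate a PRM acquisition with or without adaptive alignment
#'
#' Replays a library through a retention-time warp and simulates the
#' acquisition loop: every `update_period` seconds one alignment DIA cycle
#' is observed; with adaptation on it updates the shift estimate and the
#' active target set, with adaptation off the static schedule is used.
#' Between updates the instrument cycles over the active targets at the
#' plan's cycle time. The log records, per target, whether its (warped)
#' apex fell inside an active window and how many sampling points landed
#' across its peak base.
#'
#' @param plan a `schedule_plan` (single injection).
#' @param lib the [chrom_library()] behind the plan.
#' @param warp monotone time-warp applied to the run.
#' @param ref a `reference_map`; built from an identity-warp replay of
#'   `lib` when `NULL`.
#' @param adaptive logical; `FALSE` freezes the identity alignment.
#' @param noise_cv multiplicative noise on observed DIA intensities.
#' @param bin_width reference bin width, Thomson (used when `ref` is NULL).
#' @param seed integer seed; identical seeds give identical logs.
#' @return list with `log` (per-target data frame: `key`, `true_apex`,
#'   `captured`, `n_points`), `alignment` (per-update data frame: `t_obs`,
#'   `shift_est`, `shift_true`, `anchor_err`), `n_updates`, and the final
#'   `state`.
#' @export
simulate_run <- function(plan, lib, warp = identity, ref = NULL,
                         adaptive = TRUE, noise_cv = 0, bin_width = 1,
                         seed = 1L) {
  stopifnot(inherits(plan, "schedule_plan"), inherits(lib, "chrom_library"))
  pw <- plan$params$expected_peak_width
  up <- pw / 3.5
  if (is.null(ref)) {
    ref_run <- generate_warped_run(lib, identity, rt_step = up,
                                   noise_cv = 0, seed = seed)
    ref <- build_reference(ref_run, bin_width = bin_width, rt_step = up)
  }
  run <- generate_warped_run(lib, warp, rt_step = up, noise_cv = noise_cv,
                             seed = seed)
  truth <- library_truth(run)
  truth$key <- precursor_key(truth$peptide, truth$charge)
  e <- plan$entries
  n_t <- nrow(e)
  times <- run$times
  n_c <- length(times)
  state <- alignment_state(update_period = up)
  active <- matrix(FALSE, n_t, n_c)
  align_log <- data.frame(t_obs = times, shift_est = NA_real_,
                          shift_true = NA_real_, anchor_err = NA_real_)
  tt <- seq(0, lib$gradient_length, length.out = 256)
  true_shift_at_obs <- function(t) {
    ## shift s such that warp(r) = t, expressed as t - r
    stats::approx(warp(tt), warp(tt) - tt, xout = t, rule = 2)$y
  }
  n_updates <- 0L
  for (k in seq_len(n_c)) {
    if (adaptive && times[k] - state$last_update >= sec_to_min(up) - 1e-9) {
      cyc <- observed_cycle(run, k, ref)
      state <- estimate_shift(ref, cyc, state)
      state$last_update <- times[k]
      n_updates <- n_updates + 1L
      if (nrow(state$anchors)) {
        last <- state$anchors[nrow(state$anchors), ]
        align_log$anchor_err[k] <- abs(warp(last$t_ref) - last$t_obs)
      }
    }
    align_log$shift_est[k] <- rt_shift(state, invert_warp(state, times[k]))
    align_log$shift_true[k] <- true_shift_at_obs(times[k])
    keys <- update_active_targets(plan, state, times[k])
    active[, k] <- e$key %in% keys
  }
  apex <- truth$true_apex[match(e$key, truth$key)]
  half_base <- sec_to_min(precursor_table(lib)$peak_width[
    match(e$key, precursor_table(lib)$key)] / 2)
  apex_cycle <- pmin(pmax(findInterval(apex, times), 1L), n_c)
  captured <- active[cbind(seq_len(n_t), apex_cycle)]
  prm_times <- seq(0, lib$gradient_length, by = sec_to_min(plan$cycle_time))
  prm_cycle <- pmin(pmax(findInterval(prm_times, times), 1L), n_c)
  n_points <- integer(n_t)
  for (i in seq_len(n_t)) {
    in_peak <- abs(prm_times - apex[i]) <= half_base[i]
    n_points[i] <- sum(in_peak & active[i, prm_cycle])
  }
  list(log = data.frame(key = e$key, true_apex = apex, captured = captured,
                        n_points = n_points, stringsAsFactors = FALSE),
       alignment = align_log, n_updates = n_updates, state = state)
}
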