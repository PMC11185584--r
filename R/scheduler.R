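#' Instrument acquisition parameters and duty-cycle model
#'
#' Describes the duty cycle of a scanning instrument well enough to decide
#' how many concurrent PRM targets it can sustain: the mass-analyzer scan
#' rate and scan range set the per-spectrum analysis time, the (minimum)
#' injection time and inter-scan overhead add per-target dead time, and the
#' points-per-peak requirement together with the expected chromatographic
#' peak width sets the cycle time budget. The defaults correspond to a
#' linear ion trap scanning 200-1500 Th at 125 kDa/s (125,000 Th/s) with a
#' 15 ms minimum injection time, targeting 6 points across a 12.9 s peak.
#' Dynamic maximum injection-time modes are modeled conservatively at the
#' fixed minimum target injection time.
#'
#' @param scan_rate analyzer scan rate, Thomson per second.
#' @param scan_lo,scan_hi MS2 scan range, Thomson.
#' @param min_injection_time minimum target injection time, milliseconds.
#' @param interscan_overhead per-scan overhead, milliseconds.
#' @param points_per_peak desired sampling points across a peak.
#' @param expected_peak_width expected LC base peak width, seconds.
#' @param min_window minimum scheduling window width, minutes.
#' @param max_window cap on optimized window width, minutes.
#' @param gradient_length gradient length, minutes.
#' @return an `acquisition_params` list.
#' @export
acquisition_params <- function(scan_rate = 125000, scan_lo = 200,
                               scan_hi = 1500, min_injection_time = 15,
                               interscan_overhead = 2,
                               points_per_peak = 6L,
                               expected_peak_width = 12.9,
                               min_window = 0.75, max_window = 2,
                               gradient_length = 30) {
  stopifnot(scan_lo < scan_hi, scan_rate > 0, points_per_peak >= 1,
            expected_peak_width > 0, min_window > 0,
            max_window >= min_window, min_injection_time >= 0,
            interscan_overhead >= 0, gradient_length > 0)
  structure(list(scan_rate = scan_rate, scan_lo = scan_lo, scan_hi = scan_hi,
                 min_injection_time = min_injection_time,
                 interscan_overhead = interscan_overhead,
                 points_per_peak = as.integer(points_per_peak),
                 expected_peak_width = expected_peak_width,
                 min_window = min_window, max_window = max_window,
                 gradient_length = gradient_length),
            class = "acquisition_params")
}

#' Cycle time from peak width and points per peak
#'
#' The cycle time is the time available for one pass over all concurrent
#' targets while still sampling each chromatographic peak the desired
#' number of times: `peak_width / points_per_peak`. For example a 12.9 s
#' peak at 6 points per peak gives a 2.15 s cycle. The exact value is
#' returned; round to 0.01 s for display.
#'
#' @param peak_width base peak width, seconds.
#' @param points_per_peak desired points across the peak.
#' @return cycle time in seconds.
#' @export
compute_cycle_time <- function(peak_width, points_per_peak) {
  if (any(points_per_peak == 0))
    stop_prmflow("points_per_peak must be >= 1", class = "invalid_params")
  stopifnot(all(peak_width > 0), all(points_per_peak >= 1))
  peak_width / points_per_peak
}

#' Per-target scan time under the duty-cycle model
#'
#' Time one targeted MS2 scan occupies the instrument: the scan-range sweep
#' at the analyzer scan rate plus injection time and inter-scan overhead,
#' `(scan_hi - scan_lo)/scan_rate + (min_injection_time +
#' interscan_overhead)/1000` seconds.
#'
#' @param params an [acquisition_params()].
#' @return seconds per target per cycle.
#' @export
per_target_time <- function(params) {
  stopifnot(inherits(params, "acquisition_params"))
  (params$scan_hi - params$scan_lo) / params$scan_rate +
    (params$min_injection_time + params$interscan_overhead) / 1000
}

#' Maximum sustainable number of concurrent targets
#'
#' `floor(cycle_time / per_target_time)`: the largest number of targets
#' whose scans fit into one cycle while preserving the points-per-peak
#' sampling. Returns 0 with a warning when a single target does not fit.
#'
#' @param params an [acquisition_params()].
#' @return integer capacity.
#' @export
capacity <- function(params) {
  ct <- compute_cycle_time(params$expected_peak_width, params$points_per_peak)
  ptt <- per_target_time(params)
  if (ptt > ct) {
    warning("per-target time exceeds the cycle time; capacity is 0")
    return(0L)
  }
  as.integer(floor(ct / ptt + 1e-9))
}

## maximum concurrency of closed windows [ws, we] over interval [a, b]
## (counts at interval ends and at every window edge falling inside)
max_concurrency_in <- function(ws, we, a, b) {
  pts <- c(a, b, ws[ws > a & ws < b], we[we > a & we < b])
  if (!length(pts)) return(0L)
  max(vapply(pts, function(p) sum(ws <= p & we >= p), 0L))
}

## full concurrency profile at window-edge event points
profile_points <- function(ws, we) {
  pts <- sort(unique(c(ws, we)))
  cnt <- vapply(pts, function(p) sum(ws <= p & we >= p), 0L)
  data.frame(time = pts, count = cnt)
}

new_schedule_plan <- function(entries, params, injections = 1L) {
  ct <- compute_cycle_time(params$expected_peak_width, params$points_per_peak)
  ptt <- per_target_time(params)
  cap <- capacity(params)
  feasible <- TRUE
  max_conc <- 0L
  violations <- NULL
  profiles <- list()
  for (inj in seq_len(injections)) {
    e <- entries[entries$injection == inj, , drop = FALSE]
    if (!nrow(e)) next
    prof <- profile_points(e$window_start, e$window_end)
    profiles[[inj]] <- prof
    max_conc <- max(max_conc, max(prof$count))
    bad <- prof$count > cap
    if (any(bad)) {
      feasible <- FALSE
      violations <- rbind(violations,
                          data.frame(injection = inj,
                                     time = prof$time[bad],
                                     count = prof$count[bad]))
    }
  }
  structure(list(entries = entries, params = params,
                 cycle_time = ct, per_target_time = ptt, capacity = cap,
                 n_injections = injections, max_concurrent = max_conc,
                 feasible = feasible, violations = violations,
                 profiles = profiles),
            class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  cat(sprintf("<schedule_plan> %d targets in %d injection(s)\n",
              nrow(x$entries), x$n_injections))
  cat(sprintf("  cycle time %.2f s, per-target %.4f s, capacity %d concurrent\n",
              x$cycle_time, x$per_target_time, x$capacity))
  cat(sprintf("  max concurrent %d -> %s\n", x$max_concurrent,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  if (!is.null(x$violations))
    cat(sprintf("  %d violating time point(s), e.g. %.2f min (%d concurrent)\n",
                nrow(x$violations), x$violations$time[1],
                x$violations$count[1]))
  invisible(x)
}

#' Concurrency profile of a schedule plan
#'
#' @param plan a `schedule_plan`.
#' @param injection injection index.
#' @return data frame `time` (minutes, at window-edge event points) and
#'   `count` (number of concurrently scheduled targets).
#' @export
concurrency_profile <- function(plan, injection = 1L) {
  stopifnot(inherits(plan, "schedule_plan"))
  plan$profiles[[injection]]
}

#' @export
plot.schedule_plan <- function(x, injection = 1L, ...) {
  prof <- concurrency_profile(x, injection)
  graphics::plot(prof$time, prof$count, type = "s", xlab = "retention time (min)",
                 ylab = "concurrent precursors", ...)
  graphics::abline(h = x$capacity, lty = 2)
  invisible(x)
}

#' Assign scheduling windows to a filtered library
#'
#' Every precursor receives an acquisition window of at least `min_window`
#' minutes centered on its reference retention time. Windows then grow
#' symmetrically in fixed increments (default 0.05 min), processing
#' precursors in ascending `ref_rt` order (ties broken by peptide string),
#' each stopping when further growth would push the concurrency above the
#' duty-cycle capacity anywhere, exceed `max_window`, or leave the
#' gradient. Growth proceeds in round-robin passes so early-eluting
#' precursors cannot starve later ones. The procedure is deterministic.
#'
#' @param lib a (filtered) [chrom_library()].
#' @param params an [acquisition_params()].
#' @param grow if `FALSE`, keep all windows at `min_window`.
#' @param increment growth step per side per pass, minutes.
#' @return a `schedule_plan`; `feasible` is `FALSE` when even minimum-width
#'   windows exceed capacity somewhere, in which case the violating time
#'   points are listed in `$violations`.
#' @export
assign_windows <- function(lib, params = acquisition_params(), grow = TRUE,
                           increment = 0.05) {
  stopifnot(inherits(lib, "chrom_library"),
            inherits(params, "acquisition_params"))
  tab <- precursor_table(lib)
  ord <- order(tab$ref_rt, tab$peptide)
  tab <- tab[ord, , drop = FALSE]
  grad <- params$gradient_length
  half <- params$min_window / 2
  ws <- round(pmin(pmax(tab$ref_rt - half, 0), grad - params$min_window), 6)
  we <- round(ws + params$min_window, 6)
  cap <- capacity(params)
  n <- nrow(tab)

  if (grow && n && max(profile_points(ws, we)$count) <= cap) {
    active <- rep(TRUE, n)
    while (any(active)) {
      for (i in which(active)) {
        new_s <- round(max(0, ws[i] - increment), 6)
        new_e <- round(min(grad, we[i] + increment), 6)
        if (new_e - new_s > params$max_window + 1e-9 ||
            (new_s == ws[i] && new_e == we[i])) {
          active[i] <- FALSE
          next
        }
        old_s <- ws[i]; old_e <- we[i]
        ws[i] <- new_s; we[i] <- new_e
        ## expansion can only raise concurrency inside the two new slices
        ok <- max_concurrency_in(ws, we, new_s, old_s) <= cap &&
              max_concurrency_in(ws, we, old_e, new_e) <= cap
        if (!ok) {
          ws[i] <- old_s; we[i] <- old_e
          active[i] <- FALSE
        }
      }
    }
  }
  entries <- data.frame(peptide = tab$peptide, charge = tab$charge,
                        precursor_mz = tab$precursor_mz,
                        ref_rt = tab$ref_rt,
                        window_start = ws, window_end = we,
                        injection = 1L,
                        priority = seq_len(n),
                        key = tab$key,
                        stringsAsFactors = FALSE)
  new_schedule_plan(entries, params)
}

#' Select targets under the duty-cycle constraint
#'
#' Greedy target selection when the full library does not fit. With
#' `objective = "max_precursors"`, precursors are admitted in priority
#' order (descending clean-transition count, ties by descending total
#' area) as long as their minimum-width window keeps concurrency within
#' capacity. With `objective = "max_proteins"`, proteins take turns
#' admitting their next-best precursor, up to `per_protein_quota` each,
#' before any remaining precursors are admitted by plain priority; this
#' protein-fair round robin never covers fewer distinct proteins than the
#' precursor-greedy objective on the same input. Both are deterministic.
#'
#' @param lib a filtered [chrom_library()].
#' @param params an [acquisition_params()].
#' @param objective `"max_precursors"` or `"max_proteins"`.
#' @param per_protein_quota round-robin quota per protein before the
#'   overflow phase.
#' @return the selected [chrom_library()] subset.
#' @export
select_targets <- function(lib, params = acquisition_params(),
                           objective = c("max_precursors", "max_proteins"),
                           per_protein_quota = 2L) {
  objective <- match.arg(objective)
  tab <- precursor_table(lib)
  n <- nrow(tab)
  if (!n) return(lib)
  n_clean <- vapply(seq_len(n), function(i)
    lib$precursors[[i]]$n_clean %||% NA_integer_, 0L)
  if (anyNA(n_clean)) n_clean[is.na(n_clean)] <- tab$n_transitions[is.na(n_clean)]
  prio <- order(-n_clean, -tab$total_area, tab$peptide)
  cap <- capacity(params)
  grad <- params$gradient_length
  half <- params$min_window / 2
  w_s <- pmin(pmax(tab$ref_rt - half, 0), grad - params$min_window)
  w_e <- w_s + params$min_window

  sel <- logical(n)
  admit <- function(i) {
    idx <- which(sel)
    ok <- max_concurrency_in(w_s[idx], w_e[idx], w_s[i], w_e[i]) <= cap - 1L
    if (ok) sel[i] <<- TRUE
    ok
  }
  if (objective == "max_precursors") {
    for (i in prio) admit(i)
  } else {
    queues <- split(prio, tab$protein[prio])
    queues <- queues[order(names(queues))]
    got <- stats::setNames(integer(length(queues)), names(queues))
    repeat {
      any_new <- FALSE
      for (pr in names(queues)) {
        if (got[pr] >= per_protein_quota) next
        q <- queues[[pr]]
        while (length(q)) {
          i <- q[1]; q <- q[-1]
          if (admit(i)) { got[pr] <- got[pr] + 1L; any_new <- TRUE; break }
        }
        queues[[pr]] <- q
      }
      if (!any_new) break
    }
    for (i in prio) if (!sel[i]) admit(i)
  }
  subset_library(lib, which(sel))
}

#' Split a library over multiple injections
#'
#' When one injection cannot cover the library within the duty cycle, the
#' precursors are partitioned into the fewest injections the first-fit
#' heuristic finds: precursors sorted by ascending reference retention time
#' are each placed into the first injection whose plan stays feasible at
#' minimum window width, opening a new injection (up to `max_injections`)
#' only when none fits.
#'
#' @param lib a filtered [chrom_library()].
#' @param params an [acquisition_params()].
#' @param max_injections hard cap on the number of injections.
#' @param grow grow windows per injection after partitioning (see
#'   [assign_windows()]).
#' @return a `schedule_plan` with an `injection` column; injections
#'   partition the library (disjoint, exhaustive).
#' @export
split_injections <- function(lib, params = acquisition_params(),
                             max_injections = 3L, grow = TRUE) {
  tab <- precursor_table(lib)
  n <- nrow(tab)
  if (!n) return(assign_windows(lib, params, grow = grow))
  ord <- order(tab$ref_rt, tab$peptide)
  cap <- capacity(params)
  grad <- params$gradient_length
  half <- params$min_window / 2
  w_s <- pmin(pmax(tab$ref_rt - half, 0), grad - params$min_window)
  w_e <- w_s + params$min_window
  inj <- rep(NA_integer_, n)
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      idx <- groups[[k]]
      if (max_concurrency_in(w_s[idx], w_e[idx], w_s[i], w_e[i]) <= cap - 1L) {
        groups[[k]] <- c(idx, i); inj[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      if (length(groups) >= max_injections) {
        residual <- tab$key[ord][is.na(inj[ord])]
        stop_prmflow(sprintf(
          "library infeasible within %d injections; %d residual target(s), e.g. %s",
          max_injections, length(residual),
          paste(utils::head(residual, 3), collapse = ", ")),
          class = "infeasible_split")
      }
      groups[[length(groups) + 1L]] <- i
      inj[i] <- length(groups)
    }
  }
  k <- length(groups)
  entry_list <- vector("list", k)
  for (g in seq_len(k)) {
    sub <- subset_library(lib, groups[[g]])
    plan_g <- assign_windows(sub, params, grow = grow)
    e <- plan_g$entries
    e$injection <- g
    entry_list[[g]] <- e
  }
  entries <- do.call(rbind, entry_list)
  entries$priority <- seq_len(nrow(entries))
  new_schedule_plan(entries, params, injections = max(1L, k))
}

#' Re-center wide-window schedules onto measured apexes
#'
#' After a preliminary acquisition with wide scheduling windows, re-schedule
#' at the minimum window width centered on the retention times actually
#' observed. Targets whose apex was not observed keep a minimum-width
#' window centered on their wide-window prediction and are flagged.
#'
#' @param plan_wide a `schedule_plan` from the wide-window run.
#' @param observed data frame `peptide`, `charge`, `apex_rt` (minutes) of
#'   measured apexes.
#' @return a new `schedule_plan`; its entries carry an `observed` logical
#'   column.
#' @export
wide_to_narrow_reschedule <- function(plan_wide, observed) {
  stopifnot(inherits(plan_wide, "schedule_plan"),
            all(c("peptide", "charge", "apex_rt") %in% names(observed)))
  e <- plan_wide$entries
  params <- plan_wide$params
  okey <- precursor_key(observed$peptide, observed$charge)
  m <- match(e$key, okey)
  frac <- mean(!is.na(m))
  if (frac < 0.8)
    warning(sprintf("only %.0f%% of targets have an observed apex", 100 * frac))
  center <- ifelse(is.na(m), (e$window_start + e$window_end) / 2,
                   observed$apex_rt[m])
  half <- params$min_window / 2
  grad <- params$gradient_length
  ws <- round(pmin(pmax(center - half, 0), grad - params$min_window), 6)
  e$window_start <- ws
  e$window_end <- round(ws + params$min_window, 6)
  e$ref_rt <- center
  e$observed <- !is.na(m)
  new_schedule_plan(e, params, injections = plan_wide$n_injections)
}
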