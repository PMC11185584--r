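#' Configuration for the synthetic chromatogram-library generator
#'
#' The generator emulates the structure of a gas-phase-fractionated DIA
#' chromatogram library: precursors spread uniformly over a reversed-phase
#' gradient, Gaussian elution profiles with per-precursor base widths,
#' log-normal precursor abundances split across 3-8 fragment-ion
#' transitions, and an optional co-eluting contaminant ("interference")
#' riding on one transition of a configurable fraction of precursors.
#' Gaussian peaks make analytic truth (areas, widths, apexes) exact, which
#' is what downstream parameter-recovery tests rely on; real peaks tail.
#'
#' Two presets mirror the two biofluid applications the package targets:
#' `"csf"` (about 2,300 precursors, 13.9 s average peaks, 30 min gradient,
#' as in a CSF survey assay) and `"magnet"` (about 3,500 precursors with
#' shorter peaks, as in a Mag-Net enriched plasma EV survey assay).
#'
#' @param preset `"csf"`, `"magnet"` or `"small"` (a fast unit-test scale).
#' @param n_proteins number of synthetic proteins.
#' @param precursors_per_protein integer range `c(lo, hi)`; each protein
#'   contributes a uniform draw from this range.
#' @param gradient_length gradient length, minutes.
#' @param peak_width_mean,peak_width_sd base peak width distribution,
#'   seconds (truncated below at 4 s).
#' @param log_abundance_mean,log_abundance_sd log-normal precursor
#'   abundance parameters (natural log scale, arbitrary area units).
#' @param transition_range integer range of transitions per precursor.
#' @param interference_fraction fraction of precursors carrying a
#'   co-eluting contaminant on one transition.
#' @param interference_magnitude contaminant apex height relative to the
#'   host transition's own apex height.
#' @param trace_noise_rel additive Gaussian trace noise, as a fraction of
#'   the transition's apex height.
#' @param seed integer seed; all generators are deterministic given it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(preset = c("small", "csf", "magnet"),
                             n_proteins = NULL,
                             precursors_per_protein = NULL,
                             gradient_length = NULL,
                             peak_width_mean = NULL,
                             peak_width_sd = 2.5,
                             log_abundance_mean = log(2e4),
                             log_abundance_sd = 1.2,
                             transition_range = c(3L, 8L),
                             interference_fraction = 0.1,
                             interference_magnitude = 5,
                             trace_noise_rel = 0.005,
                             seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    small  = list(n_proteins = 40L,  ppp = c(1L, 3L), grad = 30, pw = 13.9),
    csf    = list(n_proteins = 920L, ppp = c(1L, 4L), grad = 30, pw = 13.9),
    magnet = list(n_proteins = 1000L, ppp = c(2L, 5L), grad = 30, pw = 10.5))
  cfg <- list(
    preset = preset,
    n_proteins = as.integer(n_proteins %||% def$n_proteins),
    precursors_per_protein = as.integer(precursors_per_protein %||% def$ppp),
    gradient_length = gradient_length %||% def$grad,
    peak_width_mean = peak_width_mean %||% def$pw,
    peak_width_sd = peak_width_sd,
    log_abundance_mean = log_abundance_mean,
    log_abundance_sd = log_abundance_sd,
    transition_range = as.integer(transition_range),
    interference_fraction = interference_fraction,
    interference_magnitude = interference_magnitude,
    trace_noise_rel = trace_noise_rel,
    seed = as.integer(seed))
  stopifnot(cfg$interference_fraction >= 0, cfg$interference_fraction <= 1,
            cfg$peak_width_mean > 0, cfg$gradient_length > 0,
            all(cfg$transition_range >= 1))
  class(cfg) <- "generator_config"
  cfg
}

AA <- c("A","D","E","F","G","H","I","L","N","P","Q","S","T","V","W","Y")

random_peptide <- function(n) {
  len <- sample(7:15, n, replace = TRUE)
  vapply(len, function(l) {
    paste0(paste(sample(AA, l - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, "")
}

#' Generate a synthetic chromatogram library with ground truth
#'
#' @param cfg a [generator_config()].
#' @return a [chrom_library()] whose `"truth"` attribute is a data frame
#'   with one row per precursor: `peptide`, `charge`, `protein`, `ref_rt`
#'   (min), `peak_width` (s), `total_area`, `n_transitions`, `interfered`
#'   (logical) and `interfered_fragment`. Retrieve it with
#'   [library_truth()].
#' @details Each transition carries a Gaussian chromatographic trace over
#'   its integration boundaries (boundaries at apex +/- half the base
#'   width, sigma = width/4). An interfered transition additionally carries
#'   a contaminant Gaussian centered one third of a peak width late, scaled
#'   by `interference_magnitude`; its recorded area is re-integrated from
#'   the contaminated trace, as an extraction tool would report it.
#' @export
generate_library <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  ppp <- cfg$precursors_per_protein
  n_per <- sample(ppp[1]:ppp[2], cfg$n_proteins, replace = TRUE)
  n <- sum(n_per)
  protein <- rep(sprintf("P%04d", seq_len(cfg$n_proteins)), n_per)
  peptide <- random_peptide(n)
  ## extremely unlikely collisions; regenerate deterministically if any
  while (anyDuplicated(peptide))
    peptide[duplicated(peptide)] <- random_peptide(sum(duplicated(peptide)))
  charge <- sample(2:3, n, replace = TRUE, prob = c(0.7, 0.3))
  precursor_mz <- runif(n, 400, 1000)
  ref_rt <- runif(n, 0.03, 0.97) * cfg$gradient_length
  width <- pmax(4, stats::rnorm(n, cfg$peak_width_mean, cfg$peak_width_sd))
  abundance <- stats::rlnorm(n, cfg$log_abundance_mean, cfg$log_abundance_sd)
  n_trans <- sample(cfg$transition_range[1]:cfg$transition_range[2], n,
                    replace = TRUE)
  interfered <- runif(n) < cfg$interference_fraction

  precursors <- vector("list", n)
  int_frag <- rep(NA_character_, n)
  total_area <- numeric(n)
  for (i in seq_len(n)) {
    k <- n_trans[i]
    rel <- stats::rexp(k)
    rel <- rel / sum(rel)
    frag <- paste0("y", seq(3, length.out = k))
    sigma <- width[i] / 4                      # seconds
    half_span <- sec_to_min(width[i] / 2)      # minutes
    apex <- ref_rt[i]
    area_f <- abundance[i] * rel
    amp_f <- area_f / (sigma * sqrt(2 * pi))
    tgrid <- seq(apex - half_span, apex + half_span, length.out = 25)
    which_int <- if (interfered[i]) sample.int(k, 1) else 0L
    traces <- vector("list", k)
    names(traces) <- frag
    for (j in seq_len(k)) {
      y <- amp_f[j] * exp(-(min_to_sec(tgrid - apex))^2 / (2 * sigma^2))
      if (j == which_int) {
        shift <- sec_to_min(width[i] / 3)
        y <- y + cfg$interference_magnitude * amp_f[j] *
          exp(-(min_to_sec(tgrid - apex - shift))^2 / (2 * sigma^2))
        area_f[j] <- trapz(min_to_sec(tgrid), y)
      }
      if (cfg$trace_noise_rel > 0)
        y <- pmax(0, y + stats::rnorm(25, 0, cfg$trace_noise_rel * amp_f[j]))
      traces[[j]] <- data.frame(time = tgrid, intensity = y)
    }
    if (which_int > 0L) int_frag[i] <- frag[which_int]
    trans <- data.frame(fragment = frag,
                        product_mz = runif(k, 200, 1500),
                        area = area_f,
                        apex_rt = apex,
                        start_rt = apex - half_span,
                        end_rt = apex + half_span,
                        expected_rel = rel,
                        stringsAsFactors = FALSE)
    precursors[[i]] <- precursor_entry(peptide[i], charge[i], precursor_mz[i],
                                       protein[i], trans, traces)
    total_area[i] <- precursors[[i]]$total_area
  }
  lib <- chrom_library(precursors, cfg$gradient_length,
                       paste0("synthetic-", cfg$preset, "-seed", cfg$seed))
  attr(lib, "truth") <- data.frame(
    peptide = peptide, charge = charge, protein = protein,
    ref_rt = ref_rt, peak_width = width, total_area = total_area,
    n_transitions = n_trans, interfered = interfered,
    interfered_fragment = int_frag, stringsAsFactors = FALSE)
  lib
}

#' Ground-truth table of a synthetic object
#'
#' @param x an object produced by one of the generators.
#' @return the data frame of generated truth attached to `x`.
#' @export
library_truth <- function(x) attr(x, "truth")

#' Generate a matrix-matched dilution series with ground truth
#'
#' Emulates a matrix-matched calibration curve: analytes derived from the
#' study matrix (e.g. human CSF or plasma) scale proportionally with the
#' dilution level, while a configurable fraction of "background" analytes
#' originating from the surrogate matrix stay constant across levels. Each
#' transition additionally sits on a per-precursor noise floor (a constant
#' low-level contaminating signal), so the mean response versus dilution is
#' a hinge: flat at the floor below a change point and linear above it.
#'
#' @param lib a [chrom_library()], typically from [generate_library()].
#' @param levels dilution levels in percent, strictly decreasing. Default
#'   is the 13-point volumetric ladder 100 down to 0.1.
#' @param replicates replicate injections per level.
#' @param noise_cv multiplicative measurement noise, as a coefficient of
#'   variation (fraction, e.g. 0.1 = 10 percent).
#' @param floor_frac_range range (fractions of the 100 percent signal) from
#'   which each precursor's noise-floor level is drawn log-uniformly. Use
#'   `c(0, 0)` for a floor-free, perfectly linear curve.
#' @param background_fraction fraction of precursors behaving as surrogate
#'   matrix background (constant area at every level).
#' @param contaminated_fraction fraction of precursors whose largest
#'   transition carries a strong constant contaminant (on the order of its
#'   100 percent signal), degrading the summed-area figures of merit until
#'   that transition is removed.
#' @param drift_sd run-to-run retention-time shift standard deviation
#'   (minutes); each (level, replicate) run gets one shared offset.
#' @param traces if `TRUE`, per-transition Gaussian traces are attached for
#'   every sample so areas can be re-integrated after boundary
#'   propagation. Intended for small libraries.
#' @param seed integer seed.
#' @return a [cal_curve()] whose `"truth"` attribute records, per
#'   precursor: `background`, `floor_frac`, `change_level` (the dilution
#'   percent at which signal equals the floor), `contaminated_fragment`,
#'   and per-run true retention-time offsets in `attr(, "run_truth")`.
#' @export
generate_dilution_series <- function(lib,
                                     levels = c(100, 70, 50, 30, 10, 7, 5, 3,
                                                1, 0.7, 0.5, 0.3, 0.1),
                                     replicates = 3,
                                     noise_cv = 0.1,
                                     floor_frac_range = c(0.003, 0.10),
                                     background_fraction = 0,
                                     contaminated_fraction = 0,
                                     drift_sd = 0.05,
                                     traces = FALSE,
                                     seed = 1L) {
  stopifnot(inherits(lib, "chrom_library"), all(diff(levels) < 0))
  set.seed(as.integer(seed))
  tab <- precursor_table(lib)
  n <- nrow(tab)
  is_bg <- runif(n) < background_fraction
  if (all(floor_frac_range == 0)) {
    floor_frac <- rep(0, n)
  } else {
    floor_frac <- exp(runif(n, log(floor_frac_range[1]),
                            log(floor_frac_range[2])))
  }
  contaminated <- runif(n) < contaminated_fraction
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0

  runs <- expand.grid(level = levels, replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  runs$rt_offset <- if (drift_sd > 0) stats::rnorm(nrow(runs), 0, drift_sd)
                    else 0

  area_rows <- vector("list", n)
  apex_rows <- vector("list", n)
  bound_rows <- vector("list", n)
  trace_list <- if (traces) list() else NULL
  trace_truth <- list()
  contam_frag <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- lib$precursors[[i]]
    frag <- unique(p$transitions$fragment)
    base_f <- tapply(p$transitions$area, p$transitions$fragment, mean)[frag]
    k <- length(frag)
    which_con <- if (contaminated[i]) which.max(base_f) else 0L
    floor_f <- floor_frac[i] * base_f
    if (which_con > 0L) {
      ## an interfered transition is contaminant-dominated below the
      ## undiluted level: its floor sits at its full 100%-level signal
      contam_frag[i] <- frag[which_con]
      floor_f[which_con] <- base_f[which_con]
    }
    g <- expand.grid(fragment = frag, level = levels,
                     replicate = seq_len(replicates),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fscale <- if (is_bg[i]) 1 else g$level / 100
    signal <- base_f[g$fragment] * fscale
    ## below its floor the analyte peak is lost in background and the
    ## integrated area is just the (noisier) floor; above it the response
    ## is linear in the dilution. Run-level noise is shared across a
    ## precursor's fragments (injection variation and background move all
    ## transitions together) with a small independent per-fragment
    ## component on top.
    run_id <- paste(g$level, g$replicate)
    fl <- floor_f[g$fragment]
    on_floor <- signal < fl
    expected <- pmax(signal, fl)
    if (sdlog > 0) {
      mult_run <- stats::rlnorm(nrow(runs), -sdlog^2 / 2, sdlog)
      floor_run <- stats::rlnorm(nrow(runs), 0, 0.35)
      ri <- match(run_id, paste(runs$level, runs$replicate))
      obs <- expected *
        ifelse(on_floor, floor_run[ri],
               mult_run[ri] * stats::rlnorm(nrow(g), -0.05^2 / 2, 0.05))
      if (which_con > 0L) {
        ## the contaminant comes from an unrelated co-eluting analyte, so
        ## its variation is independent of the target's run effects
        cr <- g$fragment == frag[which_con] & on_floor
        obs[cr] <- expected[cr] * stats::rlnorm(sum(cr), 0, 0.8)
      }
    } else {
      obs <- expected
    }
    area_rows[[i]] <- data.frame(peptide = p$peptide, charge = p$charge,
                                 fragment = g$fragment, level = g$level,
                                 replicate = g$replicate, area = obs,
                                 stringsAsFactors = FALSE)
    off <- runs$rt_offset[match(paste(g$level, g$replicate),
                                paste(runs$level, runs$replicate))]
    apex_obs <- p$ref_rt + off + stats::rnorm(nrow(g), 0, 0.002)
    per_run <- !duplicated(paste(g$level, g$replicate))
    apex_rows[[i]] <- data.frame(peptide = p$peptide, charge = p$charge,
                                 level = g$level[per_run],
                                 replicate = g$replicate[per_run],
                                 apex_rt = apex_obs[per_run],
                                 stringsAsFactors = FALSE)
    half <- sec_to_min(p$peak_width / 2)
    ref_runs <- runs[runs$level == levels[1], , drop = FALSE]
    bound_rows[[i]] <- data.frame(peptide = p$peptide, charge = p$charge,
                                  level = ref_runs$level,
                                  replicate = ref_runs$replicate,
                                  start_rt = p$ref_rt + ref_runs$rt_offset - half,
                                  end_rt = p$ref_rt + ref_runs$rt_offset + half,
                                  stringsAsFactors = FALSE)
    if (traces) {
      sigma <- p$peak_width / 4
      key <- precursor_key(p$peptide, p$charge)
      for (r in seq_len(nrow(runs))) {
        lv <- runs$level[r]; rp <- runs$replicate[r]
        apex <- p$ref_rt + runs$rt_offset[r]
        tg <- seq(apex - 2 * half, apex + 2 * half, length.out = 41)
        tot <- sum(obs[g$level == lv & g$replicate == rp])
        amp <- tot / (sigma * sqrt(2 * pi))
        tr <- data.frame(time = tg,
                         intensity = amp *
                           exp(-(min_to_sec(tg - apex))^2 / (2 * sigma^2)))
        trace_list[[paste(key, lv, rp, sep = "|")]] <- tr
        ## the integral inside the true boundaries is the re-integration
        ## truth (the boundary span deliberately excludes the far tails)
        inb <- tr$time >= apex - half & tr$time <= apex + half
        trace_truth[[length(trace_truth) + 1L]] <-
          data.frame(key = key, level = lv, replicate = rp,
                     area = min_to_sec(trapz(tr$time[inb],
                                             tr$intensity[inb])),
                     stringsAsFactors = FALSE)
      }
    }
  }
  curve <- cal_curve(areas = do.call(rbind, area_rows),
                     levels = levels, replicates = replicates,
                     apexes = do.call(rbind, apex_rows),
                     boundaries = do.call(rbind, bound_rows),
                     traces = trace_list)
  truth <- data.frame(peptide = tab$peptide, charge = tab$charge,
                      background = is_bg, floor_frac = floor_frac,
                      change_level = ifelse(is_bg, NA, 100 * floor_frac),
                      contaminated_fragment = contam_frag,
                      stringsAsFactors = FALSE)
  attr(curve, "truth") <- truth
  attr(curve, "run_truth") <- runs
  if (length(trace_truth))
    attr(curve, "reint_truth") <- do.call(rbind, trace_truth)
  curve
}

#' Generate a retention-time-warped DIA run
#'
#' Replays a chromatogram library through a monotone time-warp function,
#' emitting per-cycle DIA fragment events in wide isolation windows the way
#' the real-time alignment acquisition sees them (by default twelve 50-Th
#' windows over precursor m/z 400-1000). Used both to build reference maps
#' (identity warp) and to exercise shift estimation (drifting warps).
#'
#' @param lib a [chrom_library()].
#' @param warp monotone increasing function minutes -> minutes applied to
#'   every apex; checked on a fine grid and rejected if non-monotone.
#' @param rt_step cycle period in seconds; defaults to the library's mean
#'   peak width divided by 3.5, the cadence at which the target list is
#'   refreshed during acquisition.
#' @param dia_range,dia_window_width precursor m/z range and isolation
#'   width of the alignment DIA windows (Thomson).
#' @param frag_range fragment m/z range retained (Thomson).
#' @param noise_cv multiplicative log-normal noise on event intensities.
#' @param seed integer seed.
#' @return a `dia_run`: list with `times` (cycle times, minutes),
#'   `dia_windows` (matrix of window bounds), `events` (data frame
#'   `cycle`, `window`, `mz`, `intensity`), `frag_range`,
#'   `gradient_length`, `rt_step` (seconds) and a `"truth"` attribute of
#'   true warped apexes per precursor.
#' @export
generate_warped_run <- function(lib, warp = identity, rt_step = NULL,
                                dia_range = c(400, 1000),
                                dia_window_width = 50,
                                frag_range = c(200, 1500),
                                noise_cv = 0, seed = 1L) {
  stopifnot(inherits(lib, "chrom_library"))
  grad <- lib$gradient_length
  tt <- seq(0, grad, length.out = 512)
  if (any(diff(warp(tt)) <= 0))
    stop_prmflow("warp function must be strictly monotone increasing",
                 class = "invalid_warp")
  set.seed(as.integer(seed))
  tab <- precursor_table(lib)
  if (is.null(rt_step)) rt_step <- mean(tab$peak_width) / 3.5
  times <- seq(0, grad, by = sec_to_min(rt_step))
  lo <- seq(dia_range[1], dia_range[2] - dia_window_width,
            by = dia_window_width)
  windows <- cbind(lo = lo, hi = lo + dia_window_width)
  n_win <- nrow(windows)

  ev <- vector("list", length(lib$precursors))
  true_apex <- numeric(nrow(tab))
  for (i in seq_along(lib$precursors)) {
    p <- lib$precursors[[i]]
    apex <- warp(p$ref_rt)
    true_apex[i] <- apex
    w <- findInterval(p$precursor_mz, windows[, "lo"])
    if (w < 1 || w > n_win || p$precursor_mz >= windows[w, "hi"] + 1e-9) next
    sigma <- p$peak_width / 4
    span <- sec_to_min(2.5 * sigma)
    idx <- which(times >= apex - span & times <= apex + span)
    if (!length(idx)) next
    frag <- unique(p$transitions$fragment)
    area_f <- tapply(p$transitions$area, p$transitions$fragment, mean)[frag]
    pm <- p$transitions$product_mz[match(frag, p$transitions$fragment)]
    keep <- pm >= frag_range[1] & pm <= frag_range[2]
    if (!any(keep)) next
    amp <- area_f[keep] / (sigma * sqrt(2 * pi))
    g <- exp(-(min_to_sec(times[idx] - apex))^2 / (2 * sigma^2))
    ev[[i]] <- data.frame(
      cycle = rep(idx, each = sum(keep)),
      window = w,
      mz = rep(pm[keep], length(idx)),
      intensity = as.numeric(outer(amp, g)))
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
  if (is.null(events))
    events <- data.frame(cycle = integer(), window = integer(),
                         mz = numeric(), intensity = numeric())
  if (noise_cv > 0 && nrow(events)) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    events$intensity <- events$intensity *
      stats::rlnorm(nrow(events), -sdlog^2 / 2, sdlog)
  }
  run <- structure(list(times = times, dia_windows = windows,
                        events = events, frag_range = frag_range,
                        gradient_length = grad, rt_step = rt_step),
                   class = "dia_run")
  attr(run, "truth") <- data.frame(peptide = tab$peptide, charge = tab$charge,
                                   ref_rt = tab$ref_rt, true_apex = true_apex,
                                   stringsAsFactors = FALSE)
  run
}

#' @export
print.dia_run <- function(x, ...) {
  cat(sprintf("<dia_run> %d cycles (%.2f s period), %d DIA windows, %d events\n",
              length(x$times), x$rt_step, nrow(x$dia_windows),
              nrow(x$events)))
  invisible(x)
}
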