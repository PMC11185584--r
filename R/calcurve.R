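#' Construct a matrix-matched calibration curve container
#'
#' Holds replicate transition areas across a dilution ladder of the study
#' matrix into a surrogate matrix (so background composition stays constant
#' while analytes dilute), plus optional per-run apexes, integration
#' boundaries and traces for boundary propagation.
#'
#' @param areas data frame `peptide`, `charge`, `fragment`, `level`
#'   (dilution percent), `replicate`, `area` (>= 0).
#' @param levels dilution levels in percent, strictly decreasing; the first
#'   is the undiluted (100 percent) reference level.
#' @param replicates replicate injections per level.
#' @param apexes optional data frame `peptide`, `charge`, `level`,
#'   `replicate`, `apex_rt` (minutes).
#' @param boundaries optional data frame `peptide`, `charge`, `level`,
#'   `replicate`, `start_rt`, `end_rt`.
#' @param traces optional named list of summed-precursor traces, keyed
#'   `"<peptide>/<charge>|<level>|<replicate>"`.
#' @return a `cal_curve`.
#' @export
cal_curve <- function(areas, levels, replicates, apexes = NULL,
                      boundaries = NULL, traces = NULL) {
  stopifnot(all(c("peptide", "charge", "fragment", "level", "replicate",
                  "area") %in% names(areas)),
            all(diff(levels) < 0), replicates >= 1)
  if (any(areas$area < 0, na.rm = TRUE))
    stop_prmflow("areas must be >= 0", class = "invalid_curve")
  structure(list(areas = areas, levels = levels, replicates = replicates,
                 apexes = apexes, boundaries = boundaries, traces = traces),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  keys <- unique(precursor_key(x$areas$peptide, x$areas$charge))
  cat(sprintf("<cal_curve> %d precursors, %d levels (%g%% .. %g%%) x %d replicates\n",
              length(keys), length(x$levels), max(x$levels), min(x$levels),
              x$replicates))
  invisible(x)
}

## summed selected-transition area per (key, level, replicate)
summed_areas <- function(curve, peptide, charge, fragments = NULL) {
  a <- curve$areas
  sel <- a$peptide == peptide & a$charge == charge
  if (!is.null(fragments)) sel <- sel & a$fragment %in% fragments
  a <- a[sel, , drop = FALSE]
  if (!nrow(a)) return(NULL)
  out <- stats::aggregate(area ~ level + replicate, a, sum)
  out
}

#' Per-level coefficient of variation
#'
#' Percent CV (sample standard deviation over mean, times 100) of the
#' summed selected-transition areas across replicate measurements of each
#' dilution level.
#'
#' @param curve a [cal_curve()].
#' @param peptide,charge restrict to one precursor (default: all).
#' @param fragments optional transition subset (fragment labels).
#' @return data frame `peptide`, `charge`, `level`, `cv` (percent), `n`;
#'   levels with a single replicate get `NA` CV and are flagged by `n`.
#' @export
cv_by_level <- function(curve, peptide = NULL, charge = NULL,
                        fragments = NULL) {
  stopifnot(inherits(curve, "cal_curve"))
  a <- curve$areas
  if (!is.null(peptide)) a <- a[a$peptide == peptide & a$charge == charge, ]
  if (!is.null(fragments)) a <- a[a$fragment %in% fragments, ]
  s <- stats::aggregate(area ~ peptide + charge + level + replicate, a, sum)
  cv_one <- function(v) {
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(NA_real_)
    100 * stats::sd(v) / m
  }
  out <- stats::aggregate(area ~ peptide + charge + level, s,
                          function(v) c(cv = cv_one(v), n = length(v)))
  data.frame(peptide = out$peptide, charge = out$charge, level = out$level,
             cv = out$area[, "cv"], n = as.integer(out$area[, "n"]),
             stringsAsFactors = FALSE)
}

#' Accuracy ratios along the dilution ladder
#'
#' The log2 ratio of the mean summed precursor area at each dilution level
#' to the mean at the undiluted reference level. For a perfectly linear
#' response the expected value is `log2(level / 100)`.
#'
#' @inheritParams cv_by_level
#' @return data frame `peptide`, `charge`, `level`, `log2_ratio`,
#'   `log2_expected`.
#' @export
accuracy_ratios <- function(curve, peptide = NULL, charge = NULL,
                            fragments = NULL) {
  stopifnot(inherits(curve, "cal_curve"))
  a <- curve$areas
  if (!is.null(peptide)) a <- a[a$peptide == peptide & a$charge == charge, ]
  if (!is.null(fragments)) a <- a[a$fragment %in% fragments, ]
  s <- stats::aggregate(area ~ peptide + charge + level + replicate, a, sum)
  m <- stats::aggregate(area ~ peptide + charge + level, s, mean)
  ref_level <- curve$levels[1]
  key <- precursor_key(m$peptide, m$charge)
  ref <- m$area[m$level == ref_level][match(key, key[m$level == ref_level])]
  data.frame(peptide = m$peptide, charge = m$charge, level = m$level,
             log2_ratio = log2(m$area / ref),
             log2_expected = log2(m$level / ref_level),
             stringsAsFactors = FALSE)
}

#' Fit a two-segment noise-floor / linear hinge to a dilution response
#'
#' Models the mean response versus dilution as a constant noise floor below
#' a change point and a straight line through the origin above it -- in a
#' matrix-matched dilution the analyte signal is proportional to the
#' dilution level, so a proportional (zero-intercept) linear segment keeps
#' constant contaminating signal from being absorbed as an intercept and
#' pushes it into the floor segment instead. The change point is found by
#' grid search over the observed levels, minimizing the total weighted
#' squared error with `1/response^2` weights (relative error), which stops
#' the undiluted levels -- orders of magnitude more intense -- from
#' swamping the fit near the floor where the change point lives; this
#' matches the roughly constant-CV error structure of chromatographic peak
#' areas. The response is called flat -- not quantifiable -- when the best
#' linear segment has a non-positive slope or a slope indistinguishable
#' from zero (t-test p >= 0.05).
#'
#' @param level dilution levels, percent.
#' @param response mean areas at those levels.
#' @return a `hinge_fit` with `change_level` (the lowest level of the
#'   linear regime, `Inf` when flat), `floor` (fitted noise floor),
#'   `intercept`, `slope`, and `sse`. Methods: `print`, `coef`, `predict`.
#' @export
hinge_fit <- function(level, response) {
  stopifnot(length(level) == length(response), length(level) >= 3)
  o <- order(level)
  x <- level[o]; y <- response[o]
  m <- length(x)
  wt <- 1 / pmax(y, max(y) * 1e-9)^2
  best <- list(sse = Inf)
  for (j in seq_len(m - 1)) {            # x[j] = lowest level fit linearly
    lin <- j:m
    flo <- seq_len(j - 1)
    fit <- stats::lm(y[lin] ~ x[lin] + 0, weights = wt[lin])
    b <- unname(stats::coef(fit)[1])
    sse <- sum(wt[lin] * stats::resid(fit)^2)
    floor_val <- if (length(flo))
      stats::weighted.mean(y[flo], wt[flo]) else NA_real_
    if (length(flo)) sse <- sse + sum(wt[flo] * (y[flo] - floor_val)^2)
    if (sse < best$sse - 1e-12) {
      sm <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                     error = function(e) NULL)
      se <- if (is.null(sm) || nrow(sm) < 1) NA else sm[1, 2]
      pval <- if (is.null(sm) || nrow(sm) < 1) NA else sm[1, 4]
      best <- list(change_level = x[j], floor = floor_val,
                   intercept = 0, slope = b,
                   sse = sse, slope_se = se, slope_p = pval)
    }
  }
  flat <- is.na(best$slope) || best$slope <= 0 ||
    (!is.na(best$slope_se) && best$slope_se > 0 &&
     (is.na(best$slope_p) || best$slope_p >= 0.05))
  if (flat) best$change_level <- Inf
  structure(c(best, list(level = x, response = y)), class = "hinge_fit")
}

#' @export
print.hinge_fit <- function(x, ...) {
  if (is.infinite(x$change_level)) {
    cat("<hinge_fit> flat response: not quantifiable\n")
  } else {
    cat(sprintf("<hinge_fit> change point %g%%, slope %.4g, floor %.4g\n",
                x$change_level, x$slope, x$floor %||% NA))
  }
  invisible(x)
}

#' @export
coef.hinge_fit <- function(object, ...) {
  c(change_level = object$change_level, floor = object$floor %||% NA_real_,
    intercept = object$intercept, slope = object$slope)
}

#' @export
predict.hinge_fit <- function(object, newdata = object$level, ...) {
  ifelse(newdata >= object$change_level,
         object$intercept + object$slope * newdata,
         object$floor %||% NA_real_)
}

#' Estimate limits of detection and quantification for one precursor
#'
#' The limit of detection is the change point of a [hinge_fit()] of mean
#' summed area versus dilution: below it the response sits on the noise
#' floor. The limit of quantification is the lowest dilution at or above
#' the LOD whose replicate CV is within `cv_max` percent, every smaller
#' tested dilution having failed the CV bound or fallen below the floor.
#' Both are reported in dilution-percent units; a flat (pure noise)
#' response yields the `Inf` sentinel for both ("not quantifiable").
#'
#' @param curve a [cal_curve()].
#' @param peptide,charge the precursor.
#' @param fragments optional transition subset used for the summed area.
#' @param cv_max CV gate for the LOQ, percent.
#' @return list with `lod`, `loq` (dilution percent), and the `hinge_fit`.
#' @export
estimate_lod_loq <- function(curve, peptide, charge, fragments = NULL,
                             cv_max = 20) {
  s <- summed_areas(curve, peptide, charge, fragments)
  if (is.null(s) || length(unique(s$level)) < 5)
    stop_prmflow("need areas at >= 5 dilution levels",
                 class = "insufficient_curve")
  m <- stats::aggregate(area ~ level, s, mean)
  fit <- hinge_fit(m$level, m$area)
  lod <- fit$change_level
  if (is.infinite(lod))
    return(list(lod = Inf, loq = Inf, fit = fit))
  cv <- cv_by_level(curve, peptide, charge, fragments)
  cv <- cv[order(cv$level), , drop = FALSE]
  ok <- !is.na(cv$cv) & cv$cv <= cv_max & cv$level >= lod
  loq <- if (any(ok)) cv$level[which(ok)[1]] else Inf
  list(lod = lod, loq = loq, fit = fit)
}

#' Select the transition subset that optimizes the limit of quantification
#'
#' Greedy backward elimination: starting from all transitions of the
#' precursor, repeatedly remove the transition whose removal most lowers
#' the LOQ (ties resolved by removing the lower-area transition), stopping
#' when no removal improves the LOQ or only `min_keep` transitions remain.
#' The returned subset never quantifies worse than the full set.
#'
#' @inheritParams estimate_lod_loq
#' @param min_keep minimum transitions to retain.
#' @return list with `fragments` (selected subset), `loq`, `lod`, and
#'   `loq_all` (LOQ of the full set).
#' @export
optimize_transitions <- function(curve, peptide, charge, min_keep = 3L,
                                 cv_max = 20) {
  a <- curve$areas
  a <- a[a$peptide == peptide & a$charge == charge, , drop = FALSE]
  frags <- unique(a$fragment)
  mean_area <- vapply(frags, function(f) mean(a$area[a$fragment == f]), 0)
  cur <- frags
  res <- estimate_lod_loq(curve, peptide, charge, cur, cv_max)
  loq_all <- res$loq
  cur_loq <- loq_all
  while (length(cur) > min_keep) {
    cand_loq <- vapply(cur, function(f) {
      estimate_lod_loq(curve, peptide, charge, setdiff(cur, f), cv_max)$loq
    }, 0)
    improving <- cand_loq < cur_loq
    if (!any(improving)) break
    best_loq <- min(cand_loq)
    ties <- cur[cand_loq == best_loq]
    drop <- ties[which.min(mean_area[ties])]
    cur <- setdiff(cur, drop)
    cur_loq <- best_loq
  }
  final <- estimate_lod_loq(curve, peptide, charge, cur, cv_max)
  list(fragments = cur, loq = final$loq, lod = final$lod, loq_all = loq_all)
}

#' Figures of merit for every precursor on a calibration curve
#'
#' @param curve a [cal_curve()].
#' @param optimize run [optimize_transitions()] per precursor (requires
#'   more than `min_keep` transitions; otherwise the full set is used).
#' @param cv_max CV gate, percent.
#' @param min_keep minimum transitions kept during optimization.
#' @return data frame, one row per precursor: `peptide`, `charge`, `lod`,
#'   `loq` (dilution percent, `Inf` = not quantifiable), `loq_all` (before
#'   optimization), `n_transitions`, `selected` (fragment labels,
#'   `;`-separated), plus `cv_<level>` columns of per-level percent CV for
#'   the selected subset.
#' @export
figures_of_merit <- function(curve, optimize = FALSE, cv_max = 20,
                             min_keep = 3L) {
  stopifnot(inherits(curve, "cal_curve"))
  ids <- unique(curve$areas[c("peptide", "charge")])
  rows <- vector("list", nrow(ids))
  for (i in seq_len(nrow(ids))) {
    pep <- ids$peptide[i]; z <- ids$charge[i]
    frags <- unique(curve$areas$fragment[curve$areas$peptide == pep &
                                         curve$areas$charge == z])
    if (optimize && length(frags) > min_keep) {
      opt <- optimize_transitions(curve, pep, z, min_keep, cv_max)
      sel <- opt$fragments; lod <- opt$lod; loq <- opt$loq
      loq_all <- opt$loq_all
    } else {
      est <- estimate_lod_loq(curve, pep, z, NULL, cv_max)
      sel <- frags; lod <- est$lod; loq <- est$loq; loq_all <- est$loq
    }
    cv <- cv_by_level(curve, pep, z, sel)
    cvw <- stats::setNames(cv$cv[match(curve$levels, cv$level)],
                           paste0("cv_", curve$levels))
    rows[[i]] <- data.frame(peptide = pep, charge = z, lod = lod, loq = loq,
                            loq_all = loq_all,
                            n_transitions = length(frags),
                            selected = paste(sel, collapse = ";"),
                            as.list(cvw), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Propagate integration boundaries from the undiluted level
#'
#' Dilute samples often carry too little analyte signal to pick integration
#' boundaries reliably, so the boundaries determined on the undiluted
#' (reference-level) runs are mapped onto every other run through a simple
#' per-run retention-time alignment: the median apex offset of
#' high-abundance anchor precursors (top half by reference-level area)
#' between the run and the reference. When summed traces are attached the
#' areas are re-integrated (trapezoidal rule) inside the mapped boundaries.
#'
#' @param curve a [cal_curve()] with `boundaries` at the reference level
#'   and `apexes` for all runs.
#' @param reference_level the level whose boundaries are trusted (default:
#'   the first, undiluted level).
#' @return the curve with `boundaries` filled for every run, a
#'   `run_offsets` element (per-run estimated shift, minutes), and -- when
#'   traces are present -- a `reintegrated` data frame of per-precursor
#'   summed areas. Precursors lacking reference boundaries are flagged in
#'   the `"flagged"` attribute and excluded.
#' @export
propagate_boundaries <- function(curve, reference_level = NULL) {
  stopifnot(inherits(curve, "cal_curve"))
  if (is.null(curve$boundaries) || is.null(curve$apexes))
    stop_prmflow("boundary propagation needs boundaries and apexes",
                 class = "invalid_curve")
  ref_level <- reference_level %||% curve$levels[1]
  b <- curve$boundaries
  bref <- b[b$level == ref_level, , drop = FALSE]
  if (!nrow(bref))
    stop_prmflow("no boundaries at the reference level",
                 class = "invalid_curve")
  ## consensus reference boundaries and apexes per precursor
  refb <- stats::aggregate(cbind(start_rt, end_rt) ~ peptide + charge, bref,
                           mean)
  refb$key <- precursor_key(refb$peptide, refb$charge)
  ap <- curve$apexes
  ap$key <- precursor_key(ap$peptide, ap$charge)
  apref <- stats::aggregate(apex_rt ~ key,
                            ap[ap$level == ref_level, , drop = FALSE], mean)
  ## anchors: top half by reference-level mean area
  s <- stats::aggregate(area ~ peptide + charge,
                        curve$areas[curve$areas$level == ref_level, ], mean)
  s$key <- precursor_key(s$peptide, s$charge)
  anchors <- s$key[s$area >= stats::median(s$area)]
  all_keys <- unique(ap$key)
  flagged <- setdiff(all_keys, refb$key)
  runs <- unique(ap[c("level", "replicate")])
  out_rows <- vector("list", nrow(runs))
  offsets <- numeric(nrow(runs))
  reint <- list()
  for (r in seq_len(nrow(runs))) {
    lv <- runs$level[r]; rp <- runs$replicate[r]
    apr <- ap[ap$level == lv & ap$replicate == rp, , drop = FALSE]
    m <- match(apr$key, apref$key)
    use <- !is.na(m) & apr$key %in% anchors
    off <- if (any(use))
      stats::median(apr$apex_rt[use] - apref$apex_rt[m[use]]) else 0
    offsets[r] <- off
    keep <- refb$key %in% apr$key
    out_rows[[r]] <- data.frame(peptide = refb$peptide[keep],
                                charge = refb$charge[keep],
                                level = lv, replicate = rp,
                                start_rt = refb$start_rt[keep] + off,
                                end_rt = refb$end_rt[keep] + off,
                                stringsAsFactors = FALSE)
    if (!is.null(curve$traces)) {
      for (i in which(keep)) {
        key <- refb$key[i]
        tr <- curve$traces[[paste(key, lv, rp, sep = "|")]]
        if (is.null(tr)) next
        lo <- max(refb$start_rt[i] + off, min(tr$time))
        hi <- min(refb$end_rt[i] + off, max(tr$time))
        inb <- tr$time > lo & tr$time < hi
        ## clip the trace at the exact mapped boundaries so the integral
        ## does not lose a partial grid slice at either end
        tt <- c(lo, tr$time[inb], hi)
        yy <- c(stats::approx(tr$time, tr$intensity, lo)$y,
                tr$intensity[inb],
                stats::approx(tr$time, tr$intensity, hi)$y)
        reint[[length(reint) + 1L]] <-
          data.frame(key = key, level = lv, replicate = rp,
                     area = min_to_sec(trapz(tt, yy)),
                     stringsAsFactors = FALSE)
      }
    }
  }
  curve$boundaries <- do.call(rbind, out_rows)
  curve$run_offsets <- cbind(runs, offset = offsets)
  if (length(reint)) curve$reintegrated <- do.call(rbind, reint)
  attr(curve, "flagged") <- flagged
  curve
}
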