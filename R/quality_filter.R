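#' Precursor refinement thresholds
#'
#' Holds the rule set used to refine a chromatogram library into targetable
#' precursors: a minimum summed precursor area, bounds on the
#' chromatographic base peak width, and a minimum number of co-eluting,
#' interference-free transitions. The defaults are the thresholds used for
#' a linear-ion-trap CSF survey assay (area >= 500, widths 5.2-45 s, at
#' least 3 clean transitions); an Orbitrap-library variant would use e.g.
#' `min_area = 1000, max_width = 26.1`.
#'
#' @param min_area minimum summed precursor area (intensity units).
#' @param min_width,max_width allowed base peak width, seconds.
#' @param min_clean_transitions minimum number of interference-free
#'   transitions.
#' @param coelution_r_min Pearson correlation against the entry's median
#'   trace above which a transition counts as interference-free.
#' @param rel_intensity_factor fallback tolerance when traces are absent: a
#'   transition is clean if its observed area fraction is within this
#'   multiplicative factor of its library-expected relative intensity.
#' @return a `filter_params` list.
#' @export
filter_params <- function(min_area = 500, min_width = 5.2, max_width = 45,
                          min_clean_transitions = 3L,
                          coelution_r_min = 0.9,
                          rel_intensity_factor = 3) {
  stopifnot(min_width > 0, min_width < max_width,
            min_clean_transitions >= 1,
            coelution_r_min >= -1, coelution_r_min <= 1,
            rel_intensity_factor >= 1)
  structure(list(min_area = min_area, min_width = min_width,
                 max_width = max_width,
                 min_clean_transitions = as.integer(min_clean_transitions),
                 coelution_r_min = coelution_r_min,
                 rel_intensity_factor = rel_intensity_factor),
            class = "filter_params")
}

#' Co-elution scores of a precursor's transitions
#'
#' Scores each transition by the Pearson correlation of its chromatographic
#' trace against the pointwise median trace of all transitions of the
#' entry, after linear resampling onto the union time grid over the
#' integration boundary span. A transition contaminated by a co-eluting
#' interfering signal decorrelates from the consensus shape and scores low;
#' a flat (zero-variance) trace has no defined correlation and scores `NA`,
#' which downstream counting treats as failing.
#'
#' @param entry a [precursor_entry()] whose transitions carry traces.
#' @return named numeric vector of scores, one per distinct fragment; `NA`
#'   for transitions without a trace or with zero variance. If fewer than
#'   two transitions carry traces all scores are `NA` and the result has
#'   attribute `undefined = TRUE`.
#' @export
coelution_scores <- function(entry) {
  stopifnot(inherits(entry, "precursor_entry"))
  frag <- unique(entry$transitions$fragment)
  scores <- stats::setNames(rep(NA_real_, length(frag)), frag)
  traces <- entry$traces
  have <- frag[frag %in% names(traces %||% list())]
  have <- have[vapply(have, function(f) !is.null(traces[[f]]) &&
                                        nrow(traces[[f]]) >= 3, TRUE)]
  if (length(have) < 2) {
    attr(scores, "undefined") <- TRUE
    return(scores)
  }
  span <- c(min(entry$transitions$start_rt), max(entry$transitions$end_rt))
  grid <- sort(unique(unlist(lapply(have, function(f) traces[[f]]$time))))
  grid <- grid[grid >= span[1] & grid <= span[2]]
  mat <- vapply(have, function(f) {
    stats::approx(traces[[f]]$time, traces[[f]]$intensity, xout = grid,
                  rule = 2)$y
  }, numeric(length(grid)))
  med <- apply(mat, 1, stats::median)
  if (stats::sd(med) == 0) {
    attr(scores, "undefined") <- TRUE
    return(scores)
  }
  for (f in have) {
    y <- mat[, f]
    if (stats::sd(y) > 0) scores[f] <- stats::cor(y, med)
  }
  scores
}

#' Count interference-free transitions of a precursor
#'
#' A transition is interference-free when its co-elution score (see
#' [coelution_scores()]) reaches `coelution_r_min`. Transitions lacking a
#' trace fall back to a weaker relative-intensity criterion: clean when the
#' observed area fraction is within `rel_intensity_factor` of the
#' library-expected relative intensity (`expected_rel` column), flagged via
#' the `"fallback"` attribute. A single transition cannot establish
#' co-elution, so entries with one transition count zero.
#'
#' @param entry a [precursor_entry()].
#' @param params a [filter_params()].
#' @return integer count, with attribute `fallback` giving the number of
#'   transitions judged by the relative-intensity fallback.
#' @export
count_clean_transitions <- function(entry, params = filter_params()) {
  frag <- unique(entry$transitions$fragment)
  if (length(frag) < 2) return(structure(0L, fallback = 0L))
  scores <- coelution_scores(entry)
  clean <- !is.na(scores) & scores >= params$coelution_r_min
  n_fallback <- 0L
  if (isTRUE(attr(scores, "undefined"))) {
    n_fallback <- length(frag)
    if ("expected_rel" %in% names(entry$transitions)) {
      ## no usable traces: judge transitions by relative intensity instead
      per_frag <- tapply(entry$transitions$area, entry$transitions$fragment,
                         mean)[frag]
      frac <- per_frag / sum(per_frag)
      expd <- entry$transitions$expected_rel[match(frag,
                                                   entry$transitions$fragment)]
      ratio <- frac / expd
      clean <- !is.na(ratio) & ratio <= params$rel_intensity_factor &
               ratio >= 1 / params$rel_intensity_factor
    } else {
      ## neither traces nor expected intensities: cleanliness cannot be
      ## assessed, so transitions pass by default (flagged as fallback)
      clean <- rep(TRUE, length(frag))
    }
  }
  structure(as.integer(sum(clean)), fallback = n_fallback)
}

#' Filter a chromatogram library on area, width and clean-transition rules
#'
#' Applies the precursor-refinement rules in [filter_params()]: a precursor
#' survives when its summed area reaches `min_area`, its base peak width
#' lies within `[min_width, max_width]` seconds, and it has at least
#' `min_clean_transitions` interference-free transitions.
#'
#' @param lib a [chrom_library()].
#' @param params a [filter_params()].
#' @return the filtered [chrom_library()]; its `"filter_report"` attribute
#'   (also available through [filter_report()]) records input/output counts,
#'   per-rule rejection counts and the per-precursor rule evaluations.
#'   Surviving precursor entries gain an `n_clean` field so later selection
#'   steps can rank by clean-transition count without rescoring.
#' @export
filter_precursors <- function(lib, params = filter_params()) {
  stopifnot(inherits(lib, "chrom_library"), inherits(params, "filter_params"))
  tab <- precursor_table(lib)
  n <- nrow(tab)
  n_clean <- integer(n)
  for (i in seq_len(n))
    n_clean[i] <- count_clean_transitions(lib$precursors[[i]], params)
  pass_area <- tab$total_area >= params$min_area
  pass_width <- tab$peak_width >= params$min_width &
                tab$peak_width <= params$max_width
  pass_clean <- n_clean >= params$min_clean_transitions
  pass <- pass_area & pass_width & pass_clean
  detail <- data.frame(key = tab$key, total_area = tab$total_area,
                       peak_width = tab$peak_width, n_clean = n_clean,
                       pass_area = pass_area, pass_width = pass_width,
                       pass_clean = pass_clean, pass = pass,
                       stringsAsFactors = FALSE)
  report <- structure(list(n_in = n, n_pass = sum(pass),
                           fail_area = sum(!pass_area),
                           fail_width = sum(!pass_width),
                           fail_clean = sum(!pass_clean),
                           params = params, detail = detail),
                      class = "filter_report")
  kept <- lib$precursors[pass]
  kept <- Map(function(p, nc) { p$n_clean <- nc; p }, kept, n_clean[pass])
  out <- chrom_library(kept, lib$gradient_length, lib$source_label)
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report attached to a filtered library
#' @param lib a library returned by [filter_precursors()] or one of the
#'   `refine_*` functions.
#' @return the `filter_report` object, or `NULL`.
#' @export
filter_report <- function(lib) attr(lib, "filter_report")

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in -> %d pass\n", x$n_in, x$n_pass))
  cat(sprintf("  failed area >= %g        : %d\n", x$params$min_area,
              x$fail_area))
  cat(sprintf("  failed width in [%g, %g] s: %d\n", x$params$min_width,
              x$params$max_width, x$fail_width))
  cat(sprintf("  failed >= %d clean trans. : %d\n",
              x$params$min_clean_transitions, x$fail_clean))
  invisible(x)
}

#' Refine precursors by replicate reproducibility
#'
#' Keeps precursors whose percent coefficient of variation of summed area
#' across replicate injections (optionally after total-ion-current
#' normalization of each replicate) is at most `cv_max`. This is the
#' refinement applied after acquiring a preliminary assay in triplicate.
#'
#' @param lib a [chrom_library()].
#' @param areas data frame `peptide`, `charge`, `replicate`, `area` (summed
#'   precursor area per replicate). If `NULL`, areas are derived from the
#'   library's transition tables using their `replicate` column.
#' @param cv_max maximum percent CV (default 30).
#' @param normalize `"none"` or `"tic"`; TIC normalization divides each
#'   replicate's areas by that replicate's total area (rescaled by the mean
#'   total), making the CV invariant to global intensity scaling.
#' @return filtered [chrom_library()] with a `cv_table` attribute; precursors
#'   with fewer than 2 replicates or zero mean area are dropped and flagged
#'   in the table.
#' @details CVs use the sample (n-1) standard deviation.
#' @export
refine_by_replicate_cv <- function(lib, areas = NULL, cv_max = 30,
                                   normalize = c("none", "tic")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(lib, "chrom_library"))
  if (is.null(areas)) {
    rows <- lapply(lib$precursors, function(p) {
      a <- tapply(p$transitions$area,
                  list(p$transitions$replicate, p$transitions$fragment), mean)
      data.frame(peptide = p$peptide, charge = p$charge,
                 replicate = rownames(a), area = rowSums(a, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    })
    areas <- do.call(rbind, rows)
  }
  if (normalize == "tic") {
    tot <- tapply(areas$area, areas$replicate, sum)
    areas$area <- areas$area / tot[as.character(areas$replicate)] * mean(tot)
  }
  key <- precursor_key(areas$peptide, areas$charge)
  cv_one <- function(a) {
    if (length(a) < 2) return(NA_real_)
    m <- mean(a)
    if (m == 0) return(Inf)
    100 * stats::sd(a) / m
  }
  cv <- tapply(areas$area, key, cv_one)
  tab <- precursor_table(lib)
  cv_k <- as.numeric(cv[tab$key])
  keep <- !is.na(cv_k) & is.finite(cv_k) & cv_k <= cv_max
  out <- subset_library(lib, keep)
  attr(out, "cv_table") <- data.frame(key = tab$key, cv = cv_k, kept = keep,
                                      flagged = is.na(cv_k) |
                                                !is.finite(cv_k),
                                      stringsAsFactors = FALSE)
  out
}

#' Refine precursors by calibration-curve performance
#'
#' Selects precursors for a smaller, better-behaved assay from their
#' figures of merit at stated qualifying dilution levels: the precursor is
#' kept when its CV is strictly below `cv_max` percent and its observed
#' dilution ratio is within `ratio_tol` (a fraction, default 50 percent) of
#' the expected ratio, at every qualifying level supplied.
#'
#' @param lib a [chrom_library()].
#' @param fom data frame with columns `peptide`, `charge`, `cv` (percent),
#'   `log2_ratio` (observed) and `log2_expected`, one row per precursor per
#'   qualifying level.
#' @param cv_max percent CV bound (strict).
#' @param ratio_tol allowed relative deviation of observed/expected ratio.
#' @return filtered [chrom_library()].
#' @export
refine_by_curve_performance <- function(lib, fom, cv_max = 20,
                                        ratio_tol = 0.5) {
  stopifnot(inherits(lib, "chrom_library"),
            all(c("peptide", "charge", "cv", "log2_ratio", "log2_expected")
                %in% names(fom)))
  rel <- 2^(fom$log2_ratio - fom$log2_expected)
  ok <- !is.na(fom$cv) & fom$cv < cv_max &
        !is.na(rel) & abs(rel - 1) <= ratio_tol
  key <- precursor_key(fom$peptide, fom$charge)
  all_ok <- tapply(ok, key, all)
  tab <- precursor_table(lib)
  keep <- tab$key %in% names(all_ok)[unlist(all_ok)]
  subset_library(lib, keep)
}
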