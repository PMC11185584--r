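#' Construct a precursor entry
#'
#' A precursor entry bundles one targetable peptide precursor with its
#' fragment-ion transitions, a consensus reference retention time and a
#' chromatographic peak width. It is the unit on which quality filtering and
#' scheduling operate.
#'
#' @param peptide modified peptide sequence string.
#' @param charge precursor charge state (integer >= 1).
#' @param precursor_mz precursor m/z in Thomson.
#' @param protein_ids character vector of protein accessions.
#' @param transitions data frame with one row per transition observation,
#'   columns `fragment` (ion label such as `"y7"`), `product_mz`, `area`
#'   (>= 0), `apex_rt`, `start_rt`, `end_rt` (minutes) and optionally
#'   `replicate` and `expected_rel` (library-expected relative intensity).
#' @param traces optional named list (by fragment label) of data frames with
#'   columns `time` (minutes) and `intensity`, each covering the
#'   integration boundaries of its transition.
#'
#' @details The consensus reference retention time `ref_rt` is the median of
#'   the per-transition apexes, which is robust to a single interfered
#'   transition dragging its apex. The peak width is the median boundary
#'   span (`end_rt - start_rt`) converted to seconds and is treated as the
#'   base (integration) width of the peak, not the width at half maximum.
#'   When the same transition was observed in several replicates the areas
#'   are kept per replicate and `total_area` sums the per-fragment mean
#'   areas, so replicate multiplicity does not inflate the precursor area.
#'
#' @return an object of class `precursor_entry` with fields `peptide`,
#'   `charge`, `precursor_mz`, `protein_ids`, `transitions`, `traces`,
#'   `ref_rt` (minutes), `peak_width` (seconds), `total_area`.
#' @seealso [chrom_library()], [coelution_scores()]
#' @export
precursor_entry <- function(peptide, charge, precursor_mz, protein_ids,
                            transitions, traces = NULL) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L)
    stop_prmflow("precursor charge must be >= 1", class = "invalid_precursor")
  req <- c("fragment", "product_mz", "area", "apex_rt", "start_rt", "end_rt")
  miss <- setdiff(req, names(transitions))
  if (length(miss))
    stop_prmflow("transitions lack column(s): ", paste(miss, collapse = ", "),
                 class = "invalid_precursor")
  if (nrow(transitions) < 1L)
    stop_prmflow("a precursor entry needs at least one transition",
                 class = "invalid_precursor")
  if (any(transitions$area < 0, na.rm = TRUE))
    stop_prmflow("transition areas must be >= 0", class = "invalid_precursor")
  bad <- with(transitions, !(start_rt < apex_rt & apex_rt < end_rt))
  if (any(bad, na.rm = TRUE))
    stop_prmflow("transition boundaries must satisfy start < apex < end",
                 class = "invalid_precursor")
  if (!"replicate" %in% names(transitions)) transitions$replicate <- "1"
  per_frag <- tapply(transitions$area, transitions$fragment, mean)
  entry <- structure(list(
    peptide = peptide,
    charge = charge,
    precursor_mz = as.numeric(precursor_mz),
    protein_ids = as.character(protein_ids),
    transitions = transitions,
    traces = traces,
    ref_rt = stats::median(transitions$apex_rt),
    peak_width = min_to_sec(stats::median(transitions$end_rt -
                                          transitions$start_rt)),
    total_area = sum(per_frag)
  ), class = "precursor_entry")
  if (entry$peak_width <= 0)
    stop_prmflow("peak width must be positive", class = "invalid_precursor")
  entry
}

#' @export
print.precursor_entry <- function(x, ...) {
  cat(sprintf("<precursor_entry> %s (+%d), m/z %.4f\n", x$peptide, x$charge,
              x$precursor_mz))
  cat(sprintf("  %d transition row(s), ref RT %.2f min, width %.1f s, area %.3g\n",
              nrow(x$transitions), x$ref_rt, x$peak_width, x$total_area))
  invisible(x)
}

#' Construct a chromatogram library
#'
#' A chromatogram library is the collection of precursor entries extracted
#' from (typically gas-phase-fractionated) DIA data, together with the
#' gradient length of the separation it was acquired on. It is the input to
#' quality filtering and assay scheduling.
#'
#' @param precursors list of [precursor_entry()] objects; `(peptide, charge)`
#'   must be unique across the list.
#' @param gradient_length LC gradient length in minutes; all reference
#'   retention times must fall inside `[0, gradient_length]`.
#' @param source_label free-text provenance label.
#' @return an object of class `chrom_library`.
#' @export
chrom_library <- function(precursors, gradient_length, source_label = "") {
  stopifnot(is.list(precursors), gradient_length > 0)
  keys <- vapply(precursors, function(p) precursor_key(p$peptide, p$charge), "")
  if (anyDuplicated(keys))
    stop_prmflow("duplicate (peptide, charge) in library: ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", "),
                 class = "invalid_library")
  rts <- vapply(precursors, function(p) p$ref_rt, 0)
  if (length(rts) && any(rts < 0 | rts > gradient_length))
    stop_prmflow("reference retention times outside [0, gradient_length]",
                 class = "invalid_library")
  structure(list(precursors = precursors,
                 gradient_length = gradient_length,
                 source_label = source_label),
            class = "chrom_library")
}

#' @export
length.chrom_library <- function(x) length(x$precursors)

#' @export
print.chrom_library <- function(x, ...) {
  tab <- precursor_table(x)
  cat(sprintf("<chrom_library> %d precursors, %d proteins, %.1f min gradient",
              nrow(tab), length(unique(unlist(strsplit(tab$protein, ";")))),
              x$gradient_length))
  if (nzchar(x$source_label)) cat(" [", x$source_label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.chrom_library <- function(object, ...) {
  tab <- precursor_table(object)
  cat(sprintf("Chromatogram library: %d precursors / %d proteins\n",
              nrow(tab), length(unique(tab$protein))))
  if (nrow(tab)) {
    cat(sprintf("  ref RT      : %.2f - %.2f min (gradient %.1f min)\n",
                min(tab$ref_rt), max(tab$ref_rt), object$gradient_length))
    cat(sprintf("  peak width  : median %.1f s (range %.1f - %.1f s)\n",
                stats::median(tab$peak_width), min(tab$peak_width),
                max(tab$peak_width)))
    cat(sprintf("  transitions : median %d per precursor\n",
                as.integer(stats::median(tab$n_transitions))))
  }
  invisible(tab)
}

#' Flat per-precursor summary of a chromatogram library
#'
#' @param lib a [chrom_library()].
#' @return data frame with one row per precursor: `peptide`, `charge`,
#'   `precursor_mz`, `protein` (accessions collapsed with `;`), `ref_rt`
#'   (minutes), `peak_width` (seconds), `total_area`, `n_transitions`
#'   (distinct fragments) and `key`.
#' @export
precursor_table <- function(lib) {
  stopifnot(inherits(lib, "chrom_library"))
  if (!length(lib$precursors)) {
    return(data.frame(peptide = character(), charge = integer(),
                      precursor_mz = numeric(), protein = character(),
                      ref_rt = numeric(), peak_width = numeric(),
                      total_area = numeric(), n_transitions = integer(),
                      key = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(lib$precursors, function(p) {
    data.frame(peptide = p$peptide, charge = p$charge,
               precursor_mz = p$precursor_mz,
               protein = paste(p$protein_ids, collapse = ";"),
               ref_rt = p$ref_rt, peak_width = p$peak_width,
               total_area = p$total_area,
               n_transitions = length(unique(p$transitions$fragment)),
               key = precursor_key(p$peptide, p$charge),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## subset a library by a logical/integer index over precursors
subset_library <- function(lib, idx) {
  chrom_library(lib$precursors[idx], lib$gradient_length, lib$source_label)
}
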