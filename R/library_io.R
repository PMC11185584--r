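#' Column dialects for transition reports
#'
#' A dialect maps the roles the reader needs onto the column names a
#' particular exporter uses, so Skyline-style transition reports and the
#' synthetic generator's reports go through one reader. `report_dialect()`
#' is the package's native snake_case schema; `skyline_dialect()` matches
#' the default column headers of a Skyline transition results export.
#'
#' @param ... role = column-name overrides. Roles: `protein`, `peptide`,
#'   `charge`, `precursor_mz`, `fragment`, `product_mz`, `apex_rt`,
#'   `start_rt`, `end_rt`, `area`, and optionally `sample_id`, `replicate`.
#' @return named character vector of class `report_dialect`.
#' @export
report_dialect <- function(...) {
  d <- c(protein = "protein", peptide = "peptide", charge = "charge",
         precursor_mz = "precursor_mz", fragment = "fragment",
         product_mz = "product_mz", apex_rt = "apex_rt",
         start_rt = "start_rt", end_rt = "end_rt", area = "area",
         sample_id = "sample_id", replicate = "replicate")
  over <- c(...)
  d[names(over)] <- over
  structure(d, class = "report_dialect")
}

#' @rdname report_dialect
#' @export
skyline_dialect <- function(...) {
  report_dialect(protein = "Protein", peptide = "Peptide Modified Sequence",
                 charge = "Precursor Charge", precursor_mz = "Precursor Mz",
                 fragment = "Fragment Ion", product_mz = "Product Mz",
                 apex_rt = "Retention Time", start_rt = "Min Start Time",
                 end_rt = "Max End Time", area = "Area",
                 replicate = "Replicate Name", ...)
}

MANDATORY_ROLES <- c("protein", "peptide", "charge", "precursor_mz",
                     "fragment", "product_mz", "apex_rt", "start_rt",
                     "end_rt", "area")

#' Read a transition-level report into a chromatogram library
#'
#' Reads a delimited transition report (one row per transition observation)
#' and groups rows into precursor entries by `(peptide, charge)`. The
#' consensus reference retention time is the median transition apex; the
#' peak width is the median boundary span in seconds. Rows from several
#' replicates of the same precursor land in one entry with their areas kept
#' per replicate.
#'
#' @param path path to a TSV (default) or CSV file with a header row.
#' @param dialect a [report_dialect()] mapping roles to column names.
#' @param gradient_length gradient length in minutes; inferred as the
#'   ceiling of the largest boundary end when `NULL`.
#' @param sep field separator; inferred from the file extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @return a [chrom_library()]. Malformed rows (non-numeric or missing
#'   numeric fields, inverted boundaries) are collected -- not silently
#'   dropped -- into the `"malformed"` attribute with their line numbers,
#'   and reported in one warning. A report with no data rows yields an
#'   empty library with a warning.
#' @export
read_transition_report <- function(path, dialect = report_dialect(),
                                   gradient_length = NULL, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           quote = "\"", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(MANDATORY_ROLES, names(dialect))
  if (length(miss))
    stop_prmflow("dialect lacks role(s): ", paste(miss, collapse = ", "),
                 class = "config_error")
  absent <- setdiff(unname(dialect[MANDATORY_ROLES]), names(raw))
  if (length(absent))
    stop_prmflow("report lacks mandatory column(s): ",
                 paste(absent, collapse = ", "), class = "config_error")
  if (!nrow(raw)) {
    warning("empty transition report: ", path)
    out <- chrom_library(list(), gradient_length %||% 1, basename(path))
    attr(out, "malformed") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  get <- function(role) raw[[dialect[[role]]]]
  num <- function(x) suppressWarnings(as.numeric(x))
  d <- data.frame(protein = get("protein"), peptide = get("peptide"),
                  charge = suppressWarnings(as.integer(get("charge"))),
                  precursor_mz = num(get("precursor_mz")),
                  fragment = get("fragment"),
                  product_mz = num(get("product_mz")),
                  apex_rt = num(get("apex_rt")),
                  start_rt = num(get("start_rt")),
                  end_rt = num(get("end_rt")),
                  area = num(get("area")),
                  stringsAsFactors = FALSE)
  d$replicate <- if ("replicate" %in% names(dialect) &&
                     dialect[["replicate"]] %in% names(raw))
    get("replicate") else "1"
  has_rel <- "expected_rel" %in% names(raw)
  if (has_rel) d$expected_rel <- num(raw[["expected_rel"]])
  reason <- rep(NA_character_, nrow(d))
  numcols <- c("charge", "precursor_mz", "product_mz", "apex_rt",
               "start_rt", "end_rt", "area")
  bad_num <- Reduce(`|`, lapply(d[numcols], is.na))
  reason[bad_num] <- "non-numeric or missing numeric field"
  bad_geom <- !bad_num & !(d$start_rt < d$apex_rt & d$apex_rt < d$end_rt &
                           d$area >= 0)
  reason[bad_geom] <- "invalid boundaries or negative area"
  malformed <- data.frame(line = which(!is.na(reason)) + 1L,  # +1 for header
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  if (nrow(malformed))
    warning(sprintf("%d malformed row(s) skipped (lines %s)",
                    nrow(malformed),
                    paste(utils::head(malformed$line, 5), collapse = ", ")))
  d <- d[is.na(reason), , drop = FALSE]
  if (is.null(gradient_length))
    gradient_length <- if (nrow(d)) ceiling(max(d$end_rt)) else 1
  keys <- precursor_key(d$peptide, d$charge)
  precursors <- lapply(split(seq_len(nrow(d)), keys)[unique(keys)],
                       function(idx) {
    g <- d[idx, , drop = FALSE]
    cols <- c("fragment", "product_mz", "area", "apex_rt",
              "start_rt", "end_rt", "replicate",
              if (has_rel) "expected_rel")
    precursor_entry(g$peptide[1], g$charge[1], g$precursor_mz[1],
                    unique(unlist(strsplit(g$protein, ";"))),
                    g[, cols])
  })
  out <- chrom_library(unname(precursors), gradient_length, basename(path))
  attr(out, "malformed") <- malformed
  out
}

#' Write a schedule plan as a target-list file
#'
#' One delimited row per target per injection, with columns `compound`
#' (peptide), `mz` (precursor m/z, 4 decimal places), `z`, `t_start_min`,
#' `t_end_min` and `injection`. Windows extending past the gradient are
#' clipped to `[0, gradient_length]` with a warning. The file round-trips
#' losslessly through [read_target_list()].
#'
#' @param plan a `schedule_plan`; every entry must carry a window.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_target_list <- function(plan, path) {
  stopifnot(inherits(plan, "schedule_plan"))
  e <- plan$entries
  if (!nrow(e))
    stop_prmflow("plan has no scheduled targets", class = "invariant_error")
  if (any(is.na(e$window_start) | is.na(e$window_end)))
    stop_prmflow("plan contains unscheduled precursors",
                 class = "invariant_error")
  grad <- plan$params$gradient_length
  if (any(e$window_start < 0 | e$window_end > grad)) {
    warning("windows clipped to [0, gradient_length]")
    e$window_start <- pmax(e$window_start, 0)
    e$window_end <- pmin(e$window_end, grad)
  }
  out <- data.frame(compound = e$peptide,
                    mz = sprintf("%.4f", e$precursor_mz),
                    z = e$charge,
                    t_start_min = e$window_start,
                    t_end_min = e$window_end,
                    injection = e$injection)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a target list written by [write_target_list()]
#'
#' @param path CSV path.
#' @return data frame `compound`, `mz`, `z`, `t_start_min`, `t_end_min`,
#'   `injection`.
#' @export
read_target_list <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound = "character", mz = "numeric",
                                 z = "integer", t_start_min = "numeric",
                                 t_end_min = "numeric",
                                 injection = "integer"))
}

RTBIN_MAGIC <- "PRMFLOWREF"

#' Serialize and restore a reference map
#'
#' The reference map is stored in a documented single-file binary
#' container (an open analog of the proprietary serialized reference used
#' on-instrument): a magic string, a version tag, integer dimensions, then
#' IEEE-754 doubles for the window bounds, the retention-time grid and the
#' spectra, all little-endian. The round trip restores grids and spectra to
#' full stored precision. Layout:
#'
#' ```
#' char[10] magic "PRMFLOWREF" | int32 version | int32 n_win, n_rt, n_bins
#' double bin_width, frag_lo, frag_hi
#' double window bounds (n_win x 2, column-major)
#' double rt_grid (n_rt)
#' double spectra (n_bins * n_rt per window, windows in order)
#' ```
#'
#' @param map a `reference_map` with a nonempty retention-time grid.
#' @param path file path.
#' @return `save_reference()` returns `path` invisibly; `load_reference()`
#'   returns the `reference_map`. A truncated or foreign file fails
#'   cleanly without producing a partial object; a version tag the reader
#'   does not support raises an unsupported-version error.
#' @export
save_reference <- function(map, path) {
  stopifnot(inherits(map, "reference_map"))
  if (!length(map$rt_grid))
    stop_prmflow("refusing to save a reference map with an empty RT grid",
                 class = "invalid_reference")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(RTBIN_MAGIC), con)
  writeBin(as.integer(c(map$version, nrow(map$dia_windows),
                        length(map$rt_grid), nrow(map$spectra[[1]]))),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(map$bin_width, map$frag_range)), con,
           endian = "little")
  writeBin(as.numeric(map$dia_windows), con, endian = "little")
  writeBin(as.numeric(map$rt_grid), con, endian = "little")
  for (w in seq_along(map$spectra))
    writeBin(as.numeric(map$spectra[[w]]), con, endian = "little")
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", nchar(RTBIN_MAGIC)))
  if (!identical(magic, RTBIN_MAGIC))
    stop_prmflow("not a reference-map file: ", path, class = "bad_container")
  ints <- readBin(con, "integer", 4, size = 4, endian = "little")
  if (length(ints) < 4)
    stop_prmflow("truncated reference-map file: ", path,
                 class = "bad_container")
  version <- ints[1]; n_win <- ints[2]; n_rt <- ints[3]; n_bins <- ints[4]
  if (version != 1L)
    stop_prmflow("unsupported reference-map version: ", version,
                 class = "unsupported_version")
  need <- 3 + n_win * 2 + n_rt + n_win * n_bins * n_rt
  vals <- readBin(con, "double", need, endian = "little")
  if (length(vals) < need)
    stop_prmflow("truncated reference-map file: ", path,
                 class = "bad_container")
  bin_width <- vals[1]; frag_range <- vals[2:3]
  pos <- 3
  dia_windows <- matrix(vals[pos + seq_len(n_win * 2)], n_win, 2,
                        dimnames = list(NULL, c("lo", "hi")))
  pos <- pos + n_win * 2
  rt_grid <- vals[pos + seq_len(n_rt)]
  pos <- pos + n_rt
  spectra <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    spectra[[w]] <- matrix(vals[pos + seq_len(n_bins * n_rt)], n_bins, n_rt)
    pos <- pos + n_bins * n_rt
  }
  structure(list(dia_windows = dia_windows, rt_grid = rt_grid,
                 bin_width = bin_width, frag_range = frag_range,
                 spectra = spectra, version = version),
            class = "reference_map")
}

#' Write a synthetic library as a transition report
#'
#' Emits the package's native transition-report TSV (see
#' [report_dialect()]) so generated libraries can be fed back through
#' [read_transition_report()] and the command-line tools.
#'
#' @param lib a [chrom_library()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(lib, path) {
  stopifnot(inherits(lib, "chrom_library"))
  rows <- lapply(lib$precursors, function(p) {
    tr <- p$transitions
    out <- data.frame(protein = paste(p$protein_ids, collapse = ";"),
                      peptide = p$peptide, charge = p$charge,
                      precursor_mz = p$precursor_mz,
                      fragment = tr$fragment, product_mz = tr$product_mz,
                      apex_rt = tr$apex_rt, start_rt = tr$start_rt,
                      end_rt = tr$end_rt, area = tr$area,
                      replicate = tr$replicate, stringsAsFactors = FALSE)
    if ("expected_rel" %in% names(tr)) out$expected_rel <- tr$expected_rel
    out
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), peptide = character(),
               charge = integer(), precursor_mz = numeric(),
               fragment = character(), product_mz = numeric(),
               apex_rt = numeric(), start_rt = numeric(),
               end_rt = numeric(), area = numeric(),
               replicate = character())
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
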