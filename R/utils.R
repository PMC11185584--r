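#' Unit conversions between minutes and seconds
#'
#' Retention times and window boundaries are kept in minutes throughout the
#' package; chromatographic peak widths and instrument cycle times are kept
#' in seconds, matching how both are conventionally reported. All
#' conversions go through these two helpers so the convention lives in one
#' place.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @examples
#' min_to_sec(0.75)  # 45 s
#' sec_to_min(13.9)
#' @export
min_to_sec <- function(x) x * 60

#' @rdname min_to_sec
#' @export
sec_to_min <- function(x) x / 60

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical precursor key
#'
#' Precursors are identified throughout the package (schedule entries,
#' simulation logs, figure-of-merit tables) by the string
#' `"<peptide>/<charge>"`.
#'
#' @param peptide modified sequence string(s).
#' @param charge precursor charge(s).
#' @return character vector of keys.
#' @export
precursor_key <- function(peptide, charge) paste0(peptide, "/", charge)

## trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

## weighted pool-adjacent-violators: isotonic (nondecreasing) fit of y on
## ordered x with weights w.  Small n (alignment anchors), plain loop.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n <= 1) return(y)
  k <- 1L
  blk_val <- numeric(n); blk_w <- numeric(n); blk_lo <- integer(n)
  blk_val[1] <- y[1]; blk_w[1] <- w[1]; blk_lo[1] <- 1L
  for (i in 2:n) {
    k <- k + 1L
    blk_val[k] <- y[i]; blk_w[k] <- w[i]; blk_lo[k] <- i
    while (k > 1L && blk_val[k - 1L] > blk_val[k]) {
      tot <- blk_w[k - 1L] + blk_w[k]
      blk_val[k - 1L] <- (blk_val[k - 1L] * blk_w[k - 1L] +
                          blk_val[k] * blk_w[k]) / tot
      blk_w[k - 1L] <- tot
      k <- k - 1L
    }
  }
  out <- numeric(n)
  blk_hi <- if (k == 1L) n else c(blk_lo[2:k] - 1L, n)
  for (b in seq_len(k)) out[blk_lo[b]:blk_hi[b]] <- blk_val[b]
  out
}

stop_prmflow <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "prmflow_error")))
}
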