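# Shared helpers: rounding, intervals, sequence utilities.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported rates.
#' `base::round()` rounds half to even, which does not reproduce printed
#' two-decimal rates such as 0.45 from 74/165.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# round to the nearest multiple of `unit`, half-up
round_to_nearest <- function(x, unit) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

#' Construct a 0-based half-open interval
#'
#' Internal coordinate convention for all records: 0-based, half-open
#' `[start, end)`. File formats use 1-based inclusive coordinates and are
#' converted at the IO boundary.
#'
#' @param start,end integer bounds, `start <= end`.
#' @return an `interval` object (length-2 integer vector).
#' @export
interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (end < start) stop("interval end (", end, ") precedes start (", start, ")")
  structure(c(start = start, end = end), class = "interval")
}

interval_len <- function(iv) unname(iv[["end"]] - iv[["start"]])

# does [a) contain position p (0-based)?
interval_contains <- function(iv, p) {
  p >= iv[["start"]] & p < iv[["end"]]
}

interval_overlaps <- function(a, b) {
  a[["start"]] < b[["end"]] && b[["start"]] < a[["end"]]
}

# 0-based half-open substring of a character scalar
subseq0 <- function(seq, iv) {
  substr(seq, iv[["start"]] + 1L, iv[["end"]])
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

gc_fraction <- function(primer) {
  b <- chars(primer)
  mean(b %in% c("G", "C"))
}

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
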