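#' Genomic interval conventions
#'
#' All coordinates inside the package are 0-based, half-open (`[start, end)`),
#' the BED convention: `start` is the offset of the first base, `end` is one
#' past the last. Published locus coordinates (e.g. `chr2:172551998-172555000`)
#' are 1-based inclusive; conversion happens only at the I/O boundary, with
#' [from_1based()] and [to_1based()].
#'
#' @param start,end interval bounds. For `from_1based()` these are 1-based
#'   inclusive; for `to_1based()` 0-based half-open.
#' @return A tibble with 0-based half-open (`from_1based`) or 1-based
#'   inclusive (`to_1based`) `start`/`end` columns.
#' @examples
#' from_1based(172551998, 172555000) # the FB1 enhancer interval
#' @export
from_1based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  tibble(start = start - 1, end = end)
}

#' @rdname from_1based
#' @export
to_1based <- function(start, end) {
  check_interval(start, end)
  tibble(start = start + 1, end = end)
}

# shared validation: 0 <= start < end, vectorized
check_interval <- function(start, end, chrom_length = NULL) {
  if (any(start < 0) || any(end <= start)) {
    abort("intervals must satisfy 0 <= start < end (0-based half-open)")
  }
  if (!is.null(chrom_length) && any(end > chrom_length)) {
    abort(sprintf("interval end exceeds chromosome length (%d)", chrom_length))
  }
  invisible(TRUE)
}

# overlap length of [s1,e1) and [s2,e2); vectorized, >= 0
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Jaccard index of two single intervals
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- interval_overlap(s1, e1, s2, e2)
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0) return(1) # two empty/identical degenerate intervals
  inter / union
}

# midpoint of a half-open interval
interval_mid <- function(start, end) (start + end) / 2
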