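#' Define 4C viewpoints
#'
#' A viewpoint is the restriction fragment whose ligation partners the 4C
#' library captures. Each sequencing library carries a short inline barcode
#' (3-6 nt of tag sequence at the read 5' end) so pooled libraries can be
#' demultiplexed; the tag set of one pool must be mutually prefix-free, or
#' assignment would be ambiguous.
#'
#' @param name viewpoint names.
#' @param chrom,position genomic anchor of each viewpoint (0-based bp).
#' @param tag inline barcode, 3-6 nt.
#' @param tissue tissue label of the library.
#' @return A tibble usable by [demultiplex()] and [build_profile()].
#' @export
viewpoint_table <- function(name, chrom, position, tag, tissue = "unspecified") {
  nc <- nchar(tag)
  if (any(nc < 3 | nc > 6)) abort("tags must be 3-6 nt long")
  check_prefix_free(tag)
  tibble(name = name, chrom = chrom, position = position,
         tag = toupper(tag), tissue = tissue)
}

check_prefix_free <- function(tags) {
  tags <- toupper(tags)
  if (anyDuplicated(tags)) abort("duplicate barcode tags")
  for (i in seq_along(tags)) {
    pre <- tags[-i][startsWith(tags[-i], tags[i])]
    if (length(pre) > 0) {
      abort(sprintf("tag '%s' is a prefix of tag '%s': set is ambiguous",
                    tags[i], pre[1]))
    }
  }
  invisible(TRUE)
}

#' Demultiplex pooled 4C reads by inline barcode
#'
#' Assigns each read to the unique viewpoint whose tag exactly matches the
#' read's 5' prefix and trims the tag. No mismatches are tolerated; reads
#' matching no tag stay unassigned. Assignment is per-read, so the result does
#' not depend on read order.
#'
#' @param reads a tibble with `name` and `seq` columns, a named character
#'   vector of sequences, or a `DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet(path, format = "fastq")`).
#' @param viewpoints a [viewpoint_table()].
#' @return Tibble with `name`, `seq` (tag-trimmed for assigned reads),
#'   `viewpoint` (`NA` for unassigned) and `tissue`.
#' @export
demultiplex <- function(reads, viewpoints) {
  reads <- as_read_tibble(reads)
  check_prefix_free(viewpoints$tag)
  out <- mutate(reads, viewpoint = NA_character_, tissue = NA_character_)
  for (i in seq_len(nrow(viewpoints))) {
    hit <- is.na(out$viewpoint) & startsWith(out$seq, viewpoints$tag[i])
    out$viewpoint[hit] <- viewpoints$name[i]
    out$tissue[hit] <- viewpoints$tissue[i]
    out$seq[hit] <- substring(out$seq[hit], nchar(viewpoints$tag[i]) + 1L)
  }
  out
}

as_read_tibble <- function(reads) {
  if (inherits(reads, "XStringSet")) {
    tibble(name = names(reads) %||% as.character(seq_along(reads)),
           seq = unname(as.character(reads)))
  } else if (is.character(reads)) {
    tibble(name = names(reads) %||% as.character(seq_along(reads)),
           seq = unname(reads))
  } else {
    stopifnot(all(c("name", "seq") %in% names(reads)))
    tibble(name = reads$name, seq = reads$seq)
  }
}

#' Tally aligned positions per restriction fragment
#'
#' @param map a `fragment_map`.
#' @param positions 0-based aligned positions (5'-most coordinate), either a
#'   numeric vector on the map's chromosome or a tibble with `chrom` and `pos`;
#'   positions on chromosomes absent from the map are counted and reported via
#'   the `off_map` attribute.
#' @return Integer vector of counts, one per map fragment (sums to the number
#'   of in-map positions).
#' @export
count_per_fragment <- function(map, positions) {
  if (is.data.frame(positions)) {
    on_map <- positions$chrom %in% unique(map$chrom)
    off <- sum(!on_map)
    pos <- positions$pos[on_map]
  } else {
    off <- 0L
    pos <- positions
  }
  counts <- integer(nrow(map))
  if (length(pos) > 0) {
    idx <- assign_read(map, pos) + 1L
    t <- tabulate(idx, nbins = nrow(map))
    counts <- as.integer(t)
  }
  if (off > 0) warn(sprintf("%d position(s) on chromosomes absent from the map", off))
  structure(counts, off_map = off)
}

#' Assemble a per-fragment viewpoint profile
#'
#' The container for one viewpoint x tissue 4C track: raw fragment counts plus
#' the normalized, masked and smoothed layers filled in by [rpm_normalize()],
#' [mask_viewpoint()], [mask_regions()] and [smooth_profile()].
#'
#' @param map a `fragment_map`.
#' @param raw integer counts per fragment (e.g. from [count_per_fragment()]).
#' @param viewpoint one row of a [viewpoint_table()].
#' @return A `vp_profile` tibble: fragment coordinates, `midpoint`, `raw`,
#'   `normalized`, `masked`, `smoothed`; the viewpoint row and its resolved
#'   fragment index are attributes.
#' @export
build_profile <- function(map, raw, viewpoint) {
  stopifnot(length(raw) == nrow(map), all(raw >= 0))
  vp_frag <- assign_read(map, viewpoint$position)
  prof <- tibble(
    chrom = map$chrom, start = map$start, end = map$end, index = map$index,
    midpoint = interval_mid(map$start, map$end),
    raw = as.integer(round(raw)), normalized = NA_real_,
    masked = FALSE, smoothed = NA_real_
  )
  structure(prof,
    class = c("vp_profile", class(tibble())),
    viewpoint = as.list(viewpoint[1, ]),
    vp_fragment = vp_frag,
    chrom_length = attr(map, "chrom_length"),
    window = NA_integer_
  )
}

#' @export
print.vp_profile <- function(x, ...) {
  vp <- attr(x, "viewpoint")
  cat(sprintf("<vp_profile> %s (%s), %d fragments, %d masked, %s reads\n",
              vp$name, vp$tissue, nrow(x), sum(x$masked),
              format(sum(x$raw), big.mark = ",")))
  NextMethod()
}

#' Reads-per-million normalization
#'
#' Divides each fragment's count by the total count on the viewpoint
#' chromosome and multiplies by 1,000,000, so the normalized track on the
#' viewpoint chromosome sums to exactly 1e6 and libraries of different depth
#' are comparable.
#'
#' @param profile a `vp_profile` with raw counts.
#' @return The profile with `normalized` filled.
#' @export
rpm_normalize <- function(profile) {
  vp <- attr(profile, "viewpoint")
  on_vp_chrom <- profile$chrom == vp$chrom
  total <- sum(profile$raw[on_vp_chrom])
  if (total <= 0) {
    abort(sprintf("no reads on the viewpoint chromosome '%s': cannot normalize",
                  vp$chrom))
  }
  profile$normalized <- profile$raw / total * 1e6
  profile
}

#' Mask fragments near the viewpoint
#'
#' 4C signal within a short distance of the viewpoint is dominated by
#' self-ligation and undigested templates; fragments whose midpoint lies
#' within `radius` of the viewpoint fragment's midpoint are excluded from all
#' downstream statistics (10 kb by default). The viewpoint fragment itself is
#' always masked.
#'
#' @param profile a `vp_profile`.
#' @param radius exclusion radius in bp around the viewpoint fragment midpoint.
#' @return The profile with `masked` updated (masking only ever grows).
#' @export
mask_viewpoint <- function(profile, radius = 10000) {
  vp <- attr(profile, "viewpoint")
  vp_mid <- profile$midpoint[profile$index == attr(profile, "vp_fragment") &
                               profile$chrom == vp$chrom]
  near <- profile$chrom == vp$chrom & abs(profile$midpoint - vp_mid) <= radius
  near[profile$chrom == vp$chrom & profile$index == attr(profile, "vp_fragment")] <- TRUE
  profile$masked <- profile$masked | near
  profile
}

#' Mask fragments overlapping exclusion regions
#'
#' Fragments overlapping (by at least 1 bp) any interval of an exclusion set —
#' typically low-mappability regions where absent signal is artifactual — are
#' masked.
#'
#' @param profile a `vp_profile`.
#' @param regions tibble with `start`, `end` (0-based half-open) and optional
#'   `chrom`; e.g. from [read_bed()].
#' @return The profile with `masked` updated.
#' @export
mask_regions <- function(profile, regions) {
  if (nrow(regions) == 0) return(profile)
  for (i in seq_len(nrow(regions))) {
    same <- if ("chrom" %in% names(regions)) {
      profile$chrom == regions$chrom[i]
    } else TRUE
    ov <- interval_overlap(profile$start, profile$end,
                           regions$start[i], regions$end[i]) > 0
    profile$masked <- profile$masked | (same & ov)
  }
  profile
}

#' Smooth the normalized profile over adjacent fragments
#'
#' Running mean over a centered window of `window` fragments (11 by default),
#' truncated at chromosome ends. Masked fragments contribute to neither the
#' numerator nor the denominator, so low-mappability gaps do not drag the
#' smoothed signal down; smoothed values at masked fragments are `NA`.
#'
#' @param profile a normalized `vp_profile`.
#' @param window odd window size in fragments.
#' @return The profile with `smoothed` filled.
#' @export
smooth_profile <- function(profile, window = 11) {
  if (window %% 2 == 0 || window < 1) abort("window must be odd and >= 1")
  if (all(is.na(profile$normalized))) abort("normalize the profile first")
  half <- (window - 1) / 2
  out <- profile
  for (ch in unique(profile$chrom)) {
    rows <- which(profile$chrom == ch)
    x <- profile$normalized[rows]
    keep <- !profile$masked[rows]
    num <- windowed_sum(ifelse(keep, x, 0), half)
    den <- windowed_sum(as.numeric(keep), half)
    sm <- ifelse(den > 0, num / den, 0)
    sm[!keep] <- NA_real_
    out$smoothed[rows] <- sm
  }
  attr(out, "window") <- as.integer(window)
  out
}

# centered running sum with truncated edges, O(n) via cumsum
windowed_sum <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(0, seq_len(n) - half - 1)
  cs[hi + 1] - cs[lo + 1]
}

#' Per-library profile summary
#'
#' @param x a `vp_profile`.
#' @param ... unused.
#' @return One-row tibble: viewpoint, tissue, total reads, reads on the
#'   viewpoint chromosome, fraction masked, smoothing window.
#' @export
glance.vp_profile <- function(x, ...) {
  vp <- attr(x, "viewpoint")
  tibble(
    viewpoint = vp$name, tissue = vp$tissue,
    total_reads = sum(x$raw),
    vp_chrom_reads = sum(x$raw[x$chrom == vp$chrom]),
    n_fragments = nrow(x),
    frac_masked = mean(x$masked),
    window = attr(x, "window")
  )
}
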