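#' Locate restriction-site motifs on the forward strand
#'
#' Exact occurrences of a recognition motif in a nucleotide sequence,
#' overlapping matches allowed; `N` never matches. The two enzymes used by the
#' 4C protocol modelled here, NlaIII (`CATG`) and DpnII (`GATC`), are
#' palindromic, so forward-strand scanning is complete.
#'
#' @param sequence character scalar or [Biostrings::DNAString] over A/C/G/T/N.
#' @param motif recognition sequence, e.g. `"CATG"`.
#' @return Integer vector of 0-based match start offsets.
#' @examples
#' find_sites("TTCATGAA", "CATG") # 2
#' @export
find_sites <- function(sequence, motif) {
  if (nchar(as.character(motif)) == 0) abort("motif must be non-empty")
  seq <- if (inherits(sequence, "DNAString")) sequence else {
    if (nchar(sequence) == 0) return(integer())
    Biostrings::DNAString(sequence)
  }
  # fixed = TRUE: literal matching, so N in the subject matches nothing
  m <- Biostrings::matchPattern(toupper(as.character(motif)), seq, fixed = TRUE)
  as.integer(Biostrings::start(m)) - 1L
}

#' In-silico digestion of a chromosome into a restriction-fragment map
#'
#' Cuts a sequence at every primary-enzyme site and returns the ordered
#' fragments tiling the chromosome. The cut is placed after the last motif
#' base on the forward strand (`CATG^`), so the motif stays on the upstream
#' fragment's 3' end. A sequence without sites yields a single fragment.
#'
#' @param sequence character scalar or `DNAString` (one chromosome).
#' @param primary_motif primary enzyme recognition sequence (NlaIII default).
#' @param chrom chromosome name recorded in the map.
#' @return A `fragment_map`: tibble with `chrom`, `start`, `end` (0-based
#'   half-open), `index` (0-based ordinal), `length`, and — after
#'   [annotate_secondary()] — `has_secondary_site`/`blind`. Attributes
#'   `primary_motif`, `secondary_motif`, `chrom_length`.
#' @examples
#' digest("TTCATGAA", "CATG") # fragments [0,6) and [6,8)
#' @export
digest <- function(sequence, primary_motif = "CATG", chrom = "chr1") {
  len <- if (inherits(sequence, "DNAString")) length(sequence) else nchar(sequence)
  sites <- find_sites(sequence, primary_motif)
  cuts <- sites + nchar(primary_motif)
  bounds <- unique(c(0, cuts[cuts > 0 & cuts < len], len))
  map <- tibble(
    chrom = chrom,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    index = seq_len(length(bounds) - 1L) - 1L
  )
  map$length <- map$end - map$start
  map$has_secondary_site <- NA
  map$blind <- NA
  new_fragment_map(map, primary_motif = primary_motif,
                   chrom_length = len)
}

#' Construct a fragment map from explicit boundaries
#'
#' For maps not produced by [digest()] (pre-computed digests, uniform toy
#' maps): fragments must tile `[0, chrom_length)` without gaps.
#'
#' @param start,end fragment bounds, 0-based half-open, adjacent
#'   (`end[i] == start[i + 1]`), starting at 0.
#' @param chrom chromosome name.
#' @param blind optional logical vector (no internal secondary site).
#' @return A `fragment_map` tibble.
#' @examples
#' fragment_map(seq(0, 9000, 1000), seq(1000, 10000, 1000))
#' @export
fragment_map <- function(start, end, chrom = "chr1", blind = NA) {
  check_interval(start, end)
  if (start[1] != 0 || any(start[-1] != end[-length(end)])) {
    abort("fragments must tile the chromosome: start at 0, be adjacent")
  }
  map <- tibble(
    chrom = chrom, start = start, end = end,
    index = seq_along(start) - 1L, length = end - start,
    has_secondary_site = !blind, blind = blind
  )
  new_fragment_map(map, chrom_length = end[length(end)])
}

new_fragment_map <- function(map, primary_motif = NA_character_,
                             secondary_motif = NA_character_,
                             chrom_length = max(map$end)) {
  structure(map,
    class = c("fragment_map", class(tibble())),
    primary_motif = primary_motif,
    secondary_motif = secondary_motif,
    chrom_length = chrom_length
  )
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("<fragment_map> %d fragments, %s bp (%s%s)\n",
              nrow(x), format(attr(x, "chrom_length"), big.mark = ","),
              attr(x, "primary_motif"),
              if (is.na(attr(x, "secondary_motif"))) "" else
                paste0("/", attr(x, "secondary_motif"))))
  NextMethod()
}

#' Annotate fragments with secondary-enzyme sites
#'
#' Marks each primary fragment according to whether at least one secondary
#' motif occurrence lies fully inside it. Fragments without an internal
#' secondary site are "blind": in the 4C protocol they cannot form the second
#' ligation junction and their counts are unreliable. A motif straddling a
#' fragment boundary annotates neither fragment.
#'
#' @param map a [digest()] result.
#' @param sequence the same sequence the map was built from.
#' @param secondary_motif secondary enzyme recognition sequence (DpnII default).
#' @return The map with `has_secondary_site` and `blind` filled.
#' @export
annotate_secondary <- function(map, sequence, secondary_motif = "GATC") {
  len <- if (inherits(sequence, "DNAString")) length(sequence) else nchar(sequence)
  if (len != attr(map, "chrom_length")) {
    abort("sequence length does not match the fragment map")
  }
  sites <- find_sites(sequence, secondary_motif)
  site_end <- sites + nchar(secondary_motif)
  # a site is inside fragment f iff start >= f.start and end <= f.end
  f <- findInterval(sites, map$start)
  inside <- f >= 1 & site_end <= map$end[f]
  map$has_secondary_site <- map$index %in% (f[inside] - 1L)
  map$blind <- !map$has_secondary_site
  attr(map, "secondary_motif") <- secondary_motif
  map
}

#' Assign read positions to restriction fragments
#'
#' Binary-search lookup of the fragment containing each position (its 5'-most
#' aligned coordinate). Positions use the same 0-based convention as the map;
#' the half-open rule puts a position equal to a fragment boundary into the
#' downstream fragment.
#'
#' @param map a `fragment_map`.
#' @param position vector of 0-based positions on the map's chromosome.
#' @param chrom chromosome of the positions; must match the map.
#' @return Integer vector of 0-based fragment indices.
#' @export
assign_read <- function(map, position, chrom = NULL) {
  if (!is.null(chrom) && any(chrom != map$chrom[1])) {
    abort(sprintf("unknown chromosome: map covers '%s' only", map$chrom[1]))
  }
  if (any(position < 0) || any(position >= attr(map, "chrom_length"))) {
    abort("position outside the chromosome")
  }
  findInterval(position, map$start) - 1L
}

#' Digest every record of a FASTA file
#'
#' @param path FASTA file (may contain several chromosomes).
#' @inheritParams digest
#' @param secondary_motif if non-`NULL`, [annotate_secondary()] is applied.
#' @return A single tibble of fragments over all records (class
#'   `fragment_map` when the file has one record, plain tibble otherwise,
#'   with per-chromosome 0-based `index`).
#' @export
digest_fasta <- function(path, primary_motif = "CATG", secondary_motif = "GATC") {
  seqs <- Biostrings::readDNAStringSet(path)
  maps <- purrr::map(seq_along(seqs), function(i) {
    m <- digest(seqs[[i]], primary_motif, chrom = names(seqs)[i])
    if (!is.null(secondary_motif)) m <- annotate_secondary(m, seqs[[i]], secondary_motif)
    m
  })
  if (length(maps) == 1) maps[[1]] else bind_rows(maps)
}
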