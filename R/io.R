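#' Read and write BED / BedGraph tracks
#'
#' Thin wrappers around [rtracklayer] keeping the package's tibble-and-0-based
#' convention: BED and BedGraph are themselves 0-based half-open, so
#' coordinates pass through unchanged.
#'
#' @param path file path.
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` and, when
#'   present, `name`/`score`. `read_bedgraph()`: tibble with `chrom`, `start`,
#'   `end`, `value`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' @rdname read_bed
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = gr$score
  )
}

#' @rdname read_bed
#' @param x tibble with `chrom`, `start`, `end` and `name` (BED) or `value`
#'   (BedGraph) columns; 0-based half-open.
#' @param track_name optional track-line name (e.g. the allele), written as a
#'   BedGraph header.
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1, x$end),
    name = if ("name" %in% names(x)) x$name else "."
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @export
write_bedgraph <- function(x, path, track_name = NULL) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end),
                               score = x$value)
  if (is.null(track_name)) {
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    line <- methods::new("GraphTrackLine", name = track_name, type = "bedGraph")
    rtracklayer::export(gr, path, format = "bedGraph", trackLine = line)
  }
  invisible(path)
}

#' Export the layers of a viewpoint profile
#'
#' Writes BedGraph tracks for the raw, normalized and smoothed layers plus a
#' BED of masked fragments, the standard genome-browser representation of a
#' processed 4C library.
#'
#' @param profile a `vp_profile`.
#' @param prefix output path prefix; files `<prefix>.raw.bedgraph` etc. are
#'   created.
#' @return Invisibly, the written paths.
#' @export
write_profile_tracks <- function(profile, prefix) {
  vp <- attr(profile, "viewpoint")
  paths <- c()
  for (layer in c("raw", "normalized", "smoothed")) {
    v <- profile[[layer]]
    if (all(is.na(v))) next
    keep <- !is.na(v)
    p <- paste0(prefix, ".", layer, ".bedgraph")
    write_bedgraph(
      tibble(chrom = profile$chrom[keep], start = profile$start[keep],
             end = profile$end[keep], value = v[keep]),
      p, track_name = paste(vp$name, vp$tissue, layer, sep = "_")
    )
    paths <- c(paths, p)
  }
  if (any(profile$masked)) {
    p <- paste0(prefix, ".mask.bed")
    m <- profile[profile$masked, ]
    write_bed(tibble(chrom = m$chrom, start = m$start, end = m$end,
                     name = "masked"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read/write fragment-map tables
#'
#' Tab-delimited interchange format: `chrom`, `start`, `end`, `index`,
#' `blind` (0-based half-open coordinates).
#'
#' @param map a `fragment_map`; `path` a file path.
#' @export
write_fragment_map <- function(map, path) {
  df <- as.data.frame(map[, c("chrom", "start", "end", "index", "blind")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  df <- utils::read.delim(path)
  map <- as_tibble(df)
  map$length <- map$end - map$start
  map$has_secondary_site <- !map$blind
  new_fragment_map(map[, c("chrom", "start", "end", "index", "length",
                           "has_secondary_site", "blind")])
}

#' Read a viewpoint table
#'
#' Tab-delimited columns `name`, `chrom`, `position` (0-based), `tag`,
#' `tissue`.
#'
#' @param path file path.
#' @return A validated [viewpoint_table()].
#' @export
read_viewpoint_table <- function(path) {
  df <- utils::read.delim(path, colClasses = c(tag = "character"))
  viewpoint_table(df$name, df$chrom, df$position, df$tag, df$tissue)
}

#' Write simulated reads as FASTQ
#'
#' @param reads tibble with `name` and `seq` (e.g. from [simulate_reads()]).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  q <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) paste(rep("I", n), collapse = ""),
           character(1))
  )
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ reads into the demultiplexer's input form
#'
#' @param path FASTQ file.
#' @return Tibble with `name`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as_read_tibble(x)
}
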