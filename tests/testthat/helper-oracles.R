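# Independent oracles and small fixtures used across the suite.

# Per-base labeling oracle for rearrangements: materialize the rearranged
# chromosome as a vector of reference base labels (0-based) plus strand, by
# direct splicing. Events must be pairwise non-overlapping.
label_oracle <- function(events, reference_length) {
  labels <- seq_len(reference_length) - 1L
  strand <- rep("+", reference_length)
  if (nrow(events) > 0) {
    events <- events[order(events$start, decreasing = TRUE), ]
    for (i in seq_len(nrow(events))) {
      sel <- (events$start[i] + 1):events$end[i]
      if (events$kind[i] == "deletion") {
        labels <- labels[-sel]
        strand <- strand[-sel]
      } else if (events$kind[i] == "inversion") {
        labels[sel] <- rev(labels[sel])
        strand[sel] <- ifelse(strand[sel] == "+", "-", "+")
      } else if (events$kind[i] == "tandem_duplication") {
        labels <- append(labels, labels[sel], after = events$end[i])
        strand <- append(strand, strand[sel], after = events$end[i])
      }
    }
  }
  list(labels = labels, strand = strand)
}

# Exhaustive minimum SSE over all placements of k contiguous segments.
exhaustive_sse <- function(y, k) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  segcost <- function(a, b) cs2[b + 1] - cs2[a] - (cs[b + 1] - cs[a])^2 / (b - a + 1)
  if (k == 1) return(segcost(1, n))
  combos <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    bounds <- c(0, combos[, j], n)
    sse <- sum(vapply(seq_len(k), function(i) {
      segcost(bounds[i] + 1, bounds[i + 1])
    }, numeric(1)))
    if (sse < best) best <- sse
  }
  best
}

# Scaled-down synthetic locus: same structure as the default (two domains
# overlapping in a TZ, viewpoints straddling it) on a 200-kb chromosome,
# cheap enough for unit tests.
small_locus <- function(library_size = 5e4, dispersion = 0.1,
                        tissue = "brain") {
  synthetic_locus_spec(
    chrom_length = 2e5, library_size = library_size, dispersion = dispersion,
    domain_a = c(40000, 102000), domain_b = c(98000, 160000),
    tz = c(98000, 102000),
    peaks = tibble::tibble(position = c(56000, 112000), amplitude = c(2, 2),
                           width = c(3000, 3000), tissue = c("brain", "heart")),
    viewpoints = viewpoint_table(c("vpA", "vpB"), "chrS", c(70000, 130000),
                                 c("ACGT", "TGCAC"), tissue = tissue)
  )
}

# Uniform toy fragment map: nfrag fragments of width bp each.
uniform_map <- function(nfrag, width = 1000, chrom = "chrU") {
  fragment_map(seq(0, (nfrag - 1) * width, width),
               seq(width, nfrag * width, width), chrom = chrom)
}

# Planted domain edges of a viewpoint in fragment indices (midpoint rule).
planted_fragments <- function(map, domain) {
  mid <- (map$start + map$end) / 2
  c(min(map$index[mid >= domain[1]]), max(map$index[mid < domain[2]]))
}
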