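#' Detect the transition zone between two primary interaction domains
#'
#' Two adjacent viewpoints' primary interaction domains typically overlap over
#' a short region — the transition zone (TZ), which contacts both sides of the
#' locus. This classifies a domain pair as `overlap` (a TZ: the intersection,
#' with Jaccard below `merge_fraction`), `gap` (disjoint domains; the interval
#' between them), or `merged` (Jaccard at or above `merge_fraction`, as when
#' deleting the TZ fuses the two domains into one).
#'
#' @param dom_a,dom_b `interaction_domain` rows (or any one-row tibble with
#'   `chrom`, `start`, `end`), in the same coordinate frame/allele.
#' @param merge_fraction Jaccard cutoff separating a localized overlap from
#'   wholesale domain fusion.
#' @return A `transition_zone` one-row tibble: `relation`, `start`, `end`,
#'   `width` (bp), `jaccard`, plus the source domain bounds.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 5e5)
#' b <- tibble::tibble(chrom = "chr1", start = 4.8e5, end = 9e5)
#' detect_transition_zone(a, b) # 20-kb overlap
#' @export
detect_transition_zone <- function(dom_a, dom_b, merge_fraction = 0.5) {
  if (dom_a$chrom[1] != dom_b$chrom[1]) {
    abort("domains must lie on one chromosome / coordinate frame")
  }
  a <- c(dom_a$start[1], dom_a$end[1])
  b <- c(dom_b$start[1], dom_b$end[1])
  jac <- interval_jaccard(a[1], a[2], b[1], b[2])
  inter <- c(max(a[1], b[1]), min(a[2], b[2]))
  if (jac >= merge_fraction) {
    relation <- "merged"
    iv <- c(min(a[1], b[1]), max(a[2], b[2])) # the fused span
  } else if (inter[1] < inter[2]) {
    relation <- "overlap"
    iv <- inter
  } else {
    relation <- "gap"
    iv <- c(min(a[2], b[2]), max(a[1], b[1]))
  }
  structure(
    tibble(relation = relation, chrom = dom_a$chrom[1],
           start = iv[1], end = iv[2], width = iv[2] - iv[1], jaccard = jac,
           a_start = a[1], a_end = a[2], b_start = b[1], b_end = b[2]),
    class = c("transition_zone", class(tibble()))
  )
}

#' Cumulative 4C signal left and right of the viewpoint
#'
#' Sums normalized signal over unmasked fragments whose midpoints lie within
#' increasing distances of the viewpoint, separately for each side, excluding
#' the viewpoint-proximal zone. An asymmetric locus (e.g. a viewpoint next to
#' a transition zone) shows the two curves diverging; the log2 right/left
#' ratio quantifies this, guarded with one normalized unit against empty
#' sides.
#'
#' @param profile a normalized, viewpoint-masked `vp_profile`.
#' @param max_distance largest distance evaluated (bp); defaults to covering
#'   the chromosome.
#' @param step grid spacing in bp.
#' @param exclusion_radius viewpoint-proximal distance excluded from the sums
#'   (should match the [mask_viewpoint()] radius).
#' @return An `asymmetry_curve` tibble: `distance`, `cumulative_left`,
#'   `cumulative_right`, `log2_ratio` (right over left).
#' @export
cumulative_asymmetry <- function(profile, max_distance = NULL, step = 10000,
                                 exclusion_radius = 10000) {
  vp <- attr(profile, "viewpoint")
  rows <- profile$chrom == vp$chrom & !profile$masked
  mid <- profile$midpoint[rows]
  val <- profile$normalized[rows]
  if (all(is.na(val))) abort("normalize the profile first")
  offset <- mid - vp$position
  if (is.null(max_distance)) {
    max_distance <- max(abs(c(offset, 0))) + step
  }
  grid <- seq(0, max_distance, by = step)
  cum_side <- function(side) {
    sel <- abs(offset) > exclusion_radius &
      (if (side == "left") offset < 0 else offset > 0)
    vapply(grid, function(d) sum(val[sel & abs(offset) <= d]), numeric(1))
  }
  left <- cum_side("left")
  right <- cum_side("right")
  structure(
    tibble(distance = grid, cumulative_left = left, cumulative_right = right,
           log2_ratio = log2((right + 1) / (left + 1))),
    class = c("asymmetry_curve", class(tibble())),
    viewpoint = vp, exclusion_radius = exclusion_radius
  )
}

#' Fraction of normalized signal in named regions
#'
#' Percentage of the normalized 4C signal (unmasked fragments, midpoint rule)
#' falling in each of a set of non-overlapping named regions — e.g. a
#' rearranged span and its two flanking windows. Percentages are relative to
#' the total over the listed regions and sum to 100.
#'
#' @param profile a normalized, viewpoint-masked `vp_profile`.
#' @param regions tibble with `name`, `start`, `end` (plus optional `chrom`).
#' @return A `region_summary` tibble: `name`, `start`, `end`, `signal`,
#'   `percent`.
#' @export
region_fraction <- function(profile, regions) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (nrow(regions) > 1) {
    o <- order(regions$start)
    if (any(regions$start[o][-1] < regions$end[o][-nrow(regions)])) {
      abort("regions must be non-overlapping")
    }
  }
  vp <- attr(profile, "viewpoint")
  keep <- profile$chrom == vp$chrom & !profile$masked
  sig <- vapply(seq_len(nrow(regions)), function(i) {
    sel <- keep & profile$midpoint >= regions$start[i] &
      profile$midpoint < regions$end[i]
    sum(profile$normalized[sel])
  }, numeric(1))
  total <- sum(sig)
  if (total <= 0) abort("no signal over the listed regions")
  structure(
    tibble(name = regions$name, start = regions$start, end = regions$end,
           signal = sig, percent = 100 * sig / total),
    class = c("region_summary", class(tibble())),
    exclusion = "masked fragments excluded"
  )
}

#' Default region set around a rearranged span
#'
#' Builds the three-region summary used to quantify signal redistribution
#' across an engineered allele: the rearranged span itself plus flanking
#' windows of `flank` bp (400 kb by default) on both sides, clipped to the
#' chromosome.
#'
#' @param span tibble with `start`, `end` of the rearranged interval, or an
#'   `allele_map` (the span of its non-identity blocks is used).
#' @param flank flank width in bp.
#' @param chrom_length clip bound.
#' @return Regions tibble for [region_fraction()].
#' @export
flanking_regions <- function(span, flank = 400000, chrom_length = Inf) {
  if (inherits(span, "allele_map")) {
    rearranged <- span[span$orientation == "-" | span$copy_index > 0, ]
    if (nrow(rearranged) == 0) {
      # deletions leave no marked block; use the gap between identity blocks
      gaps <- span$ref_start[-1] - span$ref_end[-nrow(span)]
      i <- which(gaps > 0)
      if (length(i) == 0) abort("identity map has no rearranged span")
      span <- tibble(start = span$ref_end[i[1]], end = span$ref_start[i[1] + 1])
    } else {
      span <- tibble(start = min(rearranged$ref_start),
                     end = max(rearranged$ref_end))
    }
  }
  s <- span$start[1]; e <- span$end[1]
  tibble(
    name = c("left_flank", "rearranged", "right_flank"),
    start = c(max(0, s - flank), s, e),
    end = c(s, e, min(chrom_length, e + flank))
  )
}

#' Compare primary interaction domains between reference and rearranged allele
#'
#' Lifts each reference-allele domain into the rearranged allele's coordinates
#' and reports per-viewpoint boundary shifts, the inter-viewpoint domain
#' Jaccard in each allele, and the transition-zone relation in each allele. A
#' domain edge falling in a deleted interval is snapped to the nearest
#' surviving position and flagged.
#'
#' @param domains_ref list (or bound rows) of `interaction_domain`s called on
#'   the reference; the first two viewpoints are used for the pairwise
#'   statistics.
#' @param domains_alt matching domains called on the rearranged allele, in
#'   allele coordinates.
#' @param map the allele's [build_allele_map()].
#' @param merge_fraction passed to [detect_transition_zone()].
#' @return An `allele_comparison` list with `shifts` (per-viewpoint tibble:
#'   lifted reference bounds, allele bounds, signed start/end shifts in bp,
#'   `snapped` flag) and `overlap` (per-allele tibble: inter-viewpoint
#'   `jaccard` and TZ `relation`).
#' @export
compare_alleles <- function(domains_ref, domains_alt, map,
                            merge_fraction = 0.5) {
  dref <- bind_rows(domains_ref)
  dalt <- bind_rows(domains_alt)
  stopifnot(nrow(dref) == nrow(dalt), all(dref$viewpoint == dalt$viewpoint))

  lift_edge <- function(p) {
    res <- lift_point(map, p)
    res <- res[res$copy_index %in% c(0L, NA), ]
    if (res$deleted[1]) {
      # snap to the nearest surviving reference position
      surv <- map[map$copy_index == 0, ]
      cand <- c(surv$ref_start, surv$ref_end - 1)
      p2 <- cand[which.min(abs(cand - p))]
      list(image = lift_point(map, p2)$image[1], snapped = TRUE)
    } else {
      list(image = res$image[1], snapped = FALSE)
    }
  }

  shifts <- purrr::map_dfr(seq_len(nrow(dref)), function(i) {
    s <- lift_edge(dref$start[i])
    e <- lift_edge(dref$end[i] - 1) # last covered base
    lo <- min(s$image, e$image)
    hi <- max(s$image, e$image) + 1
    tibble(
      viewpoint = dref$viewpoint[i],
      ref_start_lifted = lo, ref_end_lifted = hi,
      alt_start = dalt$start[i], alt_end = dalt$end[i],
      shift_start = dalt$start[i] - lo, shift_end = dalt$end[i] - hi,
      snapped = s$snapped || e$snapped
    )
  })

  tz_of <- function(d) detect_transition_zone(d[1, ], d[2, ], merge_fraction)
  overlap <- bind_rows(
    mutate(tz_of(dref)[, c("jaccard", "relation")], allele = "reference"),
    mutate(tz_of(dalt)[, c("jaccard", "relation")], allele = "alternate")
  )[, c("allele", "jaccard", "relation")]

  structure(list(shifts = shifts, overlap = overlap),
            class = "allele_comparison")
}

#' @export
print.allele_comparison <- function(x, ...) {
  cat("<allele_comparison>\n$shifts\n")
  print(x$shifts)
  cat("$overlap\n")
  print(x$overlap)
  invisible(x)
}

#' @export
tidy.allele_comparison <- function(x, ...) x$shifts

#' @export
glance.allele_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$overlap, names_from = "allele",
                     values_from = c("jaccard", "relation"))
}
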