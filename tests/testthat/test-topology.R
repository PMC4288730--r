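dom <- function(start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

test_that("transition-zone detection classifies overlap, gap and merged", {
  tz <- detect_transition_zone(dom(0, 5e5), dom(4.8e5, 9e5))
  expect_equal(tz$relation, "overlap")
  expect_equal(c(tz$start, tz$end), c(4.8e5, 5e5))
  expect_equal(tz$width, 20000)
  # width additivity: |A u B| = |A| + |B| - width
  expect_equal(9e5 - 0, 5e5 + (9e5 - 4.8e5) - tz$width)

  gap <- detect_transition_zone(dom(0, 4e5), dom(5e5, 9e5))
  expect_equal(gap$relation, "gap")
  expect_equal(c(gap$start, gap$end), c(4e5, 5e5))

  merged <- detect_transition_zone(dom(0, 8e5), dom(1e5, 9e5))
  expect_equal(merged$jaccard, 7 / 9)
  expect_equal(merged$relation, "merged")

  expect_equal(detect_transition_zone(dom(1, 2), dom(1, 2))$relation, "merged")
  expect_error(detect_transition_zone(dom(0, 1), dom(0, 1, "chr2")),
               "one chromosome")
})

make_profile <- function(map, values, vp_pos, mask_radius = NULL) {
  vp <- viewpoint_table("v", map$chrom[1], vp_pos, "ACG")
  prof <- build_profile(map, values, vp)
  prof$normalized <- as.numeric(values)
  if (!is.null(mask_radius)) prof <- mask_viewpoint(prof, mask_radius)
  prof
}

test_that("cumulative asymmetry sums each side beyond the exclusion radius", {
  # fragments with midpoints -30, -20, 0, +20, +30 kb from the viewpoint
  map <- fragment_map(c(0, 15, 25, 35, 65, 75, 85) * 1000,
                      c(15, 25, 35, 65, 75, 85, 100) * 1000)
  prof <- make_profile(map, c(0, 4, 3, 99, 2, 1, 0), 50000)
  cur <- cumulative_asymmetry(prof, max_distance = 40000, step = 5000)
  at <- function(d, col) cur[[col]][cur$distance == d]
  expect_equal(at(25000, "cumulative_left"), 3)
  expect_equal(at(25000, "cumulative_right"), 2)
  expect_equal(at(5000, "cumulative_left"), 0) # inside the exclusion radius
  expect_equal(at(35000, "cumulative_left"), 7)
  expect_equal(at(35000, "cumulative_right"), 3)
  expect_true(all(diff(cur$cumulative_left) >= 0))
  expect_true(all(diff(cur$cumulative_right) >= 0))
})

test_that("mirror-symmetric profiles give identical left and right curves", {
  map <- uniform_map(41)
  vals <- c(20:1, 50, 1:20)
  prof <- make_profile(map, vals, 20500, mask_radius = 10000)
  cur <- cumulative_asymmetry(prof, step = 1000)
  expect_equal(cur$cumulative_left, cur$cumulative_right)
  # and the two sides exhaust the unmasked signal at full distance
  expect_equal(max(cur$cumulative_left + cur$cumulative_right),
               sum(prof$normalized[!prof$masked]))

  lopsided <- make_profile(map, c(20:1, 50, rep(0, 20)), 20500,
                           mask_radius = 10000)
  cur2 <- cumulative_asymmetry(lopsided, step = 1000)
  expect_true(all(cur2$cumulative_right == 0))
  expect_true(max(cur2$cumulative_left) > 0)
})

test_that("region fractions form a percentage partition", {
  map <- uniform_map(40)
  prof <- make_profile(map, rep(5, 40), 500, mask_radius = 0)

  whole <- region_fraction(prof, tibble::tibble(name = "all", start = 0,
                                                end = 4e4))
  expect_equal(whole$percent, 100)

  halves <- region_fraction(prof, tibble::tibble(
    name = c("l", "r"), start = c(0, 2e4), end = c(2e4, 4e4)))
  expect_equal(halves$percent, c(50, 50), tolerance = 0.11) # vp fragment masked

  set.seed(13)
  prof2 <- make_profile(map, runif(40, 1, 9), 500, mask_radius = 0)
  cuts <- c(0, sort(sample(seq(1000, 39000, 1000), 3)), 40000)
  parts <- tibble::tibble(name = letters[1:4], start = cuts[1:4], end = cuts[2:5])
  rf <- region_fraction(prof2, parts)
  expect_equal(sum(rf$percent), 100, tolerance = 1e-6)

  # percentages invariant under uniform rescaling of the profile
  prof3 <- prof2
  prof3$normalized <- prof3$normalized * 37.5
  expect_equal(region_fraction(prof3, parts)$percent, rf$percent)

  expect_error(region_fraction(prof, tibble::tibble(
    name = c("a", "b"), start = c(0, 1e4), end = c(2e4, 3e4))), "non-overlapping")
})

test_that("default flanking regions are 400 kb on each side of the span", {
  r <- flanking_regions(tibble::tibble(start = 6e5, end = 8e5),
                        chrom_length = 2e6)
  expect_equal(r$name, c("left_flank", "rearranged", "right_flank"))
  expect_equal(r$end - r$start, c(4e5, 2e5, 4e5))
  expect_equal(r$start, c(2e5, 6e5, 8e5))

  inv_map <- build_allele_map(rearrangement("inversion", 6e5, 8e5), 2e6)
  expect_equal(flanking_regions(inv_map, chrom_length = 2e6), r)
  del_map <- build_allele_map(rearrangement("deletion", 6e5, 8e5), 2e6)
  expect_equal(flanking_regions(del_map, chrom_length = 2e6)$name[2],
               "rearranged")
})

test_that("identity alleles compare with zero boundary shifts", {
  a <- tibble::tibble(viewpoint = "vpA", chrom = "c", start = 100, end = 500)
  b <- tibble::tibble(viewpoint = "vpB", chrom = "c", start = 450, end = 900)
  id <- build_allele_map(NULL, 1000)
  cmp <- compare_alleles(list(a, b), list(a, b), id)
  expect_equal(cmp$shifts$shift_start, c(0, 0))
  expect_equal(cmp$shifts$shift_end, c(0, 0))
  expect_false(any(cmp$shifts$snapped))
  ov <- glance(cmp)
  expect_equal(ov$jaccard_reference, ov$jaccard_alternate)
})

test_that("domain edges deleted by the allele are snapped and flagged", {
  a <- tibble::tibble(viewpoint = "vpA", chrom = "c", start = 100, end = 500)
  b <- tibble::tibble(viewpoint = "vpB", chrom = "c", start = 450, end = 900)
  del <- build_allele_map(rearrangement("deletion", 400, 600), 1000)
  alt_a <- tibble::tibble(viewpoint = "vpA", chrom = "c", start = 100, end = 400)
  alt_b <- tibble::tibble(viewpoint = "vpB", chrom = "c", start = 400, end = 700)
  cmp <- compare_alleles(list(a, b), list(alt_a, alt_b), del)
  expect_true(cmp$shifts$snapped[1]) # end 500 fell inside the deletion
  expect_equal(cmp$shifts$ref_end_lifted[1], 400)
})
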