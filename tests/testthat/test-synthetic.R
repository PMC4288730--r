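test_that("fragment-map simulation is seeded and respects the mean length", {
  spec <- small_locus()
  m1 <- simulate_fragment_map(spec, seed = 4)
  m2 <- simulate_fragment_map(spec, seed = 4)
  expect_identical(m1$start, m2$start)
  expect_identical(m1$blind, m2$blind)
  expect_false(identical(m1$start, simulate_fragment_map(spec, seed = 5)$start))

  expect_equal(nrow(m1), round(spec$chrom_length / spec$mean_fragment_length))
  expect_equal(sum(m1$length), spec$chrom_length)

  one <- synthetic_locus_spec(
    chrom_length = 1e5, mean_fragment_length = 1e5,
    domain_a = c(1e4, 5.1e4), domain_b = c(4.9e4, 9e4), tz = c(4.9e4, 5.1e4),
    viewpoints = viewpoint_table("vpA", "chrS", 3e4, "ACGT"))
  expect_equal(nrow(simulate_fragment_map(one, seed = 1)), 1)
})

test_that("realized sequences reproduce the map under digestion", {
  spec <- small_locus()
  map <- simulate_fragment_map(spec, seed = 3, with_sequence = TRUE)
  s <- attr(map, "sequence")
  expect_equal(nchar(s), spec$chrom_length)
  re <- annotate_secondary(digest(s, chrom = spec$chrom), s)
  expect_equal(re$start, map$start)
  expect_equal(re$end, map$end)
  expect_equal(re$blind, map$blind)
})

test_that("expected intensity follows the closed-form contact model", {
  # custom map with fragment midpoints exactly at the probed distances
  spec <- synthetic_locus_spec(
    chrom_length = 4e5, domain_a = c(0, 2e5), domain_b = c(2e5, 4e5),
    tz = c(199000, 201000), gamma = 0.2, alpha = 1,
    peaks = tibble::tibble(position = numeric(), amplitude = numeric(),
                           width = numeric(), tissue = character()),
    viewpoints = viewpoint_table("vpA", "chrS", 150000, "ACGT"))
  map <- fragment_map(c(0, 149, 151, 249, 251, 399) * 1000,
                      c(149, 151, 249, 251, 399, 400) * 1000, chrom = "chrS")
  mu <- expected_intensity(spec, map, "vpA")
  expect_equal(mu[2], spec$beta) # d = 0, same domain, no peaks
  expect_equal(mu[4], 0.2 / 101) # cross-domain at d = 100 kb

  # symmetry: equal distance on both sides of a mid-domain viewpoint
  sym <- fragment_map(c(0, 129, 131, 169, 171, 200) * 1000,
                      c(129, 131, 169, 171, 200, 400) * 1000, chrom = "chrS")
  mus <- expected_intensity(spec, sym, "vpA")
  expect_equal(mus[2], mus[4]) # midpoints 20 kb left and right, d equal

  # monotone decay within one domain when no peaks are active
  grid <- fragment_map(seq(0, 1.9e5, 1e4), seq(1e4, 2e5, 1e4), chrom = "chrS")
  mug <- expected_intensity(spec, grid, "vpA")
  d <- abs((grid$start + grid$end) / 2 - 150000)
  expect_true(all(diff(mug[order(d)]) <= 0))
})

test_that("the transition zone contacts both sides more than the domains contact each other", {
  spec <- small_locus() # TZ at [98k, 102k), viewpoints at 70 kb and 130 kb
  map <- fragment_map(c(0, 98, 102, 128, 132, 160) * 1000,
                      c(98, 102, 128, 132, 160, 200) * 1000, chrom = "chrS")
  mid <- (map$start + map$end) / 2
  tz_i <- which(mid >= 98000 & mid < 102000) # fragment centered in the TZ
  for (v in c("vpA", "vpB")) {
    mu <- expected_intensity(spec, map, v)
    vp_pos <- spec$viewpoints$position[spec$viewpoints$name == v]
    d_tz <- abs(mid[tz_i] - vp_pos)
    # any cross-domain fragment at least as close as the TZ is contacted less
    cross <- if (v == "vpA") mid >= 102000 else mid < 98000
    closer <- cross & abs(mid - vp_pos) >= d_tz
    expect_true(all(mu[tz_i] > mu[closer]))
  }
})

test_that("counts are seeded, depth-exact and converge to the model", {
  spec <- small_locus()
  map <- simulate_fragment_map(spec, seed = 2)
  a <- simulate_counts(spec, map, "vpA", seed = 7)
  b <- simulate_counts(spec, map, "vpA", seed = 7)
  expect_identical(a$counts, b$counts)
  expect_equal(sum(a$counts), spec$library_size)
  expect_equal(a$truth$boundaries, c(40000, 102000))

  # law of large numbers at dispersion -> 0: empirical fractions match mu
  spec0 <- small_locus(library_size = 1e6, dispersion = 0)
  c0 <- simulate_counts(spec0, map, "vpA", seed = 9)
  mu <- expected_intensity(spec0, map, "vpA")
  expect_lt(max(abs(c0$counts / 1e6 - mu / sum(mu))), 0.01)
})

test_that("each viewpoint is enriched in its own domain at matched distances", {
  spec <- small_locus()
  map <- simulate_fragment_map(spec, seed = 2)
  mid <- (map$start + map$end) / 2
  cnt <- simulate_counts(spec, map, "vpA", seed = 3)$counts
  d <- abs(mid - 70000)
  own <- mid >= 40000 & mid < 98000
  other <- mid >= 102000 & mid < 160000
  bins <- cut(d, seq(0, 2e5, 2e4))
  for (b in levels(bins)) {
    sel <- bins == b
    if (any(sel & own) && any(sel & other)) {
      expect_gt(mean(cnt[sel & own]), mean(cnt[sel & other]))
    }
  }
})

test_that("simulated reads round-trip through demultiplex and counting", {
  spec <- small_locus(library_size = 2e4)
  map <- simulate_fragment_map(spec, seed = 6, with_sequence = TRUE)
  ca <- simulate_counts(spec, map, "vpA", seed = 1)$counts
  cb <- simulate_counts(spec, map, "vpB", seed = 2)$counts
  rd <- simulate_reads(spec, map, list(vpA = ca, vpB = cb), seed = 3)

  expect_equal(nrow(rd$reads), sum(ca) + sum(cb))
  tag_len <- nchar(spec$viewpoints$tag[match(rd$truth$viewpoint,
                                             spec$viewpoints$name)])
  expect_true(all(nchar(rd$reads$seq) <= tag_len + spec$read_length))

  dx <- demultiplex(rd$reads, spec$viewpoints)
  expect_equal(mean(!is.na(dx$viewpoint)), 1) # error-free tags: 100% assigned
  j <- dplyr::inner_join(dx, rd$truth, by = "name", suffix = c("", ".true"))
  expect_equal(j$viewpoint, j$viewpoint.true)

  for (v in c("vpA", "vpB")) {
    pos <- rd$truth$pos[rd$truth$viewpoint == v]
    expect_equal(as.integer(count_per_fragment(map, pos)),
                 if (v == "vpA") ca else cb)
  }

  none <- simulate_reads(spec, map, list(vpA = integer(nrow(map))), seed = 1)
  expect_equal(nrow(none$reads), 0)
})

test_that("allele re-expression re-derives domains from the lifted TZ", {
  spec <- small_locus()

  idm <- simulate_allele(spec, NULL, "wt")
  expect_equal(idm$domain_a, spec$domain_a)
  expect_equal(idm$domain_b, spec$domain_b)
  expect_equal(idm$viewpoints$position, spec$viewpoints$position)

  # deletion covering the TZ: one merged domain across the outer limits
  del <- simulate_allele(spec, rearrangement("deletion", 90000, 110000), "del")
  expect_equal(del$chrom_length, 180000)
  expect_equal(del$domain_a, del$domain_b)
  expect_equal(del$domain_a, c(40000, 140000))
  expect_equal(del$viewpoints$position, c(70000, 110000))

  # inversion carrying the heart enhancer across the TZ
  inv <- simulate_allele(spec, rearrangement("inversion", 80000, 120000), "inv")
  expect_equal(inv$chrom_length, spec$chrom_length) # balanced
  enh <- inv$peaks$position[inv$peaks$tissue == "heart"]
  expect_equal(enh, 80000 + (120000 - 1 - 112000)) # 87999
  expect_true(enh >= inv$domain_a[1] && enh < inv$domain_a[2])
  expect_error(simulate_allele(spec, rearrangement("deletion", 60000, 80000)),
               "viewpoint")
})
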