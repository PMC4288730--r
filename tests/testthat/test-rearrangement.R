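test_that("allele maps realize single events with correct blocks and length", {
  id <- build_allele_map(NULL, 100)
  expect_equal(nrow(id), 1)
  expect_equal(id$ref_start, 0)
  expect_equal(id$ref_end, 100)
  expect_equal(id$orientation, "+")
  expect_equal(attr(id, "allele_length"), 100)

  inv <- build_allele_map(rearrangement("inversion", 20, 60), 100)
  expect_equal(inv$ref_start, c(0, 20, 60))
  expect_equal(inv$ref_end, c(20, 60, 100))
  expect_equal(inv$orientation, c("+", "-", "+"))
  expect_equal(attr(inv, "allele_length"), 100) # balanced

  del <- build_allele_map(rearrangement("deletion", 20, 60), 100)
  expect_equal(del$ref_start, c(0, 60))
  expect_equal(attr(del, "allele_length"), 60)
  # brute-force confirmation of the deletion block structure
  orc <- label_oracle(rearrangement("deletion", 20, 60), 100)
  expect_equal(length(orc$labels), 60)
  expect_equal(orc$labels[21], 60) # base after the breakpoint

  dup <- build_allele_map(rearrangement("tandem_duplication", 20, 60), 100)
  expect_equal(attr(dup, "allele_length"), 140)
  expect_equal(dup$copy_index, c(0L, 0L, 1L, 0L))
})

test_that("invalid allele definitions are rejected with diagnostics", {
  two <- dplyr::bind_rows(rearrangement("deletion", 10, 30),
                          rearrangement("inversion", 20, 50))
  expect_error(build_allele_map(two, 100), "overlapping")
  expect_error(build_allele_map(rearrangement("deletion", 50, 120), 100),
               "exceeds chromosome length")
  expect_error(lift_point(build_allele_map(NULL, 100), 100), "outside")
})

test_that("lift_point matches the closed-form block arithmetic", {
  expect_equal(lift_point(build_allele_map(NULL, 100), 42)$image, 42)

  inv <- build_allele_map(rearrangement("inversion", 20, 60), 100)
  r <- lift_point(inv, 25)
  expect_equal(r$image, 54) # 20 + (60 - 1 - 25)
  expect_equal(r$orientation, "-")

  del <- build_allele_map(rearrangement("deletion", 20, 60), 100)
  r <- lift_point(del, 25)
  expect_true(r$deleted)
  expect_true(is.na(r$image))
})

test_that("lift_point agrees with the per-base labeling oracle", {
  cases <- list(
    rearrangement("inversion", 200, 900),
    rearrangement("deletion", 100, 350),
    rearrangement("tandem_duplication", 400, 700),
    dplyr::bind_rows(rearrangement("deletion", 50, 150),
                     rearrangement("inversion", 300, 800)),
    dplyr::bind_rows(rearrangement("tandem_duplication", 100, 200),
                     rearrangement("deletion", 500, 600),
                     rearrangement("inversion", 700, 950))
  )
  L <- 1000
  for (events in cases) {
    map <- build_allele_map(events, L)
    orc <- label_oracle(events, L)
    expect_equal(attr(map, "allele_length"), length(orc$labels))
    lifted <- lift_point(map, 0:(L - 1))
    for (p in 0:(L - 1)) {
      want <- which(orc$labels == p) - 1L
      got <- lifted[lifted$position == p, ]
      if (length(want) == 0) {
        expect_true(all(got$deleted))
      } else {
        expect_setequal(got$image, want)
        expect_equal(sort(unique(orc$strand[want + 1])),
                     sort(unique(got$orientation)))
      }
    }
  }
})

test_that("non-deleted positions round-trip ref -> allele -> ref", {
  events <- dplyr::bind_rows(rearrangement("deletion", 100, 300),
                             rearrangement("inversion", 400, 800))
  map <- build_allele_map(events, 1000)
  fwd <- lift_point(map, 0:999)
  ok <- fwd[!fwd$deleted & fwd$copy_index == 0, ]
  back <- lift_point(map, ok$image, direction = "allele2ref")
  expect_equal(back$image, ok$position)
})

test_that("disjoint events compose: joint map equals sequential application", {
  e1 <- rearrangement("deletion", 100, 200)
  e2 <- rearrangement("inversion", 500, 800)
  joint <- build_allele_map(dplyr::bind_rows(e1, e2), 1000)
  m1 <- build_allele_map(e1, 1000)
  # re-express the second event in the first allele's coordinates
  img <- lift_interval(m1, 500, 800)
  m2 <- build_allele_map(rearrangement("inversion", img$start, img$end),
                         attr(m1, "allele_length"))
  p <- setdiff(0:999, 100:199)
  via_joint <- lift_point(joint, p)
  step1 <- lift_point(m1, p)
  via_seq <- lift_point(m2, step1$image)
  expect_equal(via_joint$image, via_seq$image)
  expect_equal(via_joint$orientation, via_seq$orientation)
})

test_that("lift_interval splits at breakpoints and drops deletions", {
  expect_equal(lift_interval(build_allele_map(NULL, 100), 10, 20)$start, 10)

  inv <- build_allele_map(rearrangement("inversion", 20, 60), 100)
  r <- lift_interval(inv, 15, 25)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(15, 55))
  expect_equal(r$end, c(20, 60))
  expect_equal(r$orientation, c("+", "-"))

  del <- build_allele_map(rearrangement("deletion", 20, 60), 100)
  expect_equal(nrow(lift_interval(del, 25, 30)), 0)
  # partial overlap: only the surviving piece comes back
  r <- lift_interval(del, 10, 30)
  expect_equal(sum(r$end - r$start), 10)
})

test_that("reorder_track conserves values and handles breakpoints", {
  track <- tibble::tibble(start = seq(0, 90, 10), end = seq(10, 100, 10),
                          value = 1:10)
  id <- build_allele_map(NULL, 100)
  expect_equal(reorder_track(id, track)$value, track$value)

  inv <- build_allele_map(rearrangement("inversion", 20, 60), 100)
  r <- reorder_track(inv, track)
  expect_setequal(r$value, track$value) # balanced inversion conserves multiset
  expect_equal(r$value[r$start >= 20 & r$end <= 60], c(6, 5, 4, 3)) # reversed

  del <- build_allele_map(rearrangement("deletion", 20, 60), 100)
  expect_equal(nrow(reorder_track(del, track)), 6) # 4 fragments deleted

  # a track element straddling a breakpoint is split and flagged, or rejected
  straddle <- tibble::tibble(start = 15, end = 25, value = 7)
  r <- reorder_track(inv, straddle)
  expect_true(all(r$split))
  expect_equal(r$value, c(7, 7))
  expect_error(reorder_track(inv, straddle, strict = TRUE), "breakpoint")
})

test_that("YAML allele configs convert published 1-based coordinates", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "reference: {chrom: chr2, length: 1000000}",
    "alleles:",
    "  del1:",
    "    - {kind: deletion, start: 450001, end: 550000}",
    "  INV-M:",
    "    - {kind: inversion, start: 400001, end: 600000}"
  ), cfg)
  alleles <- read_rearrangement_config(cfg)
  expect_named(alleles, c("del1", "INV-M"))
  expect_equal(alleles$del1$start, 450000) # 0-based half-open
  expect_equal(alleles$del1$end, 550000)
  expect_equal(alleles$`INV-M`$kind, "inversion")
})
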