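#' Specify a synthetic two-domain locus with a transition zone
#'
#' Generative model of the contact structure the package is designed to
#' analyse: a ~0.6-Mb locus split into two contact domains whose overlap is a
#' narrow transition zone (TZ) contacting both sides, power-law decay of 4C
#' signal with distance from the viewpoint, tissue-specific enhancer contact
#' peaks, and overdispersed fragment counts at fixed sequencing depth. The
#' expected 4C intensity of fragment at distance `d` kb from the viewpoint is
#'
#'   `mu = (1 + d)^(-alpha) * D * E`
#'
#' with `D = beta` for fragments in the viewpoint's domain, `gamma` across the
#' TZ, and `tau * (beta + gamma)/2` when either end lies in the TZ itself (the
#' TZ contacts both flanks); `E = 1 +` the Gaussian-kernel sum of enhancer
#' peaks active in the profiled tissue.
#'
#' Defaults plant a 1-Mb chromosome, ~3-kb fragments, domains
#' `[200k, 510k)` and `[490k, 810k)` overlapping in a 20-kb TZ, and two
#' viewpoints 300 kb apart straddling the TZ — geometry echoing a two-gene
#' developmental locus with promoter viewpoints.
#'
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param mean_fragment_length mean restriction-fragment length (bp).
#' @param domain_a,domain_b,tz structural intervals, `c(start, end)` 0-based
#'   half-open; the TZ should be the domain overlap (or the gap between them).
#' @param alpha distance-decay exponent (> 0).
#' @param beta within-domain contact factor (> 1).
#' @param gamma cross-domain factor (in (0, 1)).
#' @param tau TZ bidirectional-contact factor (>= 1).
#' @param peaks tibble of enhancer peaks: `position`, `amplitude`, `width`
#'   (Gaussian sd, bp), `tissue`.
#' @param dispersion overdispersion `phi` of the gamma-mixture (0 = pure
#'   multinomial).
#' @param library_size reads per library.
#' @param viewpoints a [viewpoint_table()]; tissue labels select which peaks
#'   are active.
#' @param read_length bases sampled after the barcode tag in simulated reads.
#' @return A `locus_spec` list.
#' @export
synthetic_locus_spec <- function(
    chrom = "chrS", chrom_length = 1e6,
    mean_fragment_length = 3000,
    domain_a = c(200000, 510000),
    domain_b = c(490000, 810000),
    tz = c(490000, 510000),
    alpha = 1, beta = 5, gamma = 0.2, tau = 2,
    peaks = tibble(position = c(280000, 560000), amplitude = c(2, 2),
                   width = c(5000, 5000), tissue = c("brain", "heart")),
    dispersion = 0.1, library_size = 1e6,
    viewpoints = viewpoint_table(c("vpA", "vpB"), chrom, c(350000, 650000),
                                 c("ACGT", "TGCAC"), tissue = "brain"),
    read_length = 36) {
  stopifnot(alpha > 0, beta > 1, gamma > 0, gamma < 1, tau >= 1,
            dispersion >= 0, library_size >= 1,
            mean_fragment_length >= 50)
  for (iv in list(domain_a, domain_b, tz)) {
    check_interval(iv[1], iv[2], chrom_length)
  }
  stopifnot(all(viewpoints$position >= 0),
            all(viewpoints$position < chrom_length))
  structure(
    list(chrom = chrom, chrom_length = chrom_length,
         mean_fragment_length = mean_fragment_length,
         domain_a = domain_a, domain_b = domain_b, tz = tz,
         alpha = alpha, beta = beta, gamma = gamma, tau = tau,
         peaks = peaks, dispersion = dispersion, library_size = library_size,
         viewpoints = viewpoints, read_length = read_length),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf(
    "<locus_spec> %s: %s bp, domains [%s) / [%s), TZ [%s), %d viewpoint(s)\n",
    x$chrom, format(x$chrom_length, big.mark = ","),
    paste(x$domain_a, collapse = ","), paste(x$domain_b, collapse = ","),
    paste(x$tz, collapse = ","), nrow(x$viewpoints)
  ))
  invisible(x)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

in_interval <- function(pos, iv) pos >= iv[1] & pos < iv[2]

#' Simulate a restriction-fragment map (optionally with a realizable sequence)
#'
#' Draws `round(chrom_length / mean_fragment_length)` fragments with
#' exponential-like length variation around the mean (minimum 30 bp). With
#' `with_sequence = TRUE`, a nucleotide sequence is constructed that
#' reproduces the map bit-exactly under [digest()]: the primary motif (CATG)
#' is planted exactly at each internal boundary and scrubbed everywhere else,
#' and one secondary motif (GATC) is planted inside each non-blind fragment
#' (15% of fragments are blind by default, a typical genome-wide rate).
#'
#' @param spec a [synthetic_locus_spec()].
#' @param seed integer seed; identical seeds give identical maps.
#' @param with_sequence also realize a sequence (attribute `"sequence"`).
#' @param blind_fraction fraction of fragments without a secondary site.
#' @return A `fragment_map` with `has_secondary_site`/`blind` filled.
#' @export
simulate_fragment_map <- function(spec, seed = 1, with_sequence = FALSE,
                                  blind_fraction = 0.15) {
  with_seed(seed, {
    L <- spec$chrom_length
    n <- max(1L, round(L / spec$mean_fragment_length))
    lens <- rexp(n)
    bounds <- round(L * cumsum(lens) / sum(lens))
    bounds <- bounds[-length(bounds)] # interior cuts only
    keep <- c()
    last <- 0
    for (b in bounds) { # enforce a 30-bp minimum fragment length
      if (b - last >= 30 && L - b >= 30) {
        keep <- c(keep, b)
        last <- b
      }
    }
    bounds <- c(0, keep, L)
    map <- tibble(
      chrom = spec$chrom,
      start = bounds[-length(bounds)], end = bounds[-1],
      index = seq_len(length(bounds) - 1L) - 1L
    )
    map$length <- map$end - map$start
    map$blind <- runif(nrow(map)) < blind_fraction
    map$has_secondary_site <- !map$blind
    map <- new_fragment_map(map, primary_motif = "CATG",
                            secondary_motif = "GATC", chrom_length = L)
    if (with_sequence) {
      attr(map, "sequence") <- realize_sequence(map)
    }
    map
  })
}

# build a sequence whose digestion reproduces `map` exactly:
# CATG only at internal cut sites, GATC inside non-blind fragments only
realize_sequence <- function(map, primary = "CATG", secondary = "GATC") {
  L <- attr(map, "chrom_length")
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cuts <- map$end[-nrow(map)]
  planted_catg <- cuts - 4 # 0-based motif starts
  mids <- floor((map$start + map$end) / 2)
  planted_gatc <- mids[!map$blind] - 2
  protected <- c(
    unlist(lapply(planted_catg, function(s) s:(s + 3))),
    unlist(lapply(planted_gatc, function(s) s:(s + 3)))
  ) + 1 # 1-based protected base positions

  plant <- function(starts, motif) {
    for (s in starts) bases[(s + 1):(s + 4)] <<- strsplit(motif, "")[[1]]
  }
  plant(planted_catg, primary)
  plant(planted_gatc, secondary)

  blind_of <- function(pos0) { # blind status of fragment containing pos0
    map$blind[findInterval(pos0, map$start)]
  }
  for (iter in 1:50) {
    seq_str <- paste(bases, collapse = "")
    bad_catg <- setdiff(find_sites(seq_str, primary), planted_catg)
    gatc <- setdiff(find_sites(seq_str, secondary), planted_gatc)
    # stray GATC is only a problem inside a blind fragment (it would
    # un-blind it); boundary-straddling or in non-blind fragments is harmless
    gatc_end <- gatc + 4
    f <- findInterval(gatc, map$start)
    inside <- gatc >= map$start[f] & gatc_end <= map$end[f]
    bad_gatc <- gatc[inside & map$blind[f]]
    bad <- c(bad_catg, bad_gatc)
    if (length(bad) == 0) break
    for (s in bad) {
      cand <- setdiff((s + 1):(s + 4), protected)
      i <- cand[length(cand)] # mutate the last unprotected base
      bases[i] <- setdiff(c("A", "C", "G", "T"), bases[i])[
        sample.int(3, 1)]
    }
  }
  paste(bases, collapse = "")
}

#' Expected 4C intensity of each fragment for one viewpoint
#'
#' Deterministic evaluation of the locus contact model (see
#' [synthetic_locus_spec()]) at every fragment midpoint. Domain membership of
#' fragments and viewpoint is midpoint-based; distances are in kb.
#'
#' @param spec a `locus_spec`.
#' @param map a `fragment_map` on the spec's chromosome.
#' @param viewpoint viewpoint name (row of `spec$viewpoints`).
#' @return Numeric vector of expected intensities, one per fragment.
#' @export
expected_intensity <- function(spec, map, viewpoint) {
  vp <- spec$viewpoints[spec$viewpoints$name == viewpoint, ]
  if (nrow(vp) != 1) abort(sprintf("unknown viewpoint '%s'", viewpoint))
  mid <- interval_mid(map$start, map$end)
  d_kb <- abs(mid - vp$position) / 1000

  f_in_a <- in_interval(mid, spec$domain_a)
  f_in_b <- in_interval(mid, spec$domain_b)
  f_in_tz <- in_interval(mid, spec$tz)
  v_in_a <- in_interval(vp$position, spec$domain_a)
  v_in_b <- in_interval(vp$position, spec$domain_b)
  v_in_tz <- in_interval(vp$position, spec$tz)

  D <- ifelse(f_in_tz | v_in_tz, spec$tau * (spec$beta + spec$gamma) / 2,
    ifelse((f_in_a & v_in_a) | (f_in_b & v_in_b), spec$beta, spec$gamma)
  )
  E <- rep(1, nrow(map))
  active <- spec$peaks[spec$peaks$tissue == vp$tissue, ]
  for (i in seq_len(nrow(active))) {
    E <- E + active$amplitude[i] *
      exp(-0.5 * ((mid - active$position[i]) / active$width[i])^2)
  }
  (1 + d_kb)^(-spec$alpha) * D * E
}

# planted elevated-contact span for a viewpoint: its domain joined with the TZ
planted_domain <- function(spec, viewpoint) {
  vp <- spec$viewpoints[spec$viewpoints$name == viewpoint, ]
  dom <- if (in_interval(vp$position, spec$domain_a)) spec$domain_a
         else spec$domain_b
  c(min(dom[1], spec$tz[1]), max(dom[2], spec$tz[2]))
}

#' Simulate per-fragment 4C counts for one viewpoint
#'
#' Allocates the library size over fragments by a multinomial draw with
#' probabilities proportional to the expected intensities, overdispersed by a
#' per-fragment gamma multiplier with variance `dispersion` (so total depth is
#' fixed and `dispersion = 0` recovers the pure multinomial).
#'
#' @inheritParams expected_intensity
#' @param seed integer seed.
#' @return A list: `counts` (integer per fragment), and `truth` with the
#'   expected intensities, the planted domain boundaries of this viewpoint
#'   (bp), and the planted TZ.
#' @export
simulate_counts <- function(spec, map, viewpoint, seed = 1) {
  mu <- expected_intensity(spec, map, viewpoint)
  if (all(mu <= 0)) abort("all-zero expected intensity")
  with_seed(seed, {
    w <- if (spec$dispersion > 0) {
      rgamma(length(mu), shape = 1 / spec$dispersion, rate = 1 / spec$dispersion)
    } else {
      rep(1, length(mu))
    }
    p <- mu * w
    counts <- as.integer(rmultinom(1, spec$library_size, p / sum(p)))
  })
  list(
    counts = counts,
    truth = list(
      expected = mu,
      boundaries = planted_domain(spec, viewpoint),
      tz = spec$tz,
      viewpoint = viewpoint
    )
  )
}

#' Simulate barcoded 4C reads from fragment counts
#'
#' Emits one read per count: the viewpoint's barcode tag followed by
#' `read_length` bases taken from the fragment's 5' end (from the realized
#' sequence when the map carries one, random bases otherwise). The read pool
#' is shuffled across viewpoints. Demultiplexing the pool and counting the
#' recorded alignment positions reproduces the input counts exactly.
#'
#' @param spec a `locus_spec`.
#' @param map a `fragment_map`.
#' @param counts named list of count vectors, one entry per viewpoint name.
#' @param seed integer seed.
#' @return A list: `reads` (tibble `name`, `seq`) and `truth` (tibble `name`,
#'   `viewpoint`, `chrom`, `pos`, `fragment` — the 0-based alignment position
#'   is the fragment start).
#' @export
simulate_reads <- function(spec, map, counts, seed = 1) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  seqchar <- attr(map, "sequence")
  with_seed(seed, {
    per_vp <- purrr::map_dfr(names(counts), function(vn) {
      vp <- spec$viewpoints[spec$viewpoints$name == vn, ]
      if (nrow(vp) != 1) abort(sprintf("counts given for unknown viewpoint '%s'", vn))
      cnt <- counts[[vn]]
      stopifnot(length(cnt) == nrow(map))
      frag <- rep.int(seq_len(nrow(map)), cnt)
      if (length(frag) == 0) return(NULL)
      body <- if (!is.null(seqchar)) {
        substring(seqchar, map$start[frag] + 1,
                  pmin(map$start[frag] + spec$read_length, map$end[frag]))
      } else {
        vapply(seq_along(frag), function(i) {
          paste(sample(c("A", "C", "G", "T"), spec$read_length, TRUE),
                collapse = "")
        }, character(1))
      }
      tibble(
        viewpoint = vn,
        seq = paste0(vp$tag, body),
        chrom = map$chrom[frag],
        pos = map$start[frag],
        fragment = map$index[frag]
      )
    })
    if (is.null(per_vp) || nrow(per_vp) == 0) {
      per_vp <- tibble(viewpoint = character(), seq = character(),
                       chrom = character(), pos = numeric(),
                       fragment = integer())
    }
    per_vp <- per_vp[sample.int(nrow(per_vp)), ]
    per_vp$name <- sprintf("read%07d", seq_len(nrow(per_vp)))
  })
  list(
    reads = per_vp[, c("name", "seq")],
    truth = per_vp[, c("name", "viewpoint", "chrom", "pos", "fragment")]
  )
}

#' Re-express a synthetic locus on an engineered allele
#'
#' Lifts the structural elements of a locus spec (TZ, enhancer peaks,
#' viewpoints) through a set of rearrangement events and re-derives the two
#' domains from the lifted TZ position: everything between the locus outer
#' limits on one side of the TZ belongs to one domain. Deleting the TZ
#' therefore yields a single merged domain spanning both outer limits, and an
#' inversion that carries an enhancer across the TZ relocates it into the
#' other viewpoint's domain — the two hallmark behaviours of the engineered
#' alleles this model emulates. Domains are deliberately NOT lifted wholesale.
#'
#' @param spec a `locus_spec` in reference coordinates.
#' @param events rearrangement events (see [rearrangement()]).
#' @param name allele name.
#' @return A new `locus_spec` in allele coordinates, with the
#'   [build_allele_map()] attached as attribute `"allele_map"`. Deleting a
#'   viewpoint is an error.
#' @export
simulate_allele <- function(spec, events, name = "allele") {
  map <- build_allele_map(events, spec$chrom_length, name = name,
                          chrom = spec$chrom)
  lift1 <- function(p, what) {
    res <- lift_point(map, p)
    res <- res[res$copy_index %in% 0L | res$deleted, ]
    if (res$deleted[1]) {
      if (what == "viewpoint") {
        abort(sprintf("event deletes a viewpoint at position %d", p))
      }
      return(NA_real_)
    }
    res$image[1]
  }
  vps <- spec$viewpoints
  vps$position <- vapply(vps$position, lift1, numeric(1), what = "viewpoint")

  peaks <- spec$peaks
  if (nrow(peaks) > 0) {
    peaks$position <- vapply(peaks$position, lift1, numeric(1), what = "peak")
    peaks <- peaks[!is.na(peaks$position), ]
  }

  outer_lo <- min(spec$domain_a[1], spec$domain_b[1])
  outer_hi <- max(spec$domain_a[2], spec$domain_b[2])
  snap_lift <- function(p) {
    res <- lift_point(map, p)
    if (res$deleted[1]) {
      surv <- map[map$copy_index == 0, ]
      cand <- c(surv$ref_start, surv$ref_end - 1)
      p <- cand[which.min(abs(cand - p))]
      res <- lift_point(map, p)
    }
    res$image[res$copy_index == 0][1]
  }
  lo <- snap_lift(outer_lo)
  hi <- snap_lift(outer_hi - 1) + 1

  tz_img <- lift_interval(map, spec$tz[1], spec$tz[2])
  if (nrow(tz_img) == 0) {
    # TZ deleted: one merged domain bounded by the outer limits
    dom_a <- dom_b <- c(lo, hi)
    tz_new <- c(lo, lo) # degenerate
  } else {
    tz_new <- c(min(tz_img$start), max(tz_img$end))
    left <- c(lo, tz_new[2])
    right <- c(tz_new[1], hi)
    vpa <- vps$position[1]
    if (vpa < tz_new[1]) {
      dom_a <- left; dom_b <- right
    } else {
      dom_a <- right; dom_b <- left
    }
  }

  out <- spec
  out$chrom_length <- attr(map, "allele_length")
  out$domain_a <- dom_a
  out$domain_b <- dom_b
  out$tz <- tz_new
  out$peaks <- peaks
  out$viewpoints <- vps
  attr(out, "allele_map") <- map
  attr(out, "allele_name") <- name
  out
}

#' One-call simulation of a processed viewpoint profile
#'
#' Convenience wrapper running the full forward pipeline on a synthetic locus:
#' simulate counts, assemble the profile, RPM-normalize, mask the viewpoint
#' zone, smooth. The simulation truth is attached as attribute `"truth"`.
#'
#' @inheritParams simulate_counts
#' @param window smoothing window (fragments).
#' @param mask_radius viewpoint exclusion radius (bp).
#' @return A ready-to-segment `vp_profile`.
#' @export
simulate_viewpoint_profile <- function(spec, map, viewpoint, seed = 1,
                                       window = 11, mask_radius = 10000) {
  sim <- simulate_counts(spec, map, viewpoint, seed = seed)
  vp <- spec$viewpoints[spec$viewpoints$name == viewpoint, ]
  prof <- build_profile(map, sim$counts, vp) %>%
    rpm_normalize() %>%
    mask_viewpoint(radius = mask_radius) %>%
    smooth_profile(window = window)
  attr(prof, "truth") <- sim$truth
  prof
}
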