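#' Describe a rearrangement event
#'
#' One engineered structural event on the reference: a deletion, a balanced
#' inversion, or a tandem duplication (extra copy inserted immediately after
#' the original). Events composing one allele must be pairwise non-overlapping;
#' nested or overlapping events are rejected by [build_allele_map()].
#'
#' @param kind one of `"deletion"`, `"inversion"`, `"tandem_duplication"`.
#' @param start,end target interval on the reference, 0-based half-open.
#' @param chrom chromosome name (informational; the map is single-chromosome).
#' @return A one-row tibble; rows from several calls can be `bind_rows()`ed
#'   into one allele definition.
#' @seealso [build_allele_map()], [read_rearrangement_config()]
#' @examples
#' rearrangement("inversion", 2e5, 6e5)
#' @export
rearrangement <- function(kind = c("deletion", "inversion", "tandem_duplication"),
                          start, end, chrom = "chr1") {
  kind <- match.arg(kind)
  check_interval(start, end)
  tibble(kind = kind, chrom = chrom, start = start, end = end)
}

#' Build the allele/reference coordinate map for an engineered allele
#'
#' Applies a set of pairwise non-overlapping deletion, inversion and tandem
#' duplication events to a reference chromosome and returns the ordered,
#' oriented blocks composing the rearranged allele. The map is the basis for
#' lifting points, intervals and per-fragment signal tracks between reference
#' and allele coordinates, so that 4C profiles of rearranged alleles can be
#' drawn against the actual genomic structure of each allele.
#'
#' @param events tibble of events as produced by [rearrangement()] (columns
#'   `kind`, `start`, `end`). Zero rows give the identity map.
#' @param reference_length chromosome length in bp.
#' @param name allele name carried into track headers.
#' @param chrom chromosome name.
#' @return An `allele_map`: a tibble of blocks with columns `ref_start`,
#'   `ref_end` (source interval on the reference), `orientation` (`"+"`/`"-"`),
#'   `copy_index` (0 for the original, 1 for a tandem copy) and the derived
#'   `allele_start`, `allele_end`. Attributes `reference_length`,
#'   `allele_length`, `name`, `chrom`.
#' @examples
#' build_allele_map(rearrangement("inversion", 20, 60), reference_length = 100)
#' @export
build_allele_map <- function(events = NULL, reference_length, name = "allele",
                             chrom = "chr1") {
  stopifnot(is.numeric(reference_length), reference_length > 0)
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(kind = character(), start = numeric(), end = numeric())
  }
  check_interval(events$start, events$end, reference_length)
  events <- arrange(events, .data$start)
  if (nrow(events) > 1) {
    bad <- which(events$start[-1] < events$end[-nrow(events)])
    if (length(bad) > 0) {
      abort(sprintf(
        "overlapping events: [%d,%d) %s and [%d,%d) %s",
        events$start[bad[1]], events$end[bad[1]], events$kind[bad[1]],
        events$start[bad[1] + 1], events$end[bad[1] + 1], events$kind[bad[1] + 1]
      ))
    }
  }

  blocks <- list()
  cursor <- 0
  add <- function(rs, re, orient, copy) {
    if (re > rs) {
      blocks[[length(blocks) + 1]] <<- tibble(
        ref_start = rs, ref_end = re, orientation = orient, copy_index = copy
      )
    }
  }
  for (i in seq_len(nrow(events))) {
    add(cursor, events$start[i], "+", 0L)
    s <- events$start[i]
    e <- events$end[i]
    switch(events$kind[i],
      deletion = NULL,
      inversion = add(s, e, "-", 0L),
      tandem_duplication = {
        add(s, e, "+", 0L)
        add(s, e, "+", 1L)
      },
      abort(sprintf("unknown event kind '%s'", events$kind[i]))
    )
    cursor <- e
  }
  add(cursor, reference_length, "+", 0L)

  map <- bind_rows(blocks)
  len <- map$ref_end - map$ref_start
  map$allele_end <- cumsum(len)
  map$allele_start <- map$allele_end - len
  map <- map[, c("ref_start", "ref_end", "orientation", "copy_index",
                 "allele_start", "allele_end")]
  structure(map,
    class = c("allele_map", class(tibble())),
    reference_length = reference_length,
    allele_length = sum(len),
    name = name, chrom = chrom
  )
}

#' @export
print.allele_map <- function(x, ...) {
  cat(sprintf(
    "<allele_map '%s'> reference %s bp -> allele %s bp, %d block(s)\n",
    attr(x, "name"), format(attr(x, "reference_length"), big.mark = ","),
    format(attr(x, "allele_length"), big.mark = ","), nrow(x)
  ))
  NextMethod()
}

#' Lift single positions across an allele map
#'
#' Maps base-pair positions between reference and allele coordinates. A
#' reference position inside a deleted interval has no image (`deleted = TRUE`,
#' `image = NA`); a position inside a tandem duplication has two images,
#' distinguished by `copy_index`. Allele-to-reference lifting is always
#' single-valued.
#'
#' @param map an [build_allele_map()] result.
#' @param position vector of 0-based positions in the source frame.
#' @param direction `"ref2allele"` (default) or `"allele2ref"`.
#' @return A tibble with one row per image: `position` (input), `image`,
#'   `orientation`, `copy_index`, `deleted`. Deleted positions keep one row
#'   with `image = NA`.
#' @examples
#' m <- build_allele_map(rearrangement("inversion", 20, 60), 100)
#' lift_point(m, 25) # image 54 on the minus strand
#' @export
lift_point <- function(map, position, direction = c("ref2allele", "allele2ref")) {
  direction <- match.arg(direction)
  src_len <- if (direction == "ref2allele") {
    attr(map, "reference_length")
  } else {
    attr(map, "allele_length")
  }
  if (any(position < 0) || any(position >= src_len)) {
    abort(sprintf("position outside the %s frame [0, %d)",
                  sub("2.*", "", direction), src_len))
  }
  # block-wise, so lifting many positions is vectorized
  hits <- purrr::map_dfr(seq_len(nrow(map)), function(i) {
    if (direction == "ref2allele") {
      sel <- which(position >= map$ref_start[i] & position < map$ref_end[i])
      if (length(sel) == 0) return(NULL)
      p <- position[sel]
      img <- if (map$orientation[i] == "+") {
        map$allele_start[i] + (p - map$ref_start[i])
      } else {
        map$allele_start[i] + (map$ref_end[i] - 1 - p)
      }
    } else {
      sel <- which(position >= map$allele_start[i] & position < map$allele_end[i])
      if (length(sel) == 0) return(NULL)
      p <- position[sel]
      img <- if (map$orientation[i] == "+") {
        map$ref_start[i] + (p - map$allele_start[i])
      } else {
        map$ref_end[i] - 1 - (p - map$allele_start[i])
      }
    }
    tibble(ord = sel, position = p, image = img,
           orientation = map$orientation[i], copy_index = map$copy_index[i],
           deleted = FALSE)
  })
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- tibble(ord = integer(), position = numeric(), image = numeric(),
                   orientation = character(), copy_index = integer(),
                   deleted = logical())
  }
  no_hit <- setdiff(seq_along(position), hits$ord)
  if (length(no_hit) > 0) {
    hits <- bind_rows(hits, tibble(
      ord = no_hit, position = position[no_hit], image = NA_real_,
      orientation = NA_character_, copy_index = NA_integer_, deleted = TRUE
    ))
  }
  hits <- arrange(hits, .data$ord, .data$copy_index)
  hits$ord <- NULL
  hits
}

#' Lift an interval across an allele map
#'
#' Returns the minimal set of target-frame intervals covering all non-deleted
#' images of `[start, end)`. An interval spanning an event breakpoint is split
#' into pieces; pieces falling in an inverted block come back on the minus
#' strand; pieces in a tandem duplication come back once per copy.
#'
#' @inheritParams lift_point
#' @param start,end source-frame interval, 0-based half-open.
#' @return Tibble of images sorted by target position: `start`, `end`,
#'   `orientation`, `copy_index`, plus `src_start`, `src_end` recording the
#'   originating piece. Zero rows mean the interval was entirely deleted.
#' @export
lift_interval <- function(map, start, end,
                          direction = c("ref2allele", "allele2ref")) {
  direction <- match.arg(direction)
  src_len <- if (direction == "ref2allele") {
    attr(map, "reference_length")
  } else {
    attr(map, "allele_length")
  }
  check_interval(start, end, src_len)
  if (direction == "ref2allele") {
    bs <- map$ref_start; be <- map$ref_end
  } else {
    bs <- map$allele_start; be <- map$allele_end
  }
  ps <- pmax(start, bs)
  pe <- pmin(end, be)
  keep <- which(pe > ps)
  if (length(keep) == 0) {
    return(tibble(start = numeric(), end = numeric(),
                  orientation = character(), copy_index = integer(),
                  src_start = numeric(), src_end = numeric()))
  }
  rows <- purrr::map_dfr(keep, function(i) {
    s <- ps[i]; e <- pe[i]
    if (direction == "ref2allele") {
      if (map$orientation[i] == "+") {
        ts <- map$allele_start[i] + (s - map$ref_start[i])
        te <- map$allele_start[i] + (e - map$ref_start[i])
      } else {
        ts <- map$allele_start[i] + (map$ref_end[i] - e)
        te <- map$allele_start[i] + (map$ref_end[i] - s)
      }
    } else {
      if (map$orientation[i] == "+") {
        ts <- map$ref_start[i] + (s - map$allele_start[i])
        te <- map$ref_start[i] + (e - map$allele_start[i])
      } else {
        ts <- map$ref_end[i] - (e - map$allele_start[i])
        te <- map$ref_end[i] - (s - map$allele_start[i])
      }
    }
    tibble(start = ts, end = te, orientation = map$orientation[i],
           copy_index = map$copy_index[i], src_start = s, src_end = e)
  })
  rows <- arrange(rows, .data$start)
  merge_lift_pieces(rows)
}

# coalesce pieces contiguous in both frames with matching orientation/copy
merge_lift_pieces <- function(rows) {
  if (nrow(rows) < 2) return(rows)
  out <- rows[1, ]
  for (i in 2:nrow(rows)) {
    j <- nrow(out)
    contiguous <- rows$start[i] == out$end[j] &&
      rows$orientation[i] == out$orientation[j] &&
      rows$copy_index[i] == out$copy_index[j] &&
      if (out$orientation[j] == "+") {
        rows$src_start[i] == out$src_end[j]
      } else {
        rows$src_end[i] == out$src_start[j]
      }
    if (contiguous) {
      out$end[j] <- rows$end[i]
      if (out$orientation[j] == "+") {
        out$src_end[j] <- rows$src_end[i]
      } else {
        out$src_start[j] <- rows$src_start[i]
      }
    } else {
      out <- bind_rows(out, rows[i, ])
    }
  }
  out
}

#' Reorder a per-fragment signal track into allele coordinates
#'
#' Lifts every element of a reference-keyed track (non-overlapping intervals
#' with a value, e.g. per-fragment 4C counts) into allele coordinates, so a
#' profile can be plotted against the actual structure of a rearranged allele.
#' Elements wholly inside a deletion are dropped; elements inside a tandem
#' duplication appear once per copy; an element spanning an event breakpoint
#' is split, each part keeping the full value and flagged `split = TRUE`
#' (such fragments are chimeric in a real library and unreliable), or rejected
#' when `strict = TRUE`.
#'
#' @param map an [build_allele_map()] result.
#' @param track tibble with `start`, `end`, `value` (extra columns carried
#'   along); intervals non-overlapping, reference coordinates.
#' @param strict reject breakpoint-spanning elements instead of splitting.
#' @return Track in allele coordinates, sorted by `start`, with `orientation`,
#'   `copy_index` and `split` columns added. Within an inverted span, values
#'   appear in reversed order.
#' @export
reorder_track <- function(map, track, strict = FALSE) {
  stopifnot(all(c("start", "end", "value") %in% names(track)))
  if (nrow(track) > 1) {
    o <- order(track$start)
    if (any(track$start[o][-1] < track$end[o][-nrow(track)])) {
      abort("track intervals overlap on the reference")
    }
  }
  extra <- setdiff(names(track), c("start", "end", "value"))
  pieces <- purrr::map_dfr(seq_len(nrow(track)), function(i) {
    img <- lift_interval(map, track$start[i], track$end[i])
    if (nrow(img) == 0) return(NULL)
    full <- nrow(img) == length(unique(img$copy_index)) &&
      sum(img$end - img$start) / length(unique(img$copy_index)) ==
        track$end[i] - track$start[i]
    if (!full && strict) {
      abort(sprintf("track element [%d,%d) spans a breakpoint (strict mode)",
                    track$start[i], track$end[i]))
    }
    res <- tibble(start = img$start, end = img$end, value = track$value[i],
                  orientation = img$orientation, copy_index = img$copy_index,
                  split = !full)
    for (col in extra) res[[col]] <- track[[col]][i]
    res
  })
  if (is.null(pieces) || nrow(pieces) == 0) {
    pieces <- tibble(start = numeric(), end = numeric(), value = numeric(),
                     orientation = character(), copy_index = integer(),
                     split = logical())
  }
  arrange(pieces, .data$start)
}

#' Read allele definitions from a YAML configuration file
#'
#' The file lists one allele per named entry under `alleles:`; each event has
#' `kind` (deletion / inversion / tandem_duplication), optional `chrom`, and
#' `start`/`end` given 1-based inclusive as in published locus coordinates.
#' Coordinates are converted to the package's 0-based half-open convention on
#' read.
#'
#' @param path YAML file. Optional top-level `reference:` entry with `chrom`
#'   and `length` is returned as an attribute.
#' @return Named list of event tibbles suitable for [build_allele_map()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "reference: {chrom: chr2, length: 1000000}",
#'   "alleles:",
#'   "  del1:",
#'   "    - {kind: deletion, start: 450001, end: 550000}"
#' ), cfg)
#' read_rearrangement_config(cfg)
#' @export
read_rearrangement_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alleles)) abort("configuration must contain an 'alleles:' entry")
  alleles <- purrr::map(cfg$alleles, function(events) {
    purrr::map_dfr(events, function(ev) {
      iv <- from_1based(ev$start, ev$end)
      rearrangement(ev$kind, iv$start, iv$end,
                    chrom = ev$chrom %||% cfg$reference$chrom %||% "chr1")
    })
  })
  structure(alleles, reference = cfg$reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
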