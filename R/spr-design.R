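## ReDCaT capture-duplex design.
##
## ReDCaT (reusable DNA capture technology) SPR uses test duplexes of at
## most 40 bp whose bottom strand carries a constant 20-nt single-stranded
## extension complementary to a chip-immobilised biotinylated linker, so one
## streptavidin chip can be re-used across many test sequences.  The design
## helpers build the three series used to map a binding site: overlapping
## tiles across a region, 2-bp truncation ladders from either end, and
## repeat-substitution variants.

#' The constant ReDCaT capture overhang
#'
#' The 20-nt single-stranded extension appended to the bottom strand of every
#' capture duplex, complementary to the chip-immobilised biotinylated linker.
#' @return A 20-character DNA string.
#' @export
redcat_overhang <- function() "CCTACCCTACGTCCTCCTGC"

new_design <- function(design_id, test_seq, provenance,
                       start = NA_integer_, end = NA_integer_,
                       intact_repeats = list(NULL)) {
  tibble(
    design_id = design_id,
    test_seq = test_seq,
    bottom_strand = paste0(vapply(test_seq, revcomp, character(1), USE.NAMES = FALSE),
                           redcat_overhang()),
    start = as.integer(start),
    end = as.integer(end),
    provenance = provenance,
    intact_repeats = intact_repeats
  )
}

#' Build one ReDCaT capture duplex
#'
#' The top strand is the test sequence (at most 40 nt, the ReDCaT annealing
#' limit); the bottom strand is its reverse complement followed by the 20-nt
#' capture overhang ([redcat_overhang()]).
#'
#' @param test_seq Test sequence, 1-40 nt of A/C/G/T.
#' @param design_id Identifier for the design.
#' @param provenance Free-text origin tag (default `"manual"`).
#' @return A one-row design tibble with columns `design_id`, `test_seq`,
#'   `bottom_strand`, `start`, `end`, `provenance`, `intact_repeats`.
#' @examples
#' make_redcat_duplex("ATGC", "demo")
#' @export
make_redcat_duplex <- function(test_seq, design_id, provenance = "manual") {
  test_seq <- assert_dna(test_seq, "test_seq")
  if (nchar(test_seq) > 40L) {
    abort(sprintf(
      "Test sequence is %d nt; ReDCaT capture duplexes must be <= 40 bp.",
      nchar(test_seq)
    ))
  }
  new_design(as.character(design_id), test_seq, provenance)
}

#' Tile a region with overlapping capture duplexes
#'
#' Places `n_oligos` oligos of length `oligo_len` at evenly spaced, rounded
#' starts `round(i * (L - oligo_len) / (n_oligos - 1))`, so the first starts
#' at 0, the last ends at `L`, and together they cover the whole region --
#' the layout used to split an intergenic region into overlapping 40-bp
#' test duplexes.
#'
#' @param region_seq Region sequence (A/C/G/T).
#' @param n_oligos Number of tiles (>= 1).
#' @param oligo_len Tile length in nt (default 40, the ReDCaT limit).
#' @param id_prefix Prefix for design ids (default `"O"`, giving O1, O2, ...).
#' @return A design tibble, one row per tile, with `start`/`end` giving each
#'   tile's 0-based half-open span in region coordinates.
#' @examples
#' tile_region(strrep("ACGT", 40), n_oligos = 6) # 160-nt region, 6 tiles
#' @export
tile_region <- function(region_seq, n_oligos, oligo_len = 40L,
                        id_prefix = "O") {
  region_seq <- assert_dna(region_seq, "region_seq")
  L <- nchar(region_seq)
  oligo_len <- as.integer(assert_scalar_num(oligo_len, "oligo_len", positive = TRUE))
  n_oligos <- as.integer(assert_scalar_num(n_oligos, "n_oligos", positive = TRUE))
  if (L < oligo_len) abort("Region is shorter than `oligo_len`.")
  if (n_oligos * oligo_len < L) {
    abort(sprintf(
      "%d oligos of %d nt cannot cover a %d-nt region.",
      n_oligos, oligo_len, L
    ))
  }
  starts <- if (n_oligos == 1L) 0L else
    as.integer(round((seq_len(n_oligos) - 1L) * (L - oligo_len) / (n_oligos - 1L)))
  new_design(
    design_id = paste0(id_prefix, seq_len(n_oligos)),
    test_seq = substring(region_seq, starts + 1L, starts + oligo_len),
    provenance = "tiling",
    start = starts, end = starts + oligo_len
  )
}

#' Truncation series from one end of a region
#'
#' Removes `step` bp at a time (default 2) from the chosen end until only
#' `min_len` nt remain, yielding `floor((L - min_len)/step) + 1` designs.
#' Every member is a verbatim contiguous substring of the original region;
#' `start`/`end` give each member's span in original-region coordinates, so
#' truncation ladders can be mapped back onto the footprint.
#'
#' @param region_seq Region sequence (A/C/G/T), at most 40 nt (each member
#'   must be a valid capture duplex).
#' @param side `"left"` or `"right"`: the end bases are removed from.
#' @param min_len Shortest member length in nt.
#' @param step Bases removed per truncation (default 2).
#' @param id_prefix Prefix for design ids (default `"LH"` or `"RH"` by side).
#' @return A design tibble ordered from full length to shortest.
#' @export
truncation_series <- function(region_seq, side = c("left", "right"),
                              min_len, step = 2L, id_prefix = NULL) {
  region_seq <- assert_dna(region_seq, "region_seq")
  side <- match.arg(side)
  L <- nchar(region_seq)
  step <- as.integer(assert_scalar_num(step, "step", positive = TRUE))
  min_len <- as.integer(assert_scalar_num(min_len, "min_len", positive = TRUE))
  if (min_len > L) abort("`min_len` exceeds the region length.")
  if (L > 40L) abort("Region exceeds the 40-bp ReDCaT duplex limit.")
  id_prefix <- id_prefix %||% if (side == "left") "LH" else "RH"

  removed <- seq.int(0L, L - min_len, by = step)
  if (side == "left") {
    starts <- removed
    ends <- rep(L, length(removed))
  } else {
    starts <- rep(0L, length(removed))
    ends <- L - removed
  }
  new_design(
    design_id = paste0(id_prefix, seq_along(removed)),
    test_seq = substring(region_seq, starts + 1L, ends),
    provenance = "truncation",
    start = starts, end = ends
  )
}

#' Repeat-substitution series over labelled repeat spans
#'
#' For `k` labelled repeat spans, emits one design per non-empty subset of
#' repeats kept intact (7 designs for 3 repeats): the spans of the repeats
#' *not* kept are replaced by seeded random DNA of identical length, so all
#' designs have the original length and differ from the source only inside
#' replaced spans. The kept labels are recorded in `intact_repeats`,
#' which is what [simulate_spr_cycles()] and downstream affinity comparisons
#' key on.
#'
#' @param region_seq Region sequence (A/C/G/T), at most 40 nt.
#' @param repeat_spans Data frame with columns `label`, `start`, `end`
#'   (0-based half-open, disjoint, within the region).
#' @param seed Integer seed for the replacement bases.
#' @param gc_fraction GC fraction of the random replacement DNA
#'   (default 0.5; set to the regional GC content to GC-match).
#' @return A design tibble; the first row keeps all repeats (and therefore
#'   equals the original sequence).
#' @export
substitution_series <- function(region_seq, repeat_spans, seed = NULL,
                                gc_fraction = 0.5) {
  region_seq <- assert_dna(region_seq, "region_seq")
  L <- nchar(region_seq)
  if (L > 40L) abort("Region exceeds the 40-bp ReDCaT duplex limit.")
  spans <- as_tibble(repeat_spans)
  if (!all(c("label", "start", "end") %in% names(spans))) {
    abort("`repeat_spans` needs columns `label`, `start`, `end`.")
  }
  spans <- arrange(spans, .data$start)
  if (any(spans$start < 0 | spans$end > L | spans$end <= spans$start)) {
    abort("Repeat spans must be non-empty intervals inside the region.")
  }
  if (nrow(spans) > 1L && any(spans$start[-1L] < spans$end[-nrow(spans)])) {
    abort("Repeat spans overlap.")
  }

  k <- nrow(spans)
  # all non-empty subsets, ordered by number of repeats kept (descending)
  subsets <- unlist(lapply(k:1, function(m) {
    utils::combn(seq_len(k), m, simplify = FALSE)
  }), recursive = FALSE)

  with_seed(seed, {
    rows <- map(seq_along(subsets), function(si) {
      keep <- subsets[[si]]
      chars <- seq_chars(region_seq)
      for (j in setdiff(seq_len(k), keep)) {
        span <- (spans$start[j] + 1L):spans$end[j]
        chars[span] <- sample(
          DNA_BASES, length(span), replace = TRUE,
          prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                   gc_fraction / 2, (1 - gc_fraction) / 2)
        )
      }
      kept_labels <- as.character(spans$label[keep])
      new_design(
        design_id = paste0("sub_", paste(kept_labels, collapse = "+")),
        test_seq = paste(chars, collapse = ""),
        provenance = "substitution",
        start = 0L, end = L,
        intact_repeats = list(kept_labels)
      )
    })
    list_rbind(rows)
  })
}

#' Annotate designs with the repeats they leave intact
#'
#' Marks, for each design with region coordinates, which labelled repeat
#' spans lie fully inside the design's `[start, end)` interval. This is the
#' annotation [simulate_spr_cycles()] keys on, and it links truncation or
#' tiling series to repeat content.
#'
#' @param designs A design tibble with `start`/`end` in region coordinates.
#' @param repeat_spans Data frame with columns `label`, `start`, `end`
#'   (0-based half-open, region coordinates).
#' @return `designs` with its `intact_repeats` list-column filled in.
#' @export
annotate_intact_repeats <- function(designs, repeat_spans) {
  designs <- as_tibble(designs)
  spans <- as_tibble(repeat_spans)
  if (!all(c("label", "start", "end") %in% names(spans))) {
    abort("`repeat_spans` needs columns `label`, `start`, `end`.")
  }
  if (!all(c("start", "end") %in% names(designs)) ||
      anyNA(designs$start) || anyNA(designs$end)) {
    abort("`designs` must carry region coordinates in `start`/`end`.")
  }
  designs$intact_repeats <- map(seq_len(nrow(designs)), function(i) {
    inside <- spans$start >= designs$start[i] & spans$end <= designs$end[i]
    as.character(spans$label[inside])
  })
  designs
}
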