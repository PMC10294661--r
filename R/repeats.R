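## Degenerate consensus scanning and de novo direct-repeat discovery.
##
## Direct repeats -- same-strand, same-orientation copies of a short unit --
## mark many bacterial transcription-factor operator sites. `scan_consensus`
## finds matches to a known degenerate consensus (IUPAC codes; `X` accepted
## as a synonym of N); `find_direct_repeats` discovers repeat families de
## novo in short regulatory sequences; `consensus_of` summarises aligned
## members back into a degenerate consensus.

iupac_sets <- function(consensus) {
  if (!is.character(consensus) || length(consensus) != 1L || is.na(consensus) ||
      nchar(consensus) == 0L) {
    abort("`consensus` must be a single non-empty string of IUPAC codes.")
  }
  chars <- seq_chars(toupper(consensus))
  bad <- setdiff(unique(chars), names(IUPAC_SETS))
  if (length(bad) > 0L) {
    abort(sprintf("Invalid IUPAC code(s) in consensus: %s",
                  paste(bad, collapse = ", ")))
  }
  IUPAC_SETS[chars]
}

# Mismatches between a concrete subsequence and a consensus, counting only
# positions where the consensus is a single concrete base.
consensus_mismatches <- function(subseq, sets) {
  chars <- seq_chars(subseq)
  sum(vapply(seq_along(sets), function(i) {
    length(sets[[i]]) == 1L && chars[i] != sets[[i]]
  }, logical(1)))
}

scan_one_strand <- function(seq, sets, max_mismatch, strand) {
  k <- length(sets)
  if (nchar(seq) < k) {
    return(tibble(start = integer(0), length = integer(0),
                  matched_seq = character(0), mismatches = integer(0),
                  strand = character(0)))
  }
  # Degenerate positions are replaced by N so they can never contribute a
  # mismatch; Biostrings then counts mismatches at the concrete positions.
  pat <- paste(vapply(sets, function(s) if (length(s) == 1L) s else "N",
                      character(1)), collapse = "")
  m <- Biostrings::matchPattern(
    Biostrings::DNAString(pat), Biostrings::DNAString(seq),
    max.mismatch = max_mismatch, fixed = "subject"
  )
  # with mismatches allowed, matchPattern can report views hanging over the
  # subject ends; only fully contained matches are meaningful here
  st <- Biostrings::start(m)
  en <- Biostrings::end(m)
  keep <- which(st >= 1L & en <= nchar(seq))
  starts0 <- st[keep] - 1L
  matched <- if (length(keep) == 0L) character(0) else
    substring(seq, st[keep], en[keep])
  tibble(
    start = starts0,
    length = k,
    matched_seq = matched,
    mismatches = vapply(matched, consensus_mismatches, integer(1),
                        sets = sets, USE.NAMES = FALSE),
    strand = strand
  )
}

#' Scan a sequence for matches to a degenerate consensus
#'
#' Reports every position whose substring matches the consensus with at most
#' `max_mismatch` mismatches at the consensus's non-degenerate positions;
#' degenerate positions (N/X and other multi-base codes) never count as
#' mismatches.
#'
#' @param seq DNA string (A/C/G/T).
#' @param consensus Degenerate consensus (IUPAC codes; `X` means any base,
#'   e.g. `"CGXXCTCAAC"`).
#' @param max_mismatch Maximum mismatches at non-degenerate positions
#'   (default 0).
#' @param both_strands Also scan the reverse strand (default `FALSE`:
#'   direct repeats are same-strand).
#' @return A tibble of hits ordered by `start`: `start` (0-based), `length`,
#'   `matched_seq` (the forward-strand subsequence), `mismatches`, `strand`.
#' @examples
#' scan_consensus("TTTTTCGAACTCAACTTTTT", "CGXXCTCAAC")
#' @export
scan_consensus <- function(seq, consensus, max_mismatch = 0L,
                           both_strands = FALSE) {
  seq <- assert_dna(seq, "seq", allow_empty = TRUE)
  sets <- iupac_sets(consensus)
  max_mismatch <- as.integer(assert_scalar_num(max_mismatch, "max_mismatch", nonneg = TRUE))

  hits <- scan_one_strand(seq, sets, max_mismatch, "+")
  if (both_strands) {
    rc_sets <- rev(lapply(sets, function(s) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      unname(sort(comp[s]))
    }))
    minus <- scan_one_strand(seq, rc_sets, max_mismatch, "-")
    hits <- bind_rows(hits, minus)
  }
  arrange(hits, .data$start, .data$strand)
}

# Shannon entropy of a unit's base composition, bits per base.
unit_entropy <- function(unit) {
  p <- table(seq_chars(unit))
  p <- p / sum(p)
  -sum(p * log2(p))
}

hamming <- function(a, b) sum(seq_chars(a) != seq_chars(b))

#' Discover direct-repeat families de novo
#'
#' Enumerates all unit lengths in `[min_len, max_len]` and, for each, finds
#' same-strand occurrence pairs within `max_span` whose Hamming distance is
#' at most `max_mismatch`, links them into families, and reports maximal
#' non-redundant families. A family is reported only if every pair of its
#' members is within `max_mismatch`, members do not overlap, the span from
#' first start to last end is at most `max_span`, and each member unit has
#' composition entropy of at least 1 bit/base (suppressing homopolymers and
#' other low-complexity runs).
#'
#' One underlying repeat gives rise to many candidate families -- shifted,
#' shortened or extended variants that pay extra mismatches for the shift.
#' Candidates are therefore ranked by total within-family mismatches
#' (cleanest first), then by unit length (longest first), and accepted
#' greedily; a candidate is redundant -- and dropped -- when every one of
#' its member intervals overlaps a member of an already-accepted family.
#' Output order is deterministic: unit length descending, then first start.
#'
#' Intended for short regulatory sequences (at most 10 kb).
#'
#' @param seq DNA string (A/C/G/T), length <= 10 kb.
#' @param min_len,max_len Unit-length range in nt (defaults 8 and 14).
#' @param min_copies Minimum members per family (default 2).
#' @param max_mismatch Maximum pairwise Hamming distance between members
#'   (default 1).
#' @param max_span Maximum extent, first start to last end, of a family in
#'   nt (default: the whole sequence).
#' @return A tibble with one row per family: `unit_length`, `n_members`,
#'   `first_start`, `consensus` (minimal-IUPAC), and list-columns `starts`
#'   and `spacings` (nt between consecutive starts).
#' @export
find_direct_repeats <- function(seq, min_len = 8L, max_len = 14L,
                                min_copies = 2L, max_mismatch = 1L,
                                max_span = NULL) {
  seq <- assert_dna(seq, "seq", allow_empty = TRUE)
  L <- nchar(seq)
  if (L > 10000L) abort("`seq` exceeds 10 kb; intended for short regulatory regions.")
  min_len <- as.integer(assert_scalar_num(min_len, "min_len", positive = TRUE))
  max_len <- as.integer(assert_scalar_num(max_len, "max_len", positive = TRUE))
  if (min_len > max_len) abort("`min_len` must not exceed `max_len`.")
  min_copies <- as.integer(assert_scalar_num(min_copies, "min_copies", positive = TRUE))
  max_mismatch <- as.integer(assert_scalar_num(max_mismatch, "max_mismatch", nonneg = TRUE))
  max_span <- as.integer(max_span %||% L)

  empty <- tibble(
    unit_length = integer(0), n_members = integer(0), first_start = integer(0),
    consensus = character(0), starts = list(), spacings = list()
  )
  if (L < 2L * min_len) return(empty)

  chars <- seq_chars(seq)
  unit_at <- function(s, k) substring(seq, s + 1L, s + k) # 0-based start

  families <- list()
  for (k in seq.int(min(max_len, L), min_len, by = -1L)) {
    # pair detection by offset: positions i and i+delta match if the k-long
    # windows at those offsets differ at <= max_mismatch positions
    pair_from <- integer(0)
    pair_to <- integer(0)
    max_delta <- min(max_span - k, L - k)
    if (max_delta < k) next
    for (delta in seq.int(k, max_delta)) {
      eq <- chars[seq_len(L - delta)] == chars[seq.int(delta + 1L, L)]
      cs <- c(0L, cumsum(eq))
      n_start <- L - delta - k + 1L
      if (n_start < 1L) next
      matches <- cs[seq_len(n_start) + k] - cs[seq_len(n_start)]
      ok <- which(k - matches <= max_mismatch)
      pair_from <- c(pair_from, ok - 1L)           # 0-based
      pair_to <- c(pair_to, ok - 1L + delta)
    }
    if (length(pair_from) == 0L) next

    # entropy filter on the participating units
    cand <- sort(unique(c(pair_from, pair_to)))
    ent_ok <- cand[vapply(cand, function(s) unit_entropy(unit_at(s, k)) >= 1,
                          logical(1))]
    keep_pair <- pair_from %in% ent_ok & pair_to %in% ent_ok
    pair_from <- pair_from[keep_pair]
    pair_to <- pair_to[keep_pair]
    if (length(pair_from) == 0L) next

    # connected components over the pair graph (union-find)
    nodes <- sort(unique(c(pair_from, pair_to)))
    parent <- seq_along(nodes)
    idx <- function(s) match(s, nodes)
    find_root <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (p in seq_along(pair_from)) {
      a <- find_root(idx(pair_from[p]))
      b <- find_root(idx(pair_to[p]))
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_along(nodes), find_root, integer(1))

    for (root in unique(comp)) {
      members <- sort(nodes[comp == root])
      # greedy left-to-right selection enforcing the family constraints
      kept <- integer(0)
      for (s in members) {
        if (length(kept) > 0L) {
          if (s < kept[length(kept)] + k) next            # overlap
          if (s + k - kept[1L] > max_span) next           # span
          dists <- vapply(kept, function(t) hamming(unit_at(s, k), unit_at(t, k)),
                          integer(1))
          if (any(dists > max_mismatch)) next             # pairwise distance
        }
        kept <- c(kept, s)
      }
      if (length(kept) < min_copies) next
      units <- vapply(kept, unit_at, character(1), k = k)
      pair_mm <- 0L
      for (a in seq_along(units)) {
        for (b in seq_len(a - 1L)) pair_mm <- pair_mm + hamming(units[a], units[b])
      }
      families[[length(families) + 1L]] <- list(
        unit_length = k, starts = kept, units = units, total_mismatch = pair_mm
      )
    }
  }
  if (length(families) == 0L) return(empty)

  # non-redundancy: accept cleanest (fewest internal mismatches), then
  # longest-unit candidates first; drop a candidate when every member
  # overlaps a member of an already-accepted family (shift/extension
  # variants of the same underlying repeat)
  ord <- order(
    vapply(families, `[[`, integer(1), "total_mismatch"),
    -vapply(families, `[[`, integer(1), "unit_length"),
    vapply(families, function(f) f$starts[1L], integer(1))
  )
  accepted <- list()
  for (fam in families[ord]) {
    redundant <- length(accepted) > 0L && all(vapply(fam$starts, function(s) {
      any(vapply(accepted, function(acc) {
        any(s < acc$starts + acc$unit_length & acc$starts < s + fam$unit_length)
      }, logical(1)))
    }, logical(1)))
    if (!redundant) accepted[[length(accepted) + 1L]] <- fam
  }

  out <- map(accepted, function(fam) {
    tibble(
      unit_length = fam$unit_length,
      n_members = length(fam$starts),
      first_start = fam$starts[1L],
      consensus = consensus_of(fam$units),
      starts = list(fam$starts),
      spacings = list(diff(fam$starts))
    )
  }) |> list_rbind()
  arrange(out, dplyr::desc(.data$unit_length), .data$first_start)
}

# minimal IUPAC code covering a set of observed bases (ACGT -> X)
MINIMAL_CODE <- local({
  keys <- vapply(IUPAC_SETS[setdiff(names(IUPAC_SETS), "X")],
                 function(s) paste(sort(s), collapse = ""), character(1))
  codes <- setNames(names(keys), keys)
  codes[["ACGT"]] <- "X"
  codes
})

#' Degenerate consensus of aligned repeat members
#'
#' Summarises equal-length members column by column. A column where all
#' members agree yields that base under either policy. Under
#' `"minimal-iupac"` a disagreeing column yields the smallest IUPAC code
#' covering the observed bases (`X` when all four occur); under `"strict"`
#' any disagreement yields `X`, mirroring the X-notation used for
#' direct-repeat consensi such as CGXXCTCAAC.
#'
#' @param members Character vector of equal-length DNA strings (>= 2), or a
#'   hit tibble from [scan_consensus()] (its `matched_seq` column is used).
#' @param policy `"minimal-iupac"` (default) or `"strict"`.
#' @return A degenerate consensus string.
#' @examples
#' consensus_of(c("CGAACTCAAC", "CGTTCTCAAC", "CGGTCTCAAC"), policy = "strict")
#' @export
consensus_of <- function(members, policy = c("minimal-iupac", "strict")) {
  policy <- match.arg(policy)
  if (is.data.frame(members)) {
    if (!"matched_seq" %in% names(members)) {
      abort("Hit tables must carry a `matched_seq` column.")
    }
    members <- members$matched_seq
  }
  if (!is.character(members) || length(members) < 2L) {
    abort("At least two members are required.")
  }
  members <- vapply(members, assert_dna, character(1), USE.NAMES = FALSE)
  if (length(unique(nchar(members))) != 1L) {
    abort("All members must have equal length.")
  }
  mat <- do.call(rbind, lapply(members, seq_chars))
  cols <- apply(mat, 2L, function(col) {
    obs <- sort(unique(col))
    if (length(obs) == 1L) return(obs)
    if (policy == "strict") return("X")
    MINIMAL_CODE[[paste(obs, collapse = "")]]
  })
  paste(cols, collapse = "")
}
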