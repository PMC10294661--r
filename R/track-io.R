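## Plain-text track IO: bedGraph and fixed-step wiggle.
##
## Coordinates are 0-based half-open in bedGraph (the format's native
## convention) and 1-based in fixedStep wiggle declarations; everything is
## converted to 0-based positions internally.  The readers validate rather
## than coerce: malformed lines are reported with their line number, and
## overlapping bedGraph intervals are an error because a depth track assigns
## exactly one value per nucleotide.

strip_track_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  which(keep)
}

#' Read a bedGraph file as an interval table
#'
#' @param path Path to a bedGraph file. `track`, `browser` and `#` comment
#'   lines are ignored; data lines must have exactly four whitespace-separated
#'   fields: chrom, start, end, value (0-based half-open).
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  idx <- strip_track_lines(lines)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0), value = numeric(0)))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- idx[which(nf != 4L)[1L]]
    abort(sprintf("Malformed bedGraph line %d in '%s': expected 4 fields.", bad, path))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | end <= start)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed bedGraph line %d in '%s': non-numeric coordinates/value or end <= start.",
      idx[bad[1L]], path
    ))
  }
  tibble(chrom = m[, 1], start = start, end = end, value = value)
}

#' Read a per-nucleotide depth track
#'
#' Reads coverage from bedGraph or fixed-step wiggle into a [depth_track()]
#' over a single linear replicon. Positions not covered by any interval get
#' depth 0. Overlapping bedGraph intervals are rejected: depth is defined
#' once per nucleotide.
#'
#' @param path Input file.
#' @param format `"bedGraph"` or `"wiggle"` (fixedStep).
#' @param replicon_length Length of the replicon in nt; intervals extending
#'   past it are an error.
#' @param replicon Optional replicon name; defaults to the name found in the
#'   file (an all-zero track named "replicon" for an empty file).
#' @return A [depth_track()].
#' @export
read_depth <- function(path, format = c("bedGraph", "wiggle"),
                       replicon_length, replicon = NULL) {
  format <- match.arg(format)
  replicon_length <- as.integer(
    assert_scalar_num(replicon_length, "replicon_length", positive = TRUE)
  )
  if (format == "bedGraph") {
    iv <- read_bedgraph(path)
    if (nrow(iv) > 0L) {
      if (length(unique(iv$chrom)) > 1L) {
        abort(sprintf("'%s' covers multiple replicons; a depth track holds one.", path))
      }
      if (any(iv$end > replicon_length)) {
        abort(sprintf(
          "Interval [%d, %d) in '%s' extends past the replicon end (%d nt).",
          iv$start[which(iv$end > replicon_length)[1L]],
          iv$end[which(iv$end > replicon_length)[1L]], path, replicon_length
        ))
      }
      if (any(iv$value < 0)) abort("Depth values must be non-negative.")
      o <- order(iv$start)
      if (any(iv$start[o][-1L] < iv$end[o][-nrow(iv)])) {
        abort(sprintf("Overlapping intervals in '%s'; depth must be single-valued.", path))
      }
    }
    depth <- numeric(replicon_length)
    for (k in seq_len(nrow(iv))) {
      depth[(iv$start[k] + 1L):iv$end[k]] <- iv$value[k]
    }
    name <- replicon %||% (if (nrow(iv) > 0L) iv$chrom[1L] else "replicon")
  } else {
    parsed <- read_fixedstep_wiggle(path, replicon_length)
    depth <- parsed$depth
    name <- replicon %||% parsed$chrom
  }
  depth_track(depth, replicon = name)
}

read_fixedstep_wiggle <- function(path, replicon_length) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  idx <- strip_track_lines(lines)
  depth <- numeric(replicon_length)
  chrom <- "replicon"
  pos <- NA_integer_ # next 0-based position to fill
  step <- NA_integer_
  span <- 1L
  for (i in idx) {
    line <- trimws(lines[i])
    if (grepl("^variableStep\\b", line)) {
      abort(sprintf("Line %d in '%s': only fixedStep wiggle is supported.", i, path))
    }
    if (grepl("^fixedStep\\b", line)) {
      get_kv <- function(key, default = NA) {
        m <- regmatches(line, regexec(paste0(key, "=(\\S+)"), line))[[1L]]
        if (length(m) == 2L) m[2L] else default
      }
      chrom <- get_kv("chrom", chrom)
      start1 <- suppressWarnings(as.integer(get_kv("start")))
      step <- suppressWarnings(as.integer(get_kv("step", "1")))
      span <- suppressWarnings(as.integer(get_kv("span", "1")))
      if (is.na(start1) || is.na(step) || is.na(span) || start1 < 1L) {
        abort(sprintf("Malformed fixedStep declaration at line %d in '%s'.", i, path))
      }
      pos <- start1 - 1L
      next
    }
    if (is.na(pos)) {
      abort(sprintf("Data before any fixedStep declaration at line %d in '%s'.", i, path))
    }
    v <- suppressWarnings(as.numeric(line))
    if (is.na(v)) abort(sprintf("Malformed wiggle value at line %d in '%s'.", i, path))
    if (v < 0) abort("Depth values must be non-negative.")
    if (pos + span > replicon_length) {
      abort(sprintf(
        "Wiggle value at line %d in '%s' extends past the replicon end (%d nt).",
        i, path, replicon_length
      ))
    }
    depth[(pos + 1L):(pos + span)] <- v
    pos <- pos + step
  }
  list(depth = depth, chrom = chrom)
}

#' Write an enrichment track as bedGraph
#'
#' One interval of width `step` per unmasked window, `[start, start + step)`,
#' carrying the enrichment value; masked windows are omitted. A `track` header
#' line is always written, so an all-masked track yields a header-only file.
#'
#' @param track An `enrichment_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(track, path) {
  if (!inherits(track, "enrichment_track")) abort("`track` must be an enrichment_track.")
  p <- enrichment_params(track)
  keep <- !track$masked
  lines <- c(
    sprintf(
      "track type=bedGraph name=\"enrichment\" description=\"window=%d step=%d background=%d\"",
      p$window, p$step, p$background
    ),
    sprintf(
      "%s\t%d\t%d\t%.6f",
      p$replicon, track$start[keep], track$start[keep] + p$step, track$value[keep]
    )
  )
  ok <- tryCatch({
    suppressWarnings(writeLines(lines, path))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("Cannot write to '%s'.", path))
  invisible(path)
}
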