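## Track containers for the ChIP enrichment pipeline.
##
## A depth track is a per-nucleotide coverage vector over a named linear
## replicon; an enrichment track holds the windowed enrichment ratio sampled
## every `step` nucleotides, together with the window geometry and a
## per-window validity mask.  Both are tibbles so they compose with dplyr,
## with the replicon metadata carried in attributes.

#' Construct a per-nucleotide depth track
#'
#' A depth track stores the sequencing depth at every nucleotide position of
#' a linear replicon, 0-based. This is the quantity `samtools depth` reports,
#' and the input to [windowed_enrichment()].
#'
#' @param depth Numeric vector of non-negative per-position depths; its
#'   length is the replicon length.
#' @param replicon Name of the replicon (chromosome/plasmid).
#' @return A tibble of class `depth_track` with columns `pos` (0-based) and
#'   `depth`, and attribute `replicon`.
#' @examples
#' depth_track(rep(10, 100), "chr")
#' @export
depth_track <- function(depth, replicon = "replicon") {
  if (!is.numeric(depth)) abort("`depth` must be a numeric vector.")
  if (anyNA(depth) || any(depth < 0)) {
    abort("Depth values must be non-negative and non-missing.")
  }
  out <- tibble(pos = seq_along(depth) - 1L, depth = as.numeric(depth))
  attr(out, "replicon") <- as.character(replicon)
  class(out) <- c("depth_track", class(out))
  out
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf(
    "<depth_track> replicon '%s', %d nt, mean depth %.2f\n",
    track_replicon(x), nrow(x), mean(x$depth)
  ))
  NextMethod()
}

track_replicon <- function(x) attr(x, "replicon") %||% "replicon"

new_enrichment_track <- function(start, value, masked, replicon, window, step,
                                 background, replicon_length) {
  out <- tibble(
    start = as.integer(start),
    value = as.numeric(value),
    masked = as.logical(masked)
  )
  out$value[out$masked] <- NA_real_
  attr(out, "replicon") <- replicon
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  attr(out, "background") <- as.integer(background)
  attr(out, "replicon_length") <- as.integer(replicon_length)
  class(out) <- c("enrichment_track", class(out))
  out
}

enrichment_params <- function(x) {
  list(
    replicon = attr(x, "replicon"),
    window = attr(x, "window"),
    step = attr(x, "step"),
    background = attr(x, "background"),
    replicon_length = attr(x, "replicon_length")
  )
}

#' @export
print.enrichment_track <- function(x, ...) {
  p <- enrichment_params(x)
  cat(sprintf(
    "<enrichment_track> replicon '%s' (%d nt), window %d, step %d, background %d; %d windows (%d masked)\n",
    p$replicon, p$replicon_length, p$window, p$step, p$background,
    nrow(x), sum(x$masked)
  ))
  NextMethod()
}

stopifnot_same_params <- function(a, b) {
  pa <- enrichment_params(a)
  pb <- enrichment_params(b)
  for (f in names(pa)) {
    if (!identical(pa[[f]], pb[[f]])) {
      abort(sprintf(
        "Enrichment tracks disagree on `%s` (%s vs %s); they must share replicon and window geometry.",
        f, format(pa[[f]]), format(pb[[f]])
      ))
    }
  }
  if (nrow(a) != nrow(b)) abort("Enrichment tracks have different numbers of windows.")
  invisible(TRUE)
}
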