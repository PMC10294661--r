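## Sliding-window ChIP enrichment.
##
## The statistic: for a 30-nt window advancing in 15-nt steps, enrichment is
## the mean depth inside the window divided by the mean depth over a 3,000-nt
## background window centred on it.  Control-track enrichment is subtracted
## from sample enrichment, replicates are averaged, and runs of consecutive
## above-threshold windows are merged into candidate enriched regions.

#' Windowed local enrichment of a depth track
#'
#' For each window start `s` in `0, step, 2*step, ...` (windows are kept only
#' where the full `window` nucleotides fit on the replicon) the enrichment is
#'
#' \deqn{E(s) = \frac{\mathrm{mean}(d[s, s+W))}{\mathrm{mean}(d[c - B/2, c + B/2))}}
#'
#' where `d` is per-nucleotide depth, `W` the window size, `B` the background
#' size and `c = s + W/2` the window centre. The background window is clipped
#' to the replicon and averaged over its clipped extent, so no windows are
#' lost near the ends of a linear replicon. Windows whose background mean is
#' zero carry no information and are masked rather than set to infinity.
#'
#' The statistic is scale invariant: multiplying the depth track by any
#' positive constant leaves every enrichment value unchanged.
#'
#' @param track A [depth_track()].
#' @param window Window size in nt (default 30).
#' @param step Step between window starts in nt (default 15).
#' @param background Background window size in nt (default 3000); must be
#'   at least `window`.
#' @return An `enrichment_track` tibble with columns `start`, `value`,
#'   `masked` and the window geometry in attributes.
#' @seealso [subtract_control()], [average_replicates()],
#'   [call_enriched_windows()]
#' @examples
#' tr <- depth_track(rep(10, 6000))
#' e <- windowed_enrichment(tr)
#' all(e$value == 1) # flat track normalises to 1 everywhere
#' @export
windowed_enrichment <- function(track, window = 30L, step = 15L,
                                background = 3000L) {
  if (!inherits(track, "depth_track")) abort("`track` must be a depth_track.")
  window <- as.integer(assert_scalar_num(window, "window", positive = TRUE))
  step <- as.integer(assert_scalar_num(step, "step", positive = TRUE))
  background <- as.integer(assert_scalar_num(background, "background", positive = TRUE))
  if (window > background) abort("`background` must be at least `window`.")
  len <- nrow(track)
  if (len < window) {
    abort(sprintf("Track (%d nt) is shorter than the window (%d nt).", len, window))
  }

  depth <- track$depth
  cs <- c(0, cumsum(depth))
  range_sum <- function(from, to) cs[to + 1L] - cs[from + 1L] # 0-based [from, to)

  starts <- seq.int(0L, len - window, by = step)
  num <- range_sum(starts, starts + window) / window

  centre2 <- 2L * starts + window # twice the window centre, avoids fractions
  bg_from <- pmax(0L, as.integer(floor((centre2 - background) / 2)))
  bg_to <- pmin(len, as.integer(floor((centre2 + background) / 2)))
  bg_mean <- range_sum(bg_from, bg_to) / (bg_to - bg_from)

  masked <- bg_mean == 0
  value <- ifelse(masked, NA_real_, num / bg_mean)

  new_enrichment_track(
    start = starts, value = value, masked = masked,
    replicon = track_replicon(track), window = window, step = step,
    background = background, replicon_length = len
  )
}

#' Subtract control enrichment from sample enrichment
#'
#' Element-wise difference of two enrichment tracks computed with identical
#' geometry, typically a ChIP sample minus the mock/deletion-strain control.
#' A window masked in either input is masked in the output. One control may
#' be reused against samples from several conditions or time points.
#'
#' @param sample,control `enrichment_track`s over the same replicon with the
#'   same window, step and background.
#' @return An `enrichment_track` of the differences.
#' @examples
#' tr <- depth_track(rpois(6000, 20))
#' e <- windowed_enrichment(tr)
#' d <- subtract_control(e, e)
#' all(d$value == 0)
#' @export
subtract_control <- function(sample, control) {
  for (x in list(sample, control)) {
    if (!inherits(x, "enrichment_track")) {
      abort("`sample` and `control` must be enrichment_tracks.")
    }
  }
  stopifnot_same_params(sample, control)
  masked <- sample$masked | control$masked
  value <- ifelse(masked, NA_real_, sample$value - control$value)
  p <- enrichment_params(sample)
  new_enrichment_track(
    start = sample$start, value = value, masked = masked,
    replicon = p$replicon, window = p$window, step = p$step,
    background = p$background, replicon_length = p$replicon_length
  )
}

#' Average replicate enrichment tracks
#'
#' Per-window mean over the replicates in which the window is unmasked; a
#' window is masked in the output only when it is masked in every input.
#'
#' @param tracks A list of `enrichment_track`s with identical geometry.
#' @return An `enrichment_track` of per-window means.
#' @export
average_replicates <- function(tracks) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    abort("`tracks` must be a non-empty list of enrichment_tracks.")
  }
  for (x in tracks) {
    if (!inherits(x, "enrichment_track")) {
      abort("Every element of `tracks` must be an enrichment_track.")
    }
  }
  for (x in tracks[-1]) stopifnot_same_params(tracks[[1]], x)

  vals <- vapply(tracks, function(x) x$value, numeric(nrow(tracks[[1]])))
  vals <- matrix(vals, nrow = nrow(tracks[[1]]))
  value <- rowMeans(vals, na.rm = TRUE)
  masked <- rowSums(!is.na(vals)) == 0L
  value[masked] <- NA_real_

  p <- enrichment_params(tracks[[1]])
  new_enrichment_track(
    start = tracks[[1]]$start, value = value, masked = masked,
    replicon = p$replicon, window = p$window, step = p$step,
    background = p$background, replicon_length = p$replicon_length
  )
}

#' Call enriched regions from an enrichment track
#'
#' Finds maximal runs of at least `min_consecutive` consecutive unmasked
#' windows with value at or above `threshold` and merges each run into one
#' half-open region spanning from the first window's start to the last
#' window's end. Requiring two or more consecutive windows suppresses
#' single-window noise spikes.
#'
#' @param track An `enrichment_track` (typically control-subtracted).
#' @param threshold Minimum enrichment value for a window to qualify.
#' @param min_consecutive Minimum run length in windows (default 2).
#' @return A tibble with columns `start`, `end` (0-based half-open nt),
#'   `peak_value` and `n_windows`; zero rows when nothing qualifies.
#' @export
call_enriched_windows <- function(track, threshold, min_consecutive = 2L) {
  if (!inherits(track, "enrichment_track")) abort("`track` must be an enrichment_track.")
  assert_scalar_num(threshold, "threshold")
  min_consecutive <- as.integer(assert_scalar_num(min_consecutive, "min_consecutive", positive = TRUE))
  p <- enrichment_params(track)

  ok <- !track$masked & !is.na(track$value) & track$value >= threshold
  empty <- tibble(
    start = integer(0), end = integer(0),
    peak_value = numeric(0), n_windows = integer(0)
  )
  if (!any(ok)) return(empty)

  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consecutive
  if (!any(keep)) return(empty)

  purrr::map2(run_start[keep], run_end[keep], function(i, j) {
    tibble(
      start = track$start[i],
      end = track$start[j] + p$window,
      peak_value = max(track$value[i:j]),
      n_windows = j - i + 1L
    )
  }) |> list_rbind()
}
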