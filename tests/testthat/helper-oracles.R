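# Independent oracles and small fixture builders. The oracles are written
# as plain explicit loops on the defining formulas, deliberately sharing no
# code with the package internals.

# Per-window enrichment recomputed naively: explicit mean() over the window
# and over the clipped centred background, no incremental sums.
oracle_enrichment <- function(depth, window, step, background) {
  len <- length(depth)
  starts <- seq(0, len - window, by = step)
  vals <- numeric(length(starts))
  masked <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    num <- mean(depth[(s + 1):(s + window)])
    centre <- s + window / 2
    from <- max(0, floor(centre - background / 2))
    to <- min(len, floor(centre + background / 2))
    bg <- mean(depth[(from + 1):to])
    if (bg == 0) {
      masked[i] <- TRUE
      vals[i] <- NA_real_
    } else {
      vals[i] <- num / bg
    }
  }
  list(start = starts, value = vals, masked = masked)
}

# Naive degenerate-consensus scan: explicit position-by-position comparison
# against the IUPAC sets, counting mismatches at concrete positions only.
oracle_scan <- function(seq, consensus, max_mismatch = 0) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"), X = c("A", "C", "G", "T")
  )
  sc <- strsplit(seq, "")[[1]]
  cc <- strsplit(toupper(consensus), "")[[1]]
  k <- length(cc)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  if (length(sc) < k) return(hits)
  for (s in 0:(length(sc) - k)) {
    mm <- 0
    ok <- TRUE
    for (j in seq_len(k)) {
      set <- sets[[cc[j]]]
      if (length(set) == 1) {
        if (sc[s + j] != set) mm <- mm + 1
        if (mm > max_mismatch) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) hits <- rbind(hits, data.frame(start = s, mismatches = mm))
  }
  hits
}

# All same-strand substring pairs (explicit Hamming) that could seed a
# direct-repeat family: non-overlapping, within max_span, distance <=
# max_mismatch, both units above the entropy cutoff.
oracle_repeat_pairs <- function(seq, k, max_mismatch, max_span) {
  sc <- strsplit(seq, "")[[1]]
  L <- length(sc)
  entropy_ok <- function(s) {
    p <- table(sc[(s + 1):(s + k)])
    p <- p / sum(p)
    -sum(p * log2(p)) >= 1
  }
  pairs <- list()
  for (i in 0:(L - 2 * k)) {
    for (j in (i + k):(L - k)) {
      if (j + k - i > max_span) break
      d <- sum(sc[(i + 1):(i + k)] != sc[(j + 1):(j + k)])
      if (d <= max_mismatch && entropy_ok(i) && entropy_ok(j)) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  pairs
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_lines_tmp <- function(lines, ext = ".bedgraph") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Enrichment track with prescribed window values, for region-calling and
# averaging tests (bypasses windowed_enrichment on purpose).
manual_enrichment <- function(values, masked = rep(FALSE, length(values)),
                              window = 30L, step = 15L, background = 3000L) {
  starts <- (seq_along(values) - 1L) * step
  regbind:::new_enrichment_track(
    start = starts, value = values, masked = masked,
    replicon = "manual", window = window, step = step,
    background = background,
    replicon_length = max(starts) + window
  )
}
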