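test_that("bedGraph reading follows interval semantics and validates input", {
  p <- write_lines_tmp("chr\t0\t10\t5")
  tr <- read_depth(p, "bedGraph", replicon_length = 20)
  expect_identical(tr$depth, c(rep(5, 10), rep(0, 10)))
  expect_identical(attr(tr, "replicon"), "chr")

  # empty file -> all-zero track
  empty <- read_depth(write_lines_tmp(character(0)), "bedGraph",
                      replicon_length = 15)
  expect_identical(empty$depth, rep(0, 15))

  # overlap, malformed line (named by number), past-end, negative depth
  expect_error(
    read_depth(write_lines_tmp(c("chr\t0\t10\t5", "chr\t5\t15\t2")),
               "bedGraph", replicon_length = 20),
    "Overlapping"
  )
  expect_error(
    read_depth(write_lines_tmp(c("chr\t0\t10\t5", "chr\t12\tnope")),
               "bedGraph", replicon_length = 20),
    "line 2"
  )
  expect_error(
    read_depth(write_lines_tmp("chr\t0\t30\t5"), "bedGraph",
               replicon_length = 20),
    "past the replicon end"
  )
  expect_error(
    read_depth(write_lines_tmp("chr\t0\t10\t-2"), "bedGraph",
               replicon_length = 20),
    "non-negative"
  )

  # track/comment lines are ignored
  with_header <- write_lines_tmp(c("track type=bedGraph", "# note", "chr\t2\t4\t7"))
  expect_identical(read_depth(with_header, "bedGraph", 6)$depth,
                   c(0, 0, 7, 7, 0, 0))
})

test_that("fixed-step wiggle reading honours start, step and span", {
  p <- write_lines_tmp(c("fixedStep chrom=chr start=3 step=2 span=2",
                         "4", "6"), ext = ".wig")
  tr <- read_depth(p, "wiggle", replicon_length = 10)
  # 1-based start 3 -> 0-based 2; span 2 at positions 2-3 then 4-5
  expect_identical(tr$depth, c(0, 0, 4, 4, 6, 6, 0, 0, 0, 0))

  expect_error(
    read_depth(write_lines_tmp(c("variableStep chrom=chr", "1 5"), ext = ".wig"),
               "wiggle", 10),
    "fixedStep"
  )
  expect_error(
    read_depth(write_lines_tmp(c("fixedStep chrom=chr start=9 step=1", "1", "2", "3"),
                               ext = ".wig"),
               "wiggle", 10),
    "past the replicon end"
  )
})

test_that("windowed enrichment matches the defining formula", {
  # flat positive depth -> exactly 1 everywhere
  flat <- windowed_enrichment(depth_track(rep(7, 9000)))
  expect_true(all(!flat$masked))
  expect_true(all(flat$value == 1))

  # hand-worked spike: 6000 nt of depth 1 with positions 3000-3029 at 11
  depth <- rep(1, 6000)
  depth[3001:3030] <- 11
  e <- windowed_enrichment(depth_track(depth))
  expect_equal(e$value[e$start == 3000], 10.0, tolerance = 1e-12)

  # all-zero depth -> every window masked
  zero <- windowed_enrichment(depth_track(rep(0, 6000)))
  expect_true(all(zero$masked))

  # expected number of windows
  expect_identical(nrow(e), 399L) # floor((6000 - 30)/15) + 1

  expect_error(windowed_enrichment(depth_track(rep(1, 20))), "shorter")
  expect_error(windowed_enrichment(depth_track(rep(1, 100)), window = 50,
                                   background = 40), "at least")
})

test_that("windowed enrichment is scale invariant and agrees with the naive oracle", {
  set.seed(31)
  for (len in c(2000, 7919, 20000)) {
    depth <- rpois(len, 20) * rbinom(len, 1, 0.95) # occasional zero stretches
    tr <- depth_track(depth)
    e <- windowed_enrichment(tr)

    # scale invariance, exact
    e_scaled <- windowed_enrichment(depth_track(depth * 3.7))
    expect_identical(e$masked, e_scaled$masked)
    expect_equal(e$value, e_scaled$value, tolerance = 1e-12)

    # naive per-window recomputation to 1e-9
    o <- oracle_enrichment(depth, 30, 15, 3000)
    expect_identical(e$start, as.integer(o$start))
    expect_identical(e$masked, o$masked)
    expect_equal(e$value, o$value, tolerance = 1e-9)
  }
  # non-default geometry against the oracle too
  depth <- rpois(3000, 5)
  e <- windowed_enrichment(depth_track(depth), window = 50, step = 7,
                           background = 500)
  o <- oracle_enrichment(depth, 50, 7, 500)
  expect_equal(e$value, o$value, tolerance = 1e-9)
})

test_that("control subtraction is exact and propagates masks", {
  set.seed(33)
  tr <- depth_track(rpois(9000, 30))
  e <- windowed_enrichment(tr)

  self <- subtract_control(e, e)
  expect_true(all(self$value[!self$masked] == 0))

  a <- manual_enrichment(c(10, 4, 2))
  b <- manual_enrichment(c(1, 2, 5), masked = c(FALSE, TRUE, FALSE))
  d <- subtract_control(a, b)
  expect_equal(d$value, c(9, NA, -3))
  expect_identical(d$masked, c(FALSE, TRUE, FALSE))

  # geometry mismatch rejected
  e2 <- windowed_enrichment(tr, window = 60, background = 3000)
  expect_error(subtract_control(e, e2), "window")
})

test_that("replicate averaging is mask-aware", {
  a <- manual_enrichment(c(2, 2, 8))
  b <- manual_enrichment(c(4, 6, 1), masked = c(FALSE, TRUE, FALSE))
  avg <- average_replicates(list(a, b))
  expect_equal(avg$value, c(3, 2, 4.5)) # masked replicate drops out
  expect_identical(avg$masked, c(FALSE, FALSE, FALSE))

  both_masked <- average_replicates(list(
    manual_enrichment(c(1, 2), masked = c(TRUE, FALSE)),
    manual_enrichment(c(3, 4), masked = c(TRUE, FALSE))
  ))
  expect_identical(both_masked$masked, c(TRUE, FALSE))

  single <- average_replicates(list(a))
  expect_equal(single$value, a$value)
  expect_error(average_replicates(list()), "non-empty")
})

test_that("region calling merges runs of consecutive windows", {
  tr <- manual_enrichment(c(0, 5, 5, 0))
  regions <- call_enriched_windows(tr, threshold = 2, min_consecutive = 2)
  expect_identical(nrow(regions), 1L)
  expect_identical(regions$start, 15L)
  expect_identical(regions$end, 60L)
  expect_identical(regions$n_windows, 2L)
  expect_equal(regions$peak_value, 5)

  expect_identical(nrow(call_enriched_windows(manual_enrichment(rep(0, 6)), 2)), 0L)
  # a lone above-threshold window is too short a run
  expect_identical(
    nrow(call_enriched_windows(manual_enrichment(c(0, 9, 0)), 2)), 0L
  )
  # masked windows break runs
  broken <- manual_enrichment(c(5, 5, 5, 5), masked = c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(call_enriched_windows(broken, 2)$n_windows, 2L)
})

test_that("enrichment bedGraph output round-trips", {
  tr <- manual_enrichment(c(1.25, 3.141593, 0.5), masked = c(FALSE, FALSE, FALSE))
  path <- tempfile(fileext = ".bedgraph")
  write_enrichment(tr, path)
  lines <- readLines(path)
  expect_identical(length(lines), 4L) # header + 3 windows
  iv <- read_bedgraph(path)
  expect_equal(iv$value, tr$value, tolerance = 1e-6)
  expect_identical(iv$start, tr$start)
  expect_identical(iv$end, tr$start + 15L)

  all_masked <- manual_enrichment(c(1, 2), masked = c(TRUE, TRUE))
  path2 <- tempfile(fileext = ".bedgraph")
  write_enrichment(all_masked, path2)
  expect_identical(length(readLines(path2)), 1L) # header only

  expect_error(write_enrichment(tr, file.path(tempdir(), "no", "such", "dir", "x")),
               "Cannot write")
})

test_that("simulated fold-10 site is recovered at the right place", {
  sim <- simulate_chip_tracks(20000, base_depth = 100,
                              sites = data.frame(center = 10000, fold = 10),
                              fragment_width = 600, seed = 41)
  diff <- subtract_control(windowed_enrichment(sim$sample),
                           windowed_enrichment(sim$control))
  peak_start <- diff$start[which.max(diff$value)]
  expect_lt(abs(peak_start + 15 - 10000), 600)
  # peak height matches the analytic expectation of the subtracted statistic
  expected <- expected_site_enrichment(10, 600) - 1
  expect_lt(abs(max(diff$value, na.rm = TRUE) - expected) / expected, 0.35)
})
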