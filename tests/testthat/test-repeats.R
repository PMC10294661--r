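test_that("consensus scanning matches the naive IUPAC oracle", {
  seq1 <- paste0("TTTTT", "CGAACTCAAC", "TTTTT")
  hits <- scan_consensus(seq1, "CGXXCTCAAC")
  expect_identical(hits$start, 5L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$matched_seq, "CGAACTCAAC")

  # shorter than the consensus -> empty
  expect_identical(nrow(scan_consensus("CGAAC", "CGXXCTCAAC")), 0L)

  # degenerate positions never count as mismatches; concrete ones do
  probe <- paste0("AAAAA", "CGTTCTCAAG", "AAAAA") # last base breaks C
  expect_identical(nrow(scan_consensus(probe, "CGXXCTCAAC", max_mismatch = 0)), 0L)
  h1 <- scan_consensus(probe, "CGXXCTCAAC", max_mismatch = 1)
  expect_identical(h1$start, 5L)
  expect_identical(h1$mismatches, 1L)

  # oracle equivalence on random sequences, several consensi and mismatch caps
  for (s in 1:4) {
    rnd <- random_dna(300, seed = 70 + s)
    for (cons in c("CGXXCTCAAC", "GANNTC", "RYSWKM")) {
      for (mm in 0:1) {
        got <- scan_consensus(rnd, cons, max_mismatch = mm)
        want <- oracle_scan(rnd, cons, max_mismatch = mm)
        expect_identical(got$start, as.integer(want$start))
        expect_identical(got$mismatches, as.integer(want$mismatches))
      }
    }
  }

  # zero-mismatch scanning of a concrete pattern equals substring matching
  rnd <- random_dna(500, seed = 79)
  got <- scan_consensus(rnd, "ACGT")$start
  naive <- as.integer(gregexpr("(?=ACGT)", rnd, perl = TRUE)[[1]]) - 1L
  naive <- naive[naive >= 0]
  expect_identical(got, naive)

  expect_error(scan_consensus("ACGT", "CGO"), "Invalid IUPAC")
})

test_that("reverse-strand scanning reports hits in forward coordinates", {
  core <- "CGAACTCAAC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(core)))
  seq1 <- paste0("AAAAA", rc, "AAAAA")
  both <- scan_consensus(seq1, "CGXXCTCAAC", both_strands = TRUE)
  minus <- both[both$strand == "-", ]
  expect_identical(minus$start, 5L)
  expect_identical(minus$matched_seq, rc)
  # plus-only scan ignores it
  expect_identical(nrow(scan_consensus(seq1, "CGXXCTCAAC")), 0L)
})

test_that("planted motifs are always recovered by the scanner", {
  for (s in 1:5) {
    g <- make_genome(400, gc_fraction = 0.72, seed = s)
    starts <- c(30, 120, 250, 350)
    planted <- plant_motifs(g, "CGXXCTCAAC", starts, seed = s)
    hits <- scan_consensus(planted$sequence, "CGXXCTCAAC")
    expect_true(all(starts %in% hits$start))
    expect_gte(nrow(hits), length(starts))
  }
})

test_that("direct-repeat discovery finds constructed families and drops noise", {
  # two exact copies of a 10-mer separated by 7 nt -> one family, spacing 17
  unit <- "GACGTTCAGC"
  s <- paste0("ATGCATGCAT", unit, "TTAACCG", unit, "CAGTTACGGA")
  fam <- find_direct_repeats(s)
  expect_identical(nrow(fam), 1L)
  expect_identical(fam$n_members, 2L)
  expect_identical(fam$unit_length, 10L)
  expect_identical(fam$starts[[1]], c(10L, 27L))
  expect_identical(fam$spacings[[1]], 17L)
  expect_identical(fam$consensus, unit)

  # homopolymer units fall below the 1 bit/base entropy cutoff
  expect_identical(nrow(find_direct_repeats(strrep("A", 80))), 0L)
  expect_identical(nrow(find_direct_repeats(strrep("C", 80))), 0L)

  # flank invariance: adding distant random flanks does not change the family
  flanked <- paste0(random_dna(60, seed = 81), s, random_dna(60, seed = 82))
  fam2 <- find_direct_repeats(flanked)
  core_fam <- fam2[vapply(fam2$starts, function(x) 70 %in% x, logical(1)), ]
  expect_identical(core_fam$starts[[1]] - 60L, fam$starts[[1]])
  expect_identical(core_fam$consensus, fam$consensus)

  expect_error(find_direct_repeats("ACGT", min_len = 10, max_len = 8), "min_len")
  expect_error(find_direct_repeats(random_dna(10001, seed = 1)), "10 kb")
})

test_that("reported families are sound and complete against the pair oracle", {
  rnd <- paste0(
    random_dna(80, seed = 91), "TCGGATCAAG", random_dna(15, seed = 92),
    "TCGGATCAAG", random_dna(80, seed = 93)
  )
  max_span <- nchar(rnd)
  fams <- find_direct_repeats(rnd, min_len = 8, max_len = 12, max_mismatch = 0)

  # soundness: every family member pair is a genuine oracle pair
  for (i in seq_len(nrow(fams))) {
    k <- fams$unit_length[i]
    starts <- fams$starts[[i]]
    oracle <- oracle_repeat_pairs(rnd, k, 0, max_span)
    key <- vapply(oracle, paste, character(1), collapse = "-")
    combos <- utils::combn(starts, 2, simplify = FALSE)
    for (pr in combos) {
      expect_true(paste(pr, collapse = "-") %in% key)
    }
  }

  # completeness: every oracle pair is covered by some reported family
  for (k in 8:12) {
    oracle <- oracle_repeat_pairs(rnd, k, 0, max_span)
    for (pr in oracle) {
      covered <- any(vapply(seq_len(nrow(fams)), function(i) {
        m <- fams$starts[[i]]
        ku <- fams$unit_length[i]
        both <- vapply(pr, function(p) {
          any(p < m + ku & m < p + k)
        }, logical(1))
        all(both)
      }, logical(1)))
      expect_true(covered)
    }
  }
})

test_that("column consensus follows the declared policies", {
  members <- c("CGAACTCAAC", "CGTTCTCAAC", "CGGTCTCAAC")
  expect_identical(consensus_of(members, policy = "strict"), "CGXXCTCAAC")
  # minimal IUPAC covers observed bases with the smallest code
  expect_identical(consensus_of(c("CACGT", "CGCGT")), "CRCGT")
  expect_identical(consensus_of(members),
                   paste0("CG", "D", "W", "CTCAAC")) # A/T/G -> D, A/T -> W
  expect_identical(consensus_of(c("ACGT", "ACGT")), "ACGT")
  # all four bases at a column -> X
  expect_identical(consensus_of(c("AA", "CA", "GA", "TA")), "XA")

  # hit-table input uses matched_seq
  hits <- scan_consensus(paste0("T", "CGAACTCAAC", "T", "CGTTCTCAAC"), "CGXXCTCAAC")
  expect_identical(consensus_of(hits, policy = "strict"), "CGXXCTCAAC")

  expect_error(consensus_of(c("ACG", "ACGT")), "equal length")
  expect_error(consensus_of("ACGT"), "two members")
})
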