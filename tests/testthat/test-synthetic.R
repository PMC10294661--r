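test_that("genome generation respects length, composition and seeding", {
  expect_identical(make_genome(0)$sequence, "")
  expect_identical(nrow(make_genome(0)$planted_sites), 0L)

  gc_only <- make_genome(100, gc_fraction = 1, seed = 3)
  expect_true(grepl("^[GC]+$", gc_only$sequence))

  at_only <- make_genome(100, gc_fraction = 0, seed = 3)
  expect_true(grepl("^[AT]+$", at_only$sequence))

  g <- make_genome(10000, gc_fraction = 0.5, seed = 1)
  gc_obs <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  three_sd <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(gc_obs - 0.5), three_sd)

  expect_identical(make_genome(500, seed = 7)$sequence,
                   make_genome(500, seed = 7)$sequence)
  expect_false(make_genome(500, seed = 7)$sequence ==
                 make_genome(500, seed = 8)$sequence)

  expect_error(make_genome(-5), "length")
  expect_error(make_genome(10, gc_fraction = 1.5), "gc_fraction")
})

test_that("motif planting writes consensus realizations without side effects", {
  g <- make_genome(60, seed = 42)
  planted <- plant_motifs(g, "CGXXCTCAAC", starts = c(5, 25, 45), seed = 42)

  expect_identical(nrow(planted$planted_sites), 3L)
  for (i in 1:3) {
    s <- planted$planted_sites$start[i]
    inst <- substring(planted$sequence, s + 1, s + 10)
    expect_identical(inst, planted$planted_sites$motif_instance[i])
    expect_identical(nrow(oracle_scan(inst, "CGXXCTCAAC")), 1L)
  }
  # untouched positions unchanged
  outside <- setdiff(0:59, c(5:14, 25:34, 45:54))
  expect_identical(
    strsplit(planted$sequence, "")[[1]][outside + 1],
    strsplit(g$sequence, "")[[1]][outside + 1]
  )

  expect_identical(plant_motifs(g, "CGXXCTCAAC", integer(0)), g)
  expect_error(plant_motifs(g, "CGXXCTCAAC", c(5, 10)), "overlap")
  expect_error(plant_motifs(g, "CGXXCTCAAC", 55), "past the genome end")
  expect_identical(
    plant_motifs(g, "CGXXCTCAAC", c(5, 25), seed = 1)$sequence,
    plant_motifs(g, "CGXXCTCAAC", c(5, 25), seed = 1)$sequence
  )
})

test_that("chip simulator reproduces its null and its analytic peak expectation", {
  # null: no sites, sample and control depths agree within 3 standard errors
  sim <- simulate_chip_tracks(20000, base_depth = 50, seed = 11)
  se <- sqrt(2 * 50 / 20000)
  expect_lt(abs(mean(sim$sample$depth) - mean(sim$control$depth)), 3 * se)

  # determinism
  sim2 <- simulate_chip_tracks(20000, base_depth = 50, seed = 11)
  expect_identical(sim$sample$depth, sim2$sample$depth)

  # fold = 1 site is a null: subtracted enrichment centred on 0
  flat <- simulate_chip_tracks(12000, base_depth = 100,
                               sites = data.frame(center = 6000, fold = 1),
                               seed = 5)
  d <- subtract_control(windowed_enrichment(flat$sample),
                        windowed_enrichment(flat$control))
  expect_lt(abs(mean(d$value, na.rm = TRUE)), 3 * sd(d$value, na.rm = TRUE) /
              sqrt(sum(!d$masked)))

  # replicate-averaged windowed enrichment at a planted fold-10 site
  # converges to the closed-form expectation of the statistic (the 3000-nt
  # background contains the whole 1200-nt peak, so the expected ratio is
  # well below the planted fold)
  expected <- expected_site_enrichment(10, fragment_width = 600)
  vals <- vapply(1:25, function(s) {
    sim <- simulate_chip_tracks(12000, base_depth = 100,
                                sites = data.frame(center = 6000, fold = 10),
                                seed = 100 + s)
    e <- windowed_enrichment(sim$sample)
    e$value[which.min(abs(e$start + 15 - 6000))]
  }, numeric(1))
  expect_lt(abs(mean(vals) - expected) / expected, 0.05)
})

test_that("spr simulator matches the closed-form occupancy model", {
  region <- random_dna(34, seed = 21)
  spans <- data.frame(label = c("DR1", "DR2", "DR3"),
                      start = c(0, 12, 24), end = c(10, 22, 34))
  designs <- substitution_series(region, spans, seed = 2)
  energies <- c(DR1 = -0.5, DR2 = -1.5, DR3 = -2.5)

  # zero noise: %Rmax equals 100 * c / (c + KD) to 1e-6
  cycles <- simulate_spr_cycles(designs, energies, baseline_kd = 1e-6,
                                protein_conc = 5e-7, noise_sd = 0, seed = 1)
  res <- analyze_cycles(cycles, designs, analyte_mw = 28000)
  rt <- 0.593
  for (i in seq_len(nrow(designs))) {
    kd <- 1e-6 * exp(sum(energies[designs$intact_repeats[[i]]]) / rt)
    theta <- 5e-7 / (5e-7 + kd)
    got <- res$percent_rmax[res$design_id == designs$design_id[i]]
    expect_lt(abs(got - 100 * theta), 1e-6)
  }

  # saturation: conc 1e4-fold above KD -> %Rmax = 100 within 0.1
  sat <- simulate_spr_cycles(designs[1, ], energies, baseline_kd = 1e-9,
                             protein_conc = 1e-9 * exp(sum(energies) / rt) * 1e4,
                             noise_sd = 0, seed = 1)
  sat_res <- analyze_cycles(sat, designs[1, ], analyte_mw = 28000)
  expect_lt(abs(sat_res$percent_rmax - 100), 0.1)

  # no binding: no intact repeats and KD far above conc
  bare <- designs[nrow(designs), ]
  bare$intact_repeats <- list(character(0))
  none <- simulate_spr_cycles(bare, energies, baseline_kd = 1e-3,
                              protein_conc = 1e-9, noise_sd = 0, seed = 1)
  expect_lt(analyze_cycles(none, bare, analyte_mw = 28000)$percent_rmax, 0.001)

  # conc = KD: %Rmax = 50 within 0.1
  half <- simulate_spr_cycles(bare, energies, baseline_kd = 1e-7,
                              protein_conc = 1e-7, noise_sd = 0, seed = 1)
  expect_lt(abs(analyze_cycles(half, bare, analyte_mw = 28000)$percent_rmax - 50), 0.1)

  # annotation is mandatory
  unannotated <- designs["design_id" != "", c("design_id", "test_seq", "bottom_strand")]
  expect_error(simulate_spr_cycles(unannotated, energies, 1e-6, 1e-6),
               "intact_repeats")
  expect_error(
    simulate_spr_cycles(dplyr::mutate(designs, intact_repeats = list("DR9")),
                        energies, 1e-6, 1e-6),
    "DR9"
  )
})

test_that("count simulator has the right moments and planted effects", {
  # dispersion -> 0 gives the Poisson limit: variance ~ mean over 1000 genes
  sim0 <- simulate_counts(1000, 50, 500 * 1000, dispersion = 0,
                          de_fraction = 0, seed = 13)
  m <- rowMeans(sim0$counts)
  v <- apply(sim0$counts, 1, var)
  keep <- m > 50
  expect_lt(abs(median(v[keep] / m[keep]) - 1), 0.1)

  # null: empirical log2FC distribution centred on 0
  simn <- simulate_counts(2000, 3, 500 * 2000, de_fraction = 0, seed = 17)
  den <- cpm_ttest_de(simn$counts, simn$groups)
  expect_lt(abs(median(den$log2fc)), 0.05)

  # planted log2fc = 3 at 3 reps/group, mean depth 500: median estimate
  # within +/- 0.5 (CPM normalisation absorbs part of the composition shift)
  simd <- simulate_counts(2000, 3, 500 * 2000, de_fraction = 0.05,
                          de_log2fc = 3, seed = 19)
  ded <- cpm_ttest_de(simd$counts, simd$groups)
  expect_lt(abs(median(ded$log2fc[simd$truth$is_de]) - 3), 0.5)

  # truth table is consistent
  expect_identical(simd$truth$is_de, simd$truth$true_log2fc != 0)

  # raw group-mean ratio converges to 2^log2fc as replication grows
  simb <- simulate_counts(400, 60, 500 * 400, de_fraction = 0.1,
                          de_log2fc = 2, seed = 23)
  g1 <- rowMeans(simb$counts[, simb$groups == "group1"])
  g2 <- rowMeans(simb$counts[, simb$groups == "group2"])
  ratio <- median((g2 / g1)[simb$truth$is_de])
  expect_lt(abs(ratio - 4) / 4, 0.1)

  expect_identical(simulate_counts(100, 2, 1e4, seed = 1)$counts,
                   simulate_counts(100, 2, 1e4, seed = 1)$counts)
})
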