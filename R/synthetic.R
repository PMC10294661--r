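## Seeded synthetic-data generators.
##
## Each generator is a pure function of its arguments including the seed, so
## every downstream stage of the package is testable without external data.
## The simulators carry the statistical structure the analysis stages assume:
## Poisson depth tracks with fragment-scale (~600 nt) triangular enrichment
## around planted binding sites, equilibrium-occupancy SPR responses whose
## affinity depends on which direct repeats are intact, and negative-binomial
## count matrices with planted log2 fold changes.

# Gas constant x temperature at 25 degrees C, in kcal/mol; SPR runs at 25 C.
RT_KCAL_MOL <- 0.593

#' Generate a random synthetic genome
#'
#' Bases are drawn independently with the given GC fraction (G and C equally
#' likely within the GC share, A and T within the AT share).
#'
#' @param length Genome length in nt (>= 0).
#' @param gc_fraction Probability that a position is G or C, in \[0, 1\].
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param name Label for the replicon.
#' @return A `synthetic_genome`: a list with `name`, `sequence` (A/C/G/T
#'   string) and `planted_sites` (tibble of `start`, `motif_instance`,
#'   `label`; empty until [plant_motifs()] is used).
#' @examples
#' g <- make_genome(100, gc_fraction = 0.72, seed = 1)  # Streptomyces-like GC
#' nchar(g$sequence)
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed = NULL,
                        name = "synthetic") {
  assert_scalar_num(length, "length", nonneg = TRUE)
  assert_scalar_num(gc_fraction, "gc_fraction", nonneg = TRUE)
  if (gc_fraction > 1) abort("`gc_fraction` must be in [0, 1].")
  length <- as.integer(length)

  probs <- c(
    A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2
  )
  sequence <- with_seed(seed, {
    if (length == 0L) "" else
      paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
  })
  new_synthetic_genome(name, sequence)
}

new_synthetic_genome <- function(name, sequence,
                                 planted_sites = tibble(
                                   start = integer(0),
                                   motif_instance = character(0),
                                   label = character(0)
                                 )) {
  structure(
    list(name = name, sequence = sequence, planted_sites = planted_sites),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> '%s', %d nt, %d planted site(s)\n",
    x$name, nchar(x$sequence), nrow(x$planted_sites)
  ))
  invisible(x)
}

# Sample one concrete realization of a degenerate IUPAC consensus.
realize_consensus <- function(consensus) {
  sets <- iupac_sets(consensus)
  paste(vapply(sets, function(s) if (length(s) == 1L) s else sample(s, 1L),
               character(1)), collapse = "")
}

#' Plant motif instances into a synthetic genome
#'
#' Each planted instance is an independently sampled realization of the
#' degenerate consensus (each degenerate position drawn uniformly from the
#' bases its IUPAC code covers), written over the genome at the given
#' 0-based starts. Instances must fit inside the genome and must not overlap
#' one another; positions outside the planted spans are unchanged.
#'
#' @param genome A `synthetic_genome`.
#' @param consensus Degenerate DNA string (IUPAC codes; `X` means any base).
#' @param starts Integer vector of 0-based start offsets (may be empty).
#' @param seed Integer seed for the degenerate-position draws.
#' @param labels Optional labels, one per start (default `site1`, `site2`, ...).
#' @return The genome with the instances written in and `planted_sites`
#'   extended.
#' @examples
#' g <- make_genome(60, seed = 42)
#' g <- plant_motifs(g, "CGXXCTCAAC", starts = c(5, 25, 45), seed = 42)
#' g$planted_sites
#' @export
plant_motifs <- function(genome, consensus, starts, seed = NULL,
                         labels = NULL) {
  if (!inherits(genome, "synthetic_genome")) {
    abort("`genome` must be a synthetic_genome.")
  }
  sets <- iupac_sets(consensus) # validates the consensus
  k <- length(sets)
  starts <- as.integer(starts)
  if (length(starts) == 0L) return(genome)
  if (anyNA(starts) || any(starts < 0)) abort("`starts` must be non-negative offsets.")
  len <- nchar(genome$sequence)
  if (any(starts + k > len)) {
    abort(sprintf("Motif instance extends past the genome end (%d nt).", len))
  }
  o <- order(starts)
  if (any(diff(starts[o]) < k)) abort("Planted motif instances overlap.")
  labels <- labels %||% paste0("site", seq_along(starts))
  if (length(labels) != length(starts)) abort("One label per start is required.")

  instances <- with_seed(seed, vapply(starts, function(s) realize_consensus(consensus),
                                      character(1)))
  chars <- seq_chars(genome$sequence)
  for (i in seq_along(starts)) {
    chars[(starts[i] + 1L):(starts[i] + k)] <- seq_chars(instances[i])
  }
  new_synthetic_genome(
    genome$name, paste(chars, collapse = ""),
    bind_rows(
      genome$planted_sites,
      tibble(start = starts, motif_instance = instances, label = labels)
    ) |> arrange(.data$start)
  )
}

#' Simulate paired ChIP and control depth tracks
#'
#' The control track is Poisson noise around a flat `base_depth`. The sample
#' track multiplies the base depth by an expected local fold
#' `f(pos) = 1 + sum_site (fold - 1) * max(0, 1 - |pos - center|/fragment_width)`:
#' a triangular kernel of half-width `fragment_width` centred on each site,
#' the coverage profile produced when sonication fragments of roughly
#' `fragment_width` nt (the 300-1000 bp, ~600 bp-centred range typical of
#' ChIP sonication) all contain the bound position.
#'
#' @param genome_length Replicon length in nt.
#' @param base_depth Mean background reads per nucleotide (> 0).
#' @param sites Data frame with columns `center` (nt) and `fold` (>= 1); may
#'   have zero rows for a null simulation.
#' @param fragment_width Kernel half-width in nt (default 600).
#' @param seed Integer seed; the same seed reproduces both tracks.
#' @param replicon Replicon name for the returned tracks.
#' @return A list with `sample` and `control` [depth_track()]s.
#' @examples
#' sim <- simulate_chip_tracks(20000, base_depth = 50,
#'                             sites = data.frame(center = 10000, fold = 10),
#'                             seed = 1)
#' @export
simulate_chip_tracks <- function(genome_length, base_depth,
                                 sites = data.frame(center = numeric(0),
                                                    fold = numeric(0)),
                                 fragment_width = 600, seed = NULL,
                                 replicon = "synthetic") {
  genome_length <- as.integer(assert_scalar_num(genome_length, "genome_length", positive = TRUE))
  assert_scalar_num(base_depth, "base_depth", positive = TRUE)
  assert_scalar_num(fragment_width, "fragment_width", positive = TRUE)
  sites <- as_tibble(sites)
  if (!all(c("center", "fold") %in% names(sites))) {
    abort("`sites` needs columns `center` and `fold`.")
  }
  if (nrow(sites) > 0L && any(sites$fold < 1)) abort("Site `fold` must be >= 1.")

  pos <- seq_len(genome_length) - 1L
  f <- rep(1, genome_length)
  for (i in seq_len(nrow(sites))) {
    f <- f + (sites$fold[i] - 1) *
      pmax(0, 1 - abs(pos - sites$center[i]) / fragment_width)
  }
  with_seed(seed, {
    list(
      sample = depth_track(rpois(genome_length, base_depth * f), replicon),
      control = depth_track(rpois(genome_length, base_depth), replicon)
    )
  })
}

#' Expected windowed enrichment of a simulated site
#'
#' Closed-form expectation of the [windowed_enrichment()] statistic at the
#' centre of one planted site, for a site far from the replicon ends: the
#' mean of the triangular fold profile over the small window divided by its
#' mean over the centred background window (which contains the whole peak
#' whenever `background >= 2 * fragment_width`, inflating the denominator
#' above 1 and making the expected ratio smaller than the planted fold).
#'
#' @param fold Planted fold (>= 1).
#' @param fragment_width Kernel half-width in nt.
#' @param window,background Window geometry as in [windowed_enrichment()].
#' @return Expected enrichment ratio at the site centre (dimensionless).
#' @export
expected_site_enrichment <- function(fold, fragment_width = 600, window = 30,
                                     background = 3000) {
  assert_scalar_num(fold, "fold", positive = TRUE)
  tri_mean <- function(half_extent) {
    # mean of max(0, 1 - |x|/fw) over x in [-half_extent, half_extent]
    fw <- fragment_width
    if (half_extent <= fw) 1 - half_extent / (2 * fw) else fw / (2 * half_extent)
  }
  num <- 1 + (fold - 1) * tri_mean(window / 2)
  den <- 1 + (fold - 1) * tri_mean(background / 2)
  num / den
}

#' Simulate SPR binding cycles for a set of capture duplexes
#'
#' Binding follows a single-site equilibrium-occupancy model. Each design's
#' dissociation constant is the baseline scaled by the free-energy
#' contributions of its intact repeats,
#' `KD = baseline_kd * exp(sum(ddG_intact) / RT)` with RT = 0.593 kcal/mol
#' (25 degrees C, the temperature SPR is run at), so negative ddG values
#' stabilise binding. Fractional occupancy is `theta = c / (c + KD)` at
#' analyte concentration `c`; the protein-phase response is
#' `theta * Rmax_theoretical` plus Gaussian noise, and the DNA-capture
#' response is `r_dna` plus Gaussian noise.
#'
#' @param designs Duplex design tibble (see [make_redcat_duplex()]) with a
#'   list-column `intact_repeats` naming the repeat labels left intact in
#'   each design.
#' @param repeat_energies Named numeric vector: ddG contribution of each
#'   repeat label in kcal/mol (negative = stabilising).
#' @param baseline_kd Dissociation constant with no intact repeats, molar.
#' @param protein_conc Analyte concentration, molar.
#' @param r_dna Mean DNA-capture response, response units (RU).
#' @param noise_sd Gaussian noise SD on both responses, RU.
#' @param analyte_mw Analyte molar mass in Da, used to compute each design's
#'   theoretical Rmax from its duplex mass.
#' @param n_replicates Replicate cycles per design.
#' @param seed Integer seed.
#' @return A tibble of cycles: `design_id`, `replicate`, `r_dna`,
#'   `r_protein`, plus the latent `kd` and `occupancy` used to generate them.
#' @export
simulate_spr_cycles <- function(designs, repeat_energies, baseline_kd,
                                protein_conc, r_dna = 100, noise_sd = 0,
                                analyte_mw = 28000, n_replicates = 1L,
                                seed = NULL) {
  designs <- as_tibble(designs)
  if (!"intact_repeats" %in% names(designs)) {
    abort("`designs` must carry an `intact_repeats` annotation column.")
  }
  if (!is.numeric(repeat_energies) || is.null(names(repeat_energies))) {
    abort("`repeat_energies` must be a named numeric vector (kcal/mol).")
  }
  assert_scalar_num(baseline_kd, "baseline_kd", positive = TRUE)
  assert_scalar_num(protein_conc, "protein_conc", nonneg = TRUE)
  assert_scalar_num(r_dna, "r_dna", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(analyte_mw, "analyte_mw", positive = TRUE)
  n_replicates <- as.integer(assert_scalar_num(n_replicates, "n_replicates", positive = TRUE))

  kd <- map_dbl(designs$intact_repeats, function(labels) {
    labels <- as.character(labels %||% character(0))
    if (length(labels) > 0L && !all(labels %in% names(repeat_energies))) {
      abort(sprintf(
        "Design annotation names repeat(s) not in `repeat_energies`: %s",
        paste(setdiff(labels, names(repeat_energies)), collapse = ", ")
      ))
    }
    baseline_kd * exp(sum(repeat_energies[labels]) / RT_KCAL_MOL)
  })
  theta <- protein_conc / (protein_conc + kd)
  mw_duplex <- map_dbl(seq_len(nrow(designs)), function(i) {
    dna_strand_mw(designs$test_seq[i]) + dna_strand_mw(designs$bottom_strand[i])
  })
  rmax <- theoretical_rmax(analyte_mw, mw_duplex, r_dna)

  with_seed(seed, {
    tidyr::expand_grid(i = seq_len(nrow(designs)), replicate = seq_len(n_replicates)) |>
      mutate(
        design_id = designs$design_id[.data$i],
        kd = kd[.data$i],
        occupancy = theta[.data$i],
        r_dna = r_dna + rnorm(n(), 0, noise_sd),
        r_protein = theta[.data$i] * rmax[.data$i] + rnorm(n(), 0, noise_sd)
      ) |>
      select("design_id", "replicate", "r_dna", "r_protein", "kd", "occupancy")
  })
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Two groups of `n_reps` samples each. Per-gene baseline means are drawn
#' from a gamma distribution scaled so the average per-gene depth is
#' `lib_size / n_genes`; a fraction `de_fraction` of genes get group-2 means
#' multiplied by `2^de_log2fc`. Counts are negative binomial with the given
#' dispersion (`variance = mu + dispersion * mu^2`); `dispersion = 0` gives
#' the Poisson limit. The default dispersion 0.01 corresponds to a
#' biological coefficient of variation of 0.1, the value typical of
#' replicate cultures of a genetically identical model organism; tissue
#' samples from outbred populations would need several-fold more.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per group.
#' @param lib_size Expected reads per sample.
#' @param dispersion NB dispersion (>= 0).
#' @param de_fraction Fraction of genes differentially expressed, in \[0, 1\].
#' @param de_log2fc Planted log2 fold change (group 2 over group 1) for DE
#'   genes.
#' @param seed Integer seed.
#' @return A list with `counts` (genes x samples integer matrix, groups in
#'   column names), `truth` (tibble `gene`, `true_log2fc`, `is_de`) and
#'   `groups` (named character vector sample -> group).
#' @export
simulate_counts <- function(n_genes, n_reps, lib_size, dispersion = 0.01,
                            de_fraction = 0.05, de_log2fc = 2, seed = NULL) {
  n_genes <- as.integer(assert_scalar_num(n_genes, "n_genes", positive = TRUE))
  n_reps <- as.integer(assert_scalar_num(n_reps, "n_reps", positive = TRUE))
  assert_scalar_num(lib_size, "lib_size", positive = TRUE)
  assert_scalar_num(dispersion, "dispersion", nonneg = TRUE)
  assert_scalar_num(de_fraction, "de_fraction", nonneg = TRUE)
  if (de_fraction > 1) abort("`de_fraction` must be in [0, 1].")
  assert_scalar_num(de_log2fc, "de_log2fc")

  with_seed(seed, {
    rel <- stats::rgamma(n_genes, shape = 2, rate = 2) # gene-to-gene spread
    mu1 <- rel / mean(rel) * lib_size / n_genes
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    true_lfc <- numeric(n_genes)
    true_lfc[de_idx] <- de_log2fc
    mu2 <- mu1 * 2^true_lfc

    draw <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    counts <- cbind(
      vapply(seq_len(n_reps), function(j) draw(mu1), numeric(n_genes)),
      vapply(seq_len(n_reps), function(j) draw(mu2), numeric(n_genes))
    )
    genes <- sprintf("gene%05d", seq_len(n_genes))
    samples <- c(paste0("g1_rep", seq_len(n_reps)), paste0("g2_rep", seq_len(n_reps)))
    dimnames(counts) <- list(genes, samples)
    groups <- setNames(rep(c("group1", "group2"), each = n_reps), samples)
    list(
      counts = counts,
      truth = tibble(gene = genes, true_log2fc = true_lfc, is_de = true_lfc != 0),
      groups = groups
    )
  })
}
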