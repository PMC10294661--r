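## SPR %Rmax analysis.
##
## SPR response is proportional to the mass bound at the sensor surface, so
## the theoretical maximum protein response for a captured DNA duplex is the
## captured-DNA response scaled by the analyte:ligand mass ratio (times the
## stoichiometry).  Observed protein responses expressed as a percentage of
## that maximum (%Rmax) are comparable across duplexes of different mass.

# Average monomer (nucleotide-5'-monophosphate) masses, Da.
DNMP_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
# Correction for the 5'-OH / free 3'-OH convention (loss of HPO3 + gain of H2O).
DNA_END_CORRECTION <- 61.96

#' Molecular weight of a single DNA strand
#'
#' Sum of average monomer masses (dAMP 313.21, dCMP 289.18, dGMP 329.21,
#' dTMP 304.20 Da) minus 61.96 Da for the 5'-OH, free 3'-OH convention used
#' for synthetic oligonucleotides.
#'
#' @param seq DNA string (A/C/G/T, non-empty).
#' @return Mass in Da.
#' @examples
#' dna_strand_mw("ACGT") # 1173.84
#' @export
dna_strand_mw <- function(seq) {
  seq <- assert_dna(seq, "seq")
  counts <- table(factor(seq_chars(seq), levels = DNA_BASES))
  sum(as.numeric(counts) * DNMP_MASS[DNA_BASES]) - DNA_END_CORRECTION
}

#' Molecular weight of a capture duplex
#'
#' Mass of the complete captured species: top (test) strand plus the bottom
#' strand including its 20-nt capture overhang.
#'
#' @param design A one-or-more-row design tibble (see [make_redcat_duplex()]).
#' @return Numeric vector of duplex masses in Da, one per design row.
#' @export
duplex_mw <- function(design) {
  design <- as_tibble(design)
  if (!all(c("test_seq", "bottom_strand") %in% names(design))) {
    abort("`design` needs columns `test_seq` and `bottom_strand`.")
  }
  vapply(seq_len(nrow(design)), function(i) {
    dna_strand_mw(design$test_seq[i]) + dna_strand_mw(design$bottom_strand[i])
  }, numeric(1))
}

#' Theoretical maximum SPR response
#'
#' `Rmax = (mw_analyte / mw_ligand) * r_ligand * stoichiometry`: the largest
#' response the analyte can give if every captured ligand molecule binds
#' `stoichiometry` analyte monomers.
#'
#' @param mw_analyte Analyte (protein) molar mass, Da.
#' @param mw_ligand Ligand (captured duplex) molar mass, Da; vectorised.
#' @param r_ligand Observed ligand-capture response, RU; vectorised.
#' @param stoichiometry Analyte monomers per ligand (default 1).
#' @return Theoretical maximum response in RU.
#' @examples
#' theoretical_rmax(30000, 24700, 100) # 121.457 RU
#' @export
theoretical_rmax <- function(mw_analyte, mw_ligand, r_ligand,
                             stoichiometry = 1) {
  assert_scalar_num(mw_analyte, "mw_analyte", positive = TRUE)
  assert_scalar_num(stoichiometry, "stoichiometry", positive = TRUE)
  if (!is.numeric(mw_ligand) || any(!is.finite(mw_ligand)) || any(mw_ligand <= 0)) {
    abort("`mw_ligand` must be positive and finite.")
  }
  if (!is.numeric(r_ligand) || any(!is.finite(r_ligand)) || any(r_ligand <= 0)) {
    abort("`r_ligand` must be positive and finite.")
  }
  (mw_analyte / mw_ligand) * r_ligand * stoichiometry
}

#' Express a response as a percentage of the theoretical maximum
#'
#' @param r_protein Observed analyte response, RU; vectorised.
#' @param rmax Theoretical maximum response, RU (> 0); vectorised.
#' @return `100 * r_protein / rmax`. Values slightly above 100 are permitted
#'   (instrument noise at saturation); values above 120 trigger a warning
#'   since they usually indicate a wrong mass or stoichiometry.
#' @examples
#' percent_rmax(60, 121.457) # 49.40
#' @export
percent_rmax <- function(r_protein, rmax) {
  if (!is.numeric(rmax) || any(!is.finite(rmax)) || any(rmax <= 0)) {
    abort("`rmax` must be positive and finite.")
  }
  if (!is.numeric(r_protein) || any(!is.finite(r_protein))) {
    abort("`r_protein` must be numeric and finite.")
  }
  out <- 100 * r_protein / rmax
  if (any(out > 120)) {
    warn("%Rmax above 120: check analyte mass and stoichiometry.")
  }
  out
}

#' Reduce SPR cycles to per-design %Rmax binding results
#'
#' Joins replicate cycles to their designs, computes each design's
#' theoretical Rmax from the full captured-duplex mass (both strands
#' including the capture overhang) and the cycle's own captured-DNA
#' response, converts the protein response to %Rmax, and summarises
#' replicates as mean and standard error.
#'
#' @param cycles Tibble of cycles with columns `design_id`, `r_dna`,
#'   `r_protein` (one row per replicate cycle).
#' @param designs Design tibble; every `design_id` in `cycles` must resolve.
#' @param analyte_mw Analyte molar mass, Da (include tag mass if the tagged
#'   protein is flown).
#' @param stoichiometry Analyte monomers per duplex (default 1).
#' @param loss_threshold %Rmax at or above which a design is flagged
#'   `bound` (default 20).
#' @return A tibble with one row per design: `design_id`,
#'   `rmax_theoretical` (mean over cycles, RU), `percent_rmax` (mean),
#'   `se` (standard error over replicates; 0 for a single cycle), `n_cycles`
#'   and `bound`.
#' @export
analyze_cycles <- function(cycles, designs, analyte_mw, stoichiometry = 1,
                           loss_threshold = 20) {
  cycles <- as_tibble(cycles)
  designs <- as_tibble(designs)
  if (!all(c("design_id", "r_dna", "r_protein") %in% names(cycles))) {
    abort("`cycles` needs columns `design_id`, `r_dna`, `r_protein`.")
  }
  missing_ids <- setdiff(cycles$design_id, designs$design_id)
  if (length(missing_ids) > 0L) {
    abort(sprintf(
      "Cycle design_id(s) not found among designs: %s",
      paste(unique(missing_ids), collapse = ", ")
    ))
  }
  if (any(cycles$r_dna <= 0)) {
    abort("Cycles with non-positive captured-DNA response are not analyzable.")
  }
  mw <- setNames(duplex_mw(designs), designs$design_id)

  cycles |>
    mutate(
      rmax_theoretical = theoretical_rmax(
        analyte_mw, mw[.data$design_id], .data$r_dna, stoichiometry
      ),
      percent_rmax = percent_rmax(.data$r_protein, .data$rmax_theoretical)
    ) |>
    group_by(.data$design_id) |>
    summarise(
      rmax_theoretical = mean(.data$rmax_theoretical),
      se = if (n() > 1L) stats::sd(.data$percent_rmax) / sqrt(n()) else 0,
      percent_rmax = mean(.data$percent_rmax),
      n_cycles = n(),
      .groups = "drop"
    ) |>
    mutate(bound = .data$percent_rmax >= loss_threshold) |>
    select("design_id", "rmax_theoretical", "percent_rmax", "se",
           "n_cycles", "bound") |>
    arrange(match(.data$design_id, designs$design_id))
}

#' Infer footprint boundaries from left/right truncation series
#'
#' Walks each truncation ladder from the full-length duplex inwards and
#' declares binding lost at the first design whose %Rmax drops below
#' `loss_fraction` times the full-length %Rmax. The footprint is the
#' interval, in original-region coordinates, spanned by the last design on
#' each side that still retained binding. If binding is never lost on a
#' side, the region end on that side is reported and flagged.
#'
#' @param left_series Binding results (as from [analyze_cycles()]) joined to
#'   their designs' `start`/`end`, ordered from full length, for the series
#'   truncated from the left.
#' @param right_series Same, for the series truncated from the right.
#' @param loss_fraction Fraction of full-length %Rmax below which binding is
#'   deemed lost (default 0.2).
#' @return A one-row tibble: `start`, `end` (0-based half-open footprint),
#'   `left_open`, `right_open` (TRUE when binding was never lost on that
#'   side, with a warning).
#' @export
infer_footprint <- function(left_series, right_series, loss_fraction = 0.2) {
  assert_scalar_num(loss_fraction, "loss_fraction", positive = TRUE)

  boundary <- function(series, side) {
    series <- as_tibble(series)
    need <- c("percent_rmax", "start", "end")
    if (!all(need %in% names(series))) {
      abort("Each series needs columns `percent_rmax`, `start`, `end` (join results to designs).")
    }
    if (nrow(series) == 0L || series$percent_rmax[1L] <= 0) {
      abort("Full-length %Rmax must be positive to anchor the loss threshold.")
    }
    cut <- loss_fraction * series$percent_rmax[1L]
    lost_at <- which(series$percent_rmax < cut)
    if (length(lost_at) == 0L) {
      warn(sprintf(
        "Binding never lost on the %s side; footprint boundary set to the region end.",
        side
      ))
      last_retained <- nrow(series)
      open <- TRUE
    } else {
      last_retained <- lost_at[1L] - 1L
      open <- FALSE
    }
    list(
      start = series$start[last_retained],
      end = series$end[last_retained],
      open = open
    )
  }

  left <- boundary(left_series, "left")
  right <- boundary(right_series, "right")
  tibble(
    start = left$start,
    end = right$end,
    left_open = left$open,
    right_open = right$open
  )
}
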