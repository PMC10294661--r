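## Differential-expression classification and qPCR standard-curve
## quantification.
##
## Volcano classification applies the fixed thresholds used for RNA-seq
## summaries of this kind: |log2FC| strictly above 1 and unadjusted P at or
## below 0.01.  qPCR quantification fits a genomic-DNA dilution standard
## curve per primer pair (Cq against log10 quantity), inverts it to starting
## quantities (SQ), and normalises target SQ to a reference gene and then to
## a baseline group set to 1.

#' Convert a log2 fold change to a fold change
#'
#' @param x Log2 fold change(s); finite.
#' @return `2^x`.
#' @examples
#' log2fc_to_fc(9.56) # ~750-fold
#' @export
log2fc_to_fc <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric.")
  2^x
}

#' Classify a differential-expression table by volcano thresholds
#'
#' A gene is `up` when `log2fc > lfc_gt` and `p_value <= p_le`, `down` when
#' `log2fc < -lfc_gt` and `p_value <= p_le`, otherwise `ns`. The fold-change
#' inequality is strict and the P inequality inclusive, so `log2fc = 1`
#' is not significant while `p = 0.01` is.
#'
#' @param data Data frame with columns `gene`, `log2fc`, `p_value` (an
#'   optional `fdr` column is passed through untouched).
#' @param lfc_gt Absolute log2-fold-change threshold, exceeded strictly
#'   (default 1).
#' @param p_le Inclusive P-value threshold (default 0.01).
#' @return The input as a tibble of class `volcano_table` with an added
#'   `class` factor (`up`/`down`/`ns`); per-class counts are in
#'   `attr(, "class_counts")` and shown by [volcano_counts()].
#' @examples
#' volcano_classify(data.frame(gene = "iosA", log2fc = 9.56, p_value = 1e-30))
#' @export
volcano_classify <- function(data, lfc_gt = 1, p_le = 0.01) {
  data <- as_tibble(data)
  need <- c("gene", "log2fc", "p_value")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  assert_scalar_num(lfc_gt, "lfc_gt", nonneg = TRUE)
  assert_scalar_num(p_le, "p_le", nonneg = TRUE)
  if (anyNA(data$p_value) || any(data$p_value < 0 | data$p_value > 1)) {
    abort("`p_value` must lie in [0, 1].")
  }
  if (anyNA(data$log2fc) || any(!is.finite(data$log2fc))) {
    abort("`log2fc` must be finite.")
  }
  out <- mutate(
    data,
    class = factor(
      case_when(
        .data$log2fc > lfc_gt & .data$p_value <= p_le ~ "up",
        .data$log2fc < -lfc_gt & .data$p_value <= p_le ~ "down",
        TRUE ~ "ns"
      ),
      levels = c("up", "down", "ns")
    )
  )
  attr(out, "class_counts") <- table(out$class)
  attr(out, "thresholds") <- c(lfc_gt = lfc_gt, p_le = p_le)
  class(out) <- c("volcano_table", class(out))
  out
}

#' Per-class counts of a classified volcano table
#'
#' @param x A `volcano_table` from [volcano_classify()].
#' @return A named table of `up`/`down`/`ns` counts.
#' @export
volcano_counts <- function(x) {
  if (!inherits(x, "volcano_table")) abort("`x` must come from volcano_classify().")
  table(x$class)
}

#' Naive per-gene differential-expression table from a count matrix
#'
#' An intentionally simple exercise path for volcano classification on
#' synthetic counts: log2 fold change is the ratio of group-mean CPM with a
#' pseudocount of 0.5, and the P value is a two-sample t-test on
#' `log2(CPM + 0.5)`. This is *not* equivalent to a negative-binomial GLM
#' fit (edgeR/DESeq2) and should not be used for real RNA-seq inference.
#'
#' @param counts Genes x samples count matrix with dimnames.
#' @param groups Named character vector mapping sample -> group (exactly two
#'   groups); fold changes are group 2 over group 1 in sorted group order.
#' @return A tibble `gene`, `log2fc`, `p_value` suitable for
#'   [volcano_classify()].
#' @export
cpm_ttest_de <- function(counts, groups) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must be a genes x samples matrix with dimnames.")
  }
  if (is.null(names(groups)) || !all(colnames(counts) %in% names(groups))) {
    abort("`groups` must name every sample in `counts`.")
  }
  grp <- factor(groups[colnames(counts)])
  if (nlevels(grp) != 2L) abort("Exactly two groups are required.")
  if (min(table(grp)) < 2L) abort("At least two replicates per group are required.")

  cpm <- t(t(counts) / colSums(counts)) * 1e6
  logcpm <- log2(cpm + 0.5)
  idx1 <- grp == levels(grp)[1L]
  idx2 <- grp == levels(grp)[2L]

  lfc <- log2((rowMeans(cpm[, idx2, drop = FALSE]) + 0.5) /
                (rowMeans(cpm[, idx1, drop = FALSE]) + 0.5))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    a <- logcpm[i, idx1]
    b <- logcpm[i, idx2]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    t.test(b, a)$p.value
  }, numeric(1))
  tibble(gene = rownames(counts), log2fc = unname(lfc), p_value = p)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq against log10 starting quantity over a
#' serial-dilution series: `Cq = slope * log10(q) + intercept`. The
#' amplification efficiency is `E = 10^(-1/slope) - 1` (fraction; 1.0 means
#' perfect doubling per cycle, amplification factor 2).
#'
#' @param points Data frame with columns `log10_quantity` and `cq`; at least
#'   3 distinct quantities.
#' @return A `standard_curve` object with elements `slope` (Cq per log10
#'   quantity, negative for valid curves), `intercept` (Cq at quantity 1),
#'   `efficiency` (fraction), `amplification` (`10^(-1/slope)`),
#'   `r_squared`, `n`, and the underlying `lm` fit. Has [tidy()]/[glance()]
#'   and [autoplot()] methods.
#' @examples
#' pts <- data.frame(log10_quantity = 0:4, cq = 40 - 3.3219 * (0:4))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  points <- as_tibble(points)
  if (!all(c("log10_quantity", "cq") %in% names(points))) {
    abort("`points` needs columns `log10_quantity` and `cq`.")
  }
  points <- filter(points, complete.cases(points[, c("log10_quantity", "cq")]))
  if (length(unique(points$log10_quantity)) < 3L) {
    abort("At least 3 distinct quantities are required for a standard curve.")
  }
  fit <- lm(cq ~ log10_quantity, data = points)
  fit_summary <- suppressWarnings(summary(fit)) # noiseless curves fit exactly
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  if (slope >= 0) {
    warn("Standard-curve slope is non-negative; Cq should fall as quantity rises.")
  }
  structure(
    list(
      slope = slope,
      intercept = intercept,
      efficiency = 10^(-1 / slope) - 1,
      amplification = 10^(-1 / slope),
      r_squared = fit_summary$r.squared,
      n = nrow(points),
      fit = fit
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    paste0("<standard_curve> Cq = %.4f * log10(q) + %.4f\n",
           "  efficiency %.3f (amplification %.3f), r^2 %.4f, n = %d\n"),
    x$slope, x$intercept, x$efficiency, x$amplification, x$r_squared, x$n
  ))
  invisible(x)
}

#' Convert quantification cycles to starting quantities
#'
#' Inverts a fitted standard curve: `SQ = 10^((cq - intercept) / slope)`.
#'
#' @param cq Quantification cycle value(s).
#' @param curve A `standard_curve` from [fit_standard_curve()] with negative
#'   slope.
#' @return Starting quantities on the scale of the curve's quantity axis.
#' @export
cq_to_sq <- function(cq, curve) {
  if (!inherits(curve, "standard_curve")) abort("`curve` must be a standard_curve.")
  if (curve$slope >= 0) abort("A valid standard curve must have negative slope.")
  if (!is.numeric(cq) || any(!is.finite(cq))) abort("`cq` must be finite numeric.")
  10^((cq - curve$intercept) / curve$slope)
}

#' Reference-normalised relative expression by group
#'
#' Per sample, the target SQ is divided by the mean reference-gene SQ of the
#' sample's group (or by the sample's own reference SQ with
#' `per_sample_pairing = TRUE`); per group, the mean of those ratios is
#' divided by the baseline group's mean ratio, so the baseline group reports
#' exactly 1. The result is invariant to rescaling all SQ values by a
#' common factor.
#'
#' @param data Data frame with columns `sample`, `group`, `target_sq`,
#'   `ref_sq`.
#' @param baseline_group Group label whose mean relative expression is set
#'   to 1 (e.g. the wild type).
#' @param per_sample_pairing Divide each sample's target SQ by its own
#'   reference SQ instead of the group-mean reference SQ (default `FALSE`).
#' @return A tibble `group`, `n_samples`, `relative_expression`, with the
#'   per-sample ratios in `attr(, "per_sample")`.
#' @export
relative_expression <- function(data, baseline_group,
                                per_sample_pairing = FALSE) {
  data <- as_tibble(data)
  need <- c("sample", "group", "target_sq", "ref_sq")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (anyNA(data$target_sq) || anyNA(data$ref_sq)) {
    abort("Every sample needs both target and reference SQ values.")
  }
  if (!baseline_group %in% data$group) {
    abort(sprintf("Baseline group '%s' has no samples.", baseline_group))
  }

  per_sample <- data |>
    group_by(.data$group) |>
    mutate(ref_denominator = if (per_sample_pairing) .data$ref_sq
           else mean(.data$ref_sq)) |>
    ungroup()
  if (any(per_sample$ref_denominator == 0)) {
    abort("Reference SQ mean is zero for at least one group.")
  }
  per_sample <- mutate(per_sample,
                       ratio = .data$target_sq / .data$ref_denominator)

  by_group <- per_sample |>
    group_by(.data$group) |>
    summarise(n_samples = n(), mean_ratio = mean(.data$ratio), .groups = "drop")
  baseline <- by_group$mean_ratio[by_group$group == baseline_group]
  if (baseline == 0) abort("Baseline group's mean ratio is zero.")

  out <- by_group |>
    mutate(relative_expression = .data$mean_ratio / baseline) |>
    select("group", "n_samples", "relative_expression")
  attr(out, "per_sample") <- select(per_sample, "sample", "group", "ratio")
  out
}

#' Average technical replicates to one Cq per biological sample
#'
#' Technical replicates are averaged on the Cq scale before conversion to
#' starting quantities.
#'
#' @param data Data frame with columns `sample` and `cq` (one row per
#'   technical replicate).
#' @return A tibble `sample`, `cq`, `n_technical`.
#' @export
average_technical_cq <- function(data) {
  data <- as_tibble(data)
  if (!all(c("sample", "cq") %in% names(data))) {
    abort("`data` needs columns `sample` and `cq`.")
  }
  data |>
    group_by(.data$sample) |>
    summarise(cq = mean(.data$cq), n_technical = n(), .groups = "drop")
}
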