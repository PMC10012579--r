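# X chromosome inactivation skew: compares paternal-ratio distributions of
# X-linked vs autosomal transcripts per sample. Imprinted XCI (paternal-X
# silencing in extraembryonic tissue) shifts X ratios below the autosomal
# centre.

#' Per-sample autosome vs chrX ratio summaries
#'
#' Sentinel cells are excluded; transcripts are classed by chromosome
#' (`chrX` vs everything else).
#'
#' @param mat Paternal-ratio matrix from [paternal_ratio_matrix()].
#' @param annotation Transcript table with `transcript_id` and `chrom`.
#' @param x_chrom Name of the X chromosome.
#' @return Data.frame with one row per sample: means, medians and valid
#'   transcript counts per class, plus a `flag` column (`"no_valid_X"` when
#'   no X-linked cell is valid; near-zero X coverage also suggests an
#'   XO-genotype sample worth reviewing).
#' @export
chrom_class_ratios <- function(mat, annotation, x_chrom = "chrX") {
  chrom <- annotation$chrom[match(rownames(mat), annotation$transcript_id)]
  if (anyNA(chrom)) stop("annotation missing for some transcripts",
                         call. = FALSE)
  is_x <- chrom == x_chrom
  out <- lapply(colnames(mat), function(s) {
    v <- mat[, s]
    valid <- v >= 0 & v <= 1
    a <- v[valid & !is_x]
    x <- v[valid & is_x]
    data.frame(
      sample_id = s,
      mean_autosomal = if (length(a) > 0L) mean(a) else NA_real_,
      median_autosomal = if (length(a) > 0L) stats::median(a) else NA_real_,
      n_autosomal = length(a),
      mean_X = if (length(x) > 0L) mean(x) else NA_real_,
      median_X = if (length(x) > 0L) stats::median(x) else NA_real_,
      n_X = length(x),
      flag = if (length(x) == 0L) "no_valid_X" else "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  tis <- attr(mat, "tissue")
  if (!is.null(tis)) out$tissue <- unname(tis[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Rank-sum test for XCI skew in one sample
#'
#' Two-sided Wilcoxon rank-sum location test of the X-linked vs autosomal
#' per-transcript paternal ratios. Direction `paternal_X_inactivated` means
#' the X ratios sit significantly below the autosomal ratios (the paternal
#' X is silenced); `maternal_X_inactivated` is the mirror; `none` when not
#' significant.
#'
#' @param autosomal,x_linked Valid paternal ratios of one sample.
#' @param alpha Significance level.
#' @param min_x,min_autosomal Minimum transcript counts to test.
#' @return List with `statistic` (rank-sum statistic centred at zero, so
#'   relabelling the parental alleles negates it), `p`, `direction`,
#'   `mean_X`, `mean_autosomal`; direction `not_testable` when counts are
#'   too low.
#' @export
xci_skew_test <- function(autosomal, x_linked, alpha = 0.05,
                          min_x = 10L, min_autosomal = 50L) {
  if (length(x_linked) < min_x || length(autosomal) < min_autosomal) {
    return(list(statistic = NA_real_, p = NA_real_,
                direction = "not_testable",
                mean_X = if (length(x_linked) > 0L) mean(x_linked) else NA_real_,
                mean_autosomal = if (length(autosomal) > 0L)
                  mean(autosomal) else NA_real_))
  }
  wt <- stats::wilcox.test(x_linked, autosomal, exact = FALSE)
  mx <- mean(x_linked); ma <- mean(autosomal)
  direction <- if (wt$p.value >= alpha) "none"
               else if (mx < ma) "paternal_X_inactivated"
               else "maternal_X_inactivated"
  # centred rank-sum statistic: antisymmetric under maternal/paternal flip
  stat <- unname(wt$statistic) - length(x_linked) * length(autosomal) / 2
  list(statistic = stat, p = wt$p.value,
       direction = direction, mean_X = mx, mean_autosomal = ma)
}

#' XCI skew summary for every sample of a ratio matrix
#'
#' @inheritParams chrom_class_ratios
#' @param alpha Significance level of the per-sample rank-sum test.
#' @param min_x,min_autosomal Minimum valid transcripts per class.
#' @return Data.frame with per-sample class summaries plus `statistic`,
#'   `p` and `direction`.
#' @export
xci_summary <- function(mat, annotation, x_chrom = "chrX", alpha = 0.05,
                        min_x = 10L, min_autosomal = 50L) {
  chrom <- annotation$chrom[match(rownames(mat), annotation$transcript_id)]
  is_x <- chrom == x_chrom
  base <- chrom_class_ratios(mat, annotation, x_chrom)
  tests <- lapply(colnames(mat), function(s) {
    v <- mat[, s]
    valid <- v >= 0 & v <= 1
    xci_skew_test(v[valid & !is_x], v[valid & is_x], alpha, min_x,
                  min_autosomal)
  })
  base$statistic <- vapply(tests, `[[`, numeric(1), "statistic")
  base$p <- vapply(tests, `[[`, numeric(1), "p")
  base$direction <- vapply(tests, `[[`, character(1), "direction")
  base
}
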