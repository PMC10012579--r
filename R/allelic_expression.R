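# Expression-ratio computation, filtering with sentinel codes, and the
# per-transcript t-test path for calling imprinted transcripts.

#' Reads per kilobase per million aligned reads
#'
#' @param reads Read count(s).
#' @param exonic_kb Summed exon length in kilobases (> 0).
#' @param library_size Total aligned reads of the sample (> 0).
#' @return RPKM = reads / (library_size / 1e6 * exonic_kb).
#' @export
compute_rpkm <- function(reads, exonic_kb, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  if (any(exonic_kb <= 0)) stop("exonic_kb must be > 0", call. = FALSE)
  reads / (library_size / 1e6 * exonic_kb)
}

#' Reads per million aligned reads
#'
#' @inheritParams compute_rpkm
#' @return RPM = reads / (library_size / 1e6).
#' @export
compute_rpm <- function(reads, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  reads / (library_size / 1e6)
}

#' Paternal expression ratio with sentinel codes
#'
#' The ratio is paternal / (paternal + maternal) allelic coverage. Cells
#' failing the expression filter (RPKM < `rpkm_min`) are coded -2; cells
#' expressed but without informative allelic coverage (both allelic RPM <
#' `allelic_rpm_min`) are coded -1. Sentinel cells never enter any
#' downstream mean or test statistic.
#'
#' @param maternal_reads,paternal_reads Allelic read counts.
#' @param rpkm Allele-agnostic expression of the transcript in the sample.
#' @param maternal_rpm,paternal_rpm Allelic reads per million.
#' @param rpkm_min,allelic_rpm_min Filter thresholds.
#' @return Numeric vector in \[0, 1\] or the sentinels -1 / -2.
#' @export
paternal_ratio <- function(maternal_reads, paternal_reads, rpkm,
                           maternal_rpm, paternal_rpm,
                           rpkm_min = 1, allelic_rpm_min = 0.5) {
  n <- length(rpkm)
  out <- numeric(n)
  not_expressed <- rpkm < rpkm_min
  no_allelic <- !not_expressed &
    pmax(maternal_rpm, paternal_rpm) < allelic_rpm_min
  ok <- !not_expressed & !no_allelic
  out[not_expressed] <- -2
  out[no_allelic] <- -1
  denom <- maternal_reads[ok] + paternal_reads[ok]
  # the allelic RPM filter guarantees denom > 0 for passing cells
  out[ok] <- paternal_reads[ok] / denom
  out
}

#' Build the transcripts x samples paternal-ratio matrix
#'
#' Computes RPKM/RPM from the raw count table and the transcript annotation,
#' applies the expression and allelic-coverage filters, and returns a matrix
#' whose cells are paternal ratios in \[0, 1\] or the sentinels -1 / -2.
#'
#' @param records Allelic count table (see [read_allelic_counts()]).
#' @param annotation Transcript table with `transcript_id` and `exonic_kb`.
#' @param rpkm_min,allelic_rpm_min Filter thresholds.
#' @return Numeric matrix (transcripts x samples) with attribute `tissue`,
#'   a named character vector mapping sample to tissue.
#' @export
paternal_ratio_matrix <- function(records, annotation, rpkm_min = 1,
                                  allelic_rpm_min = 0.5) {
  kb <- stats::setNames(annotation$exonic_kb, annotation$transcript_id)
  missing <- setdiff(unique(records$transcript_id), names(kb))
  if (length(missing) > 0L) {
    stop(sprintf("annotation missing for transcript(s): %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  rpkm <- compute_rpkm(records$total_reads, kb[records$transcript_id],
                       records$library_size)
  mrpm <- compute_rpm(records$maternal_reads, records$library_size)
  prpm <- compute_rpm(records$paternal_reads, records$library_size)
  ratio <- paternal_ratio(records$maternal_reads, records$paternal_reads,
                          rpkm, mrpm, prpm, rpkm_min, allelic_rpm_min)
  tx <- sort(unique(records$transcript_id))
  sm <- unique(records[c("sample_id", "tissue")])
  if (anyDuplicated(sm$sample_id)) {
    stop("a sample_id maps to more than one tissue", call. = FALSE)
  }
  mat <- matrix(-2, nrow = length(tx), ncol = nrow(sm),
                dimnames = list(tx, sm$sample_id))
  mat[cbind(match(records$transcript_id, tx),
            match(records$sample_id, sm$sample_id))] <- ratio
  attr(mat, "tissue") <- stats::setNames(sm$tissue, sm$sample_id)
  mat
}

#' Bonferroni adjustment
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of tests in the family (>= 1).
#' @return min(1, p * m).
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

.one_sample_t <- function(x, mu = 0.5) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) {
    # limit of the t statistic for degenerate replicate sets
    return(if (isTRUE(all.equal(x[[1L]], mu))) 1 else 0)
  }
  tt <- (mean(x) - mu) / (s / sqrt(n))
  2 * stats::pt(-abs(tt), df = n - 1L)
}

#' Call imprinted transcripts by per-transcript t-test
#'
#' For each transcript, the valid cells of the paternal-ratio matrix (those
#' in \[0, 1\]; sentinels are excluded) are tested against the balanced
#' ratio 0.5 with a two-sided one-sample t-test, pooling replicates of both
#' reciprocal crosses. Bonferroni control is applied over the tested family.
#' A transcript is called paternally (maternally) expressed when its
#' adjusted p-value is below `alpha`, it has at least `min_valid` valid
#' samples, and its mean ratio is above (below) 0.5; otherwise it is
#' `biallelic` (tested, not significant) or `not_testable` (insufficient
#' valid samples).
#'
#' @param mat Paternal-ratio matrix from [paternal_ratio_matrix()],
#'   restricted to one tissue (see `tissue`).
#' @param tissue Optional tissue label; when given and the matrix carries a
#'   `tissue` attribute, only that tissue's samples are used.
#' @param min_valid Minimum valid samples for a call (6 for the rat arm,
#'   4 for the mouse arm).
#' @param alpha Adjusted p-value cutoff.
#' @param family Bonferroni family: `"min_valid"` counts transcripts with at
#'   least `min_valid` valid samples (default); `"any_valid"` counts all
#'   transcripts with at least one valid sample.
#' @return An `imprint_calls` data.frame with one row per transcript:
#'   `transcript_id`, `tissue`, `status`, `mean_ratio`, `raw_p`, `adj_p`,
#'   `n_valid_samples`, `test`, `blood_expressed`.
#' @export
call_imprinted_ttest <- function(mat, tissue = NULL, min_valid = 6,
                                 alpha = 0.05,
                                 family = c("min_valid", "any_valid")) {
  family <- match.arg(family)
  tis <- attr(mat, "tissue")
  if (!is.null(tissue)) {
    if (is.null(tis)) {
      stop(paste("matrix carries no tissue attribute (note: `[` subsetting",
                 "drops it); subset to the tissue yourself or rebuild with",
                 "paternal_ratio_matrix()"), call. = FALSE)
    }
    mat <- mat[, names(tis)[tis == tissue], drop = FALSE]
  }
  valid <- mat >= 0 & mat <= 1
  n_valid <- rowSums(valid)
  mean_ratio <- ifelse(n_valid > 0,
                       rowSums(mat * valid) / pmax(n_valid, 1), NA_real_)
  raw_p <- vapply(seq_len(nrow(mat)), function(i) {
    .one_sample_t(mat[i, valid[i, ]])
  }, numeric(1))
  tested <- !is.na(raw_p)
  m <- if (family == "min_valid") sum(n_valid >= min_valid & tested)
       else sum(n_valid >= 1L & tested)
  m <- max(m, 1L)
  adj_p <- rep(NA_real_, nrow(mat))
  adj_p[tested] <- pmin(1, raw_p[tested] * m)
  status <- rep("not_testable", nrow(mat))
  testable <- n_valid >= min_valid & tested
  status[testable] <- "biallelic"
  sig <- testable & adj_p < alpha
  status[sig & mean_ratio > 0.5] <- "paternal"
  status[sig & mean_ratio < 0.5] <- "maternal"
  out <- data.frame(
    transcript_id = rownames(mat),
    tissue = if (!is.null(tissue)) tissue else NA_character_,
    status = status, mean_ratio = mean_ratio, raw_p = raw_p, adj_p = adj_p,
    n_valid_samples = as.integer(n_valid), test = "t_test",
    blood_expressed = FALSE, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("imprint_calls", "data.frame")
  out
}

#' Flag maternal extraembryonic calls expressed in adult blood
#'
#' Extraembryonic (EPC) samples are dissected through maternal decidua, so
#' apparent maternal-specific expression can be a contamination artifact.
#' Maternal calls in EPC whose transcript is expressed in adult blood
#' (RPKM > `threshold`) are flagged `blood_expressed`; downstream list
#' building excludes them from the final maternal set, but they are retained
#' in the output. Paternal calls and embryonic-tissue calls are unaffected.
#' Transcripts missing from the blood table are treated as unexpressed.
#'
#' @param calls An `imprint_calls` data.frame.
#' @param blood Data.frame with `transcript_id` and `rpkm`.
#' @param threshold Blood RPKM cutoff.
#' @param epc_tissue Label of the extraembryonic tissue.
#' @return `calls` with the `blood_expressed` flag set.
#' @export
decidua_filter <- function(calls, blood, threshold = 1, epc_tissue = "EPC") {
  rpkm <- stats::setNames(blood$rpkm, blood$transcript_id)
  b <- rpkm[calls$transcript_id]
  b[is.na(b)] <- 0
  calls$blood_expressed <- calls$status == "maternal" &
    !is.na(calls$tissue) & calls$tissue == epc_tissue & b > threshold
  calls
}

#' @export
print.imprint_calls <- function(x, ...) {
  called <- x$status %in% c("paternal", "maternal")
  cat(sprintf(
    "imprint_calls: %d transcripts (%s); %d paternal, %d maternal, %d flagged blood-expressed\n",
    nrow(x), if (all(is.na(x$tissue))) "tissue NA" else
      paste(unique(stats::na.omit(x$tissue)), collapse = "/"),
    sum(x$status == "paternal"), sum(x$status == "maternal"),
    sum(x$blood_expressed)))
  if (any(called)) {
    print.data.frame(utils::head(x[called, , drop = FALSE], 10))
  }
  invisible(x)
}

#' @export
summary.imprint_calls <- function(object, ...) {
  table(status = object$status)
}
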