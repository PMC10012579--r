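# Cross-species comparison of oocyte epigenomes over syntenic 1-kb bins,
# and mark-domain calling with size statistics.

#' Pair mark levels across two genomes via a synteny map
#'
#' @param tracks_a,tracks_b Named lists of bedGraph-style data.frames (per
#'   mark) for genomes A and B, with bins matching the map's intervals.
#' @param map Synteny map (see [read_synteny_map()]).
#' @return Data.frame with one row per syntenic pair and columns
#'   `<mark>_a` / `<mark>_b` for each mark present in both genomes.
#' @export
build_paired_bins <- function(tracks_a, tracks_b, map) {
  marks <- intersect(names(tracks_a), names(tracks_b))
  out <- map
  for (mk in marks) {
    ta <- tracks_a[[mk]]; tb <- tracks_b[[mk]]
    ia <- match(paste(map$chrom_a, map$start_a), paste(ta$chrom, ta$start))
    ib <- match(paste(map$chrom_b, map$start_b), paste(tb$chrom, tb$start))
    if (anyNA(ia) || anyNA(ib)) {
      stop(sprintf("track '%s' does not cover every syntenic bin", mk),
           call. = FALSE)
    }
    out[[paste0(mk, "_a")]] <- ta$level[ia]
    out[[paste0(mk, "_b")]] <- tb$level[ib]
  }
  out
}

#' Spearman rank correlation
#'
#' Average ranks for ties; constant input yields NA with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\], or NA for degenerate input.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Count species-specific H3K27me3 bins
#'
#' A bin is A-specific when K27 in A exceeds B by more than `k27_delta_min`
#' RPKM while DNAme in B exceeds A by more than `dname_delta_min`
#' percentage points (the reciprocal DNAme difference reflecting the
#' H3K27me3/DNAme anticorrelation); B-specific is the mirror image.
#'
#' @param paired Paired bin table from [build_paired_bins()] with columns
#'   `H3K27me3_a`, `H3K27me3_b`, `DNAme_a`, `DNAme_b`.
#' @param k27_delta_min RPKM threshold.
#' @param dname_delta_min Percentage-point threshold.
#' @return List with `count_a`, `count_b` and `ratio` (= count_a / count_b,
#'   NA when count_b is zero).
#' @export
species_specific_bins <- function(paired, k27_delta_min = 0.5,
                                  dname_delta_min = 75) {
  a_spec <- (paired$H3K27me3_a - paired$H3K27me3_b > k27_delta_min) &
    (paired$DNAme_b - paired$DNAme_a > dname_delta_min)
  b_spec <- (paired$H3K27me3_b - paired$H3K27me3_a > k27_delta_min) &
    (paired$DNAme_a - paired$DNAme_b > dname_delta_min)
  ca <- sum(a_spec, na.rm = TRUE)
  cb <- sum(b_spec, na.rm = TRUE)
  list(count_a = ca, count_b = cb,
       ratio = if (cb == 0L) NA_real_ else ca / cb)
}

#' Call enriched mark domains from a binned track
#'
#' Maximal runs of bins at or above `level_min` become peaks; peaks whose
#' gap is at most `group_gap` bp are grouped into one domain. By default
#' `level_min` is the 90th percentile of non-zero bin levels.
#'
#' @param track bedGraph-style data.frame (`chrom`, `start`, `end`,
#'   `level`), tiled bins.
#' @param level_min Absolute enrichment threshold; `NULL` for the
#'   percentile default.
#' @param group_gap Peak-grouping distance (bp).
#' @param percentile Percentile used when `level_min` is `NULL`.
#' @return List with `domains` (data.frame `chrom`, `start`, `end`,
#'   `mean_level`) and `size_summary` (`n`, `mean_bp`, `median_bp`).
#' @export
call_domains <- function(track, level_min = NULL, group_gap = 3000,
                         percentile = 0.9) {
  if (is.null(level_min)) {
    nz <- track$level[track$level > 0]
    level_min <- if (length(nz) > 0L) stats::quantile(nz, percentile,
                                                      names = FALSE) else Inf
  }
  enriched <- track[track$level >= level_min, , drop = FALSE]
  if (nrow(enriched) == 0L) {
    domains <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), mean_level = numeric(0))
    return(list(domains = domains,
                size_summary = c(n = 0L, mean_bp = NA_real_,
                                 median_bp = NA_real_)))
  }
  domains <- do.call(rbind, lapply(split(enriched, enriched$chrom),
                                   function(cc) {
    cc <- cc[order(cc$start), ]
    gap <- c(Inf, cc$start[-1L] - cc$end[-nrow(cc)])
    grp <- cumsum(gap > group_gap)
    do.call(rbind, lapply(split(cc, grp), function(g) {
      data.frame(chrom = g$chrom[1L], start = min(g$start),
                 end = max(g$end), mean_level = mean(g$level),
                 stringsAsFactors = FALSE)
    }))
  }))
  domains <- domains[order(domains$chrom, domains$start), ]
  rownames(domains) <- NULL
  sizes <- domains$end - domains$start
  list(domains = domains,
       size_summary = c(n = nrow(domains), mean_bp = mean(sizes),
                        median_bp = stats::median(sizes)))
}

#' Compare mean domain sizes between two domain sets
#'
#' Sign convention: positive values mean A's domains are larger. The
#' percent difference is relative to A's mean.
#'
#' @param domains_a,domains_b Domain data.frames with `start`, `end` (both
#'   non-empty).
#' @return List with `mean_diff_bp` (mean_A - mean_B) and `pct_diff`
#'   (100 * (mean_A - mean_B) / mean_A).
#' @export
compare_domain_sizes <- function(domains_a, domains_b) {
  if (nrow(domains_a) == 0L || nrow(domains_b) == 0L) {
    stop("both domain sets must be non-empty", call. = FALSE)
  }
  ma <- mean(domains_a$end - domains_a$start)
  mb <- mean(domains_b$end - domains_b$start)
  list(mean_diff_bp = ma - mb, pct_diff = 100 * (ma - mb) / ma)
}
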