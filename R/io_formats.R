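# Tabular and interval formats used throughout the pipeline.
#
# Conventions: all tables are plain TSV (tab separators, "#" comment lines,
# UTF-8, no quoting); all genomic intervals are 0-based half-open, BED-style,
# in memory and on disk.

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.check_counts <- function(df, cols, what) {
  for (cc in cols) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
      stop(sprintf("%s: column '%s' must contain non-negative integers", what, cc),
           call. = FALSE)
    }
    bad <- which(v < 0)
    if (length(bad) > 0L) {
      stop(sprintf("%s: negative count in column '%s' at row %d", what, cc, bad[1L]),
           call. = FALSE)
    }
  }
}

#' Read an allele-resolved expression count table
#'
#' Reads per-transcript, per-sample read counts split by parental allele,
#' as produced by an allele-aware aligner on reciprocal F1 hybrid RNA-seq.
#' The `cross` column names the maternal strain first (e.g. `"BW"` means
#' a B dam crossed with a W sire), which is what lets downstream code
#' separate parent-of-origin from strain effects.
#'
#' @param path Path to a TSV file with columns `transcript_id`, `sample_id`,
#'   `cross`, `tissue`, `total_reads`, `maternal_reads`, `paternal_reads`,
#'   `library_size` (total aligned reads of the sample).
#' @return A data.frame of validated records. RPKM/RPM columns are not
#'   computed here; see [paternal_ratio_matrix()].
#' @export
read_allelic_counts <- function(path) {
  df <- .read_tsv(path)
  req <- c("transcript_id", "sample_id", "cross", "tissue",
           "total_reads", "maternal_reads", "paternal_reads", "library_size")
  .require_columns(df, req, "allelic counts")
  .check_counts(df, c("total_reads", "maternal_reads", "paternal_reads"),
                "allelic counts")
  if (any(df$library_size <= 0)) {
    stop("allelic counts: library_size must be positive", call. = FALSE)
  }
  bad <- which(df$maternal_reads + df$paternal_reads > df$total_reads)
  if (length(bad) > 0L) {
    stop(sprintf(
      "allelic counts: maternal_reads + paternal_reads > total_reads at row %d",
      bad[1L]), call. = FALSE)
  }
  df[req]
}

#' Write an allele-resolved expression count table
#'
#' @param records Data.frame as returned by [read_allelic_counts()] or
#'   [simulate_reciprocal_expression()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(records, path) {
  .write_tsv(records, path)
  invisible(path)
}

#' Read a per-CpG allele-resolved methylation report
#'
#' Each row carries methylated/unmethylated read counts for one CpG in one
#' sample and allele track. CpGs are keyed to the position of the C on the
#' plus strand (strand-symmetric collapsing is assumed done upstream).
#' Rows are returned sorted by (chrom, pos); duplicate
#' (chrom, pos, sample_id, allele) keys are rejected.
#'
#' @param path TSV with columns `chrom`, `pos` (0-based), `sample_id`,
#'   `allele` (one of maternal, paternal, total, oocyte, sperm),
#'   `meth_reads`, `unmeth_reads`.
#' @return Sorted data.frame of CpG records.
#' @export
read_cpg_report <- function(path) {
  df <- .read_tsv(path)
  req <- c("chrom", "pos", "sample_id", "allele", "meth_reads", "unmeth_reads")
  .require_columns(df, req, "CpG report")
  .check_counts(df, c("meth_reads", "unmeth_reads"), "CpG report")
  if (!is.numeric(df$pos) || any(df$pos < 0) || any(df$pos != floor(df$pos))) {
    stop("CpG report: 'pos' must be a non-negative integer coordinate",
         call. = FALSE)
  }
  key <- paste(df$chrom, df$pos, df$sample_id, df$allele, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop(sprintf("CpG report: duplicate record for %s:%d (%s, %s)",
                 df$chrom[dup[1L]], df$pos[dup[1L]],
                 df$sample_id[dup[1L]], df$allele[dup[1L]]), call. = FALSE)
  }
  df <- df[order(df$chrom, df$pos, df$sample_id, df$allele), req]
  rownames(df) <- NULL
  df
}

#' Write a per-CpG methylation report
#'
#' @param cpgs Data.frame of CpG records (see [read_cpg_report()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cpg_report <- function(cpgs, path) {
  .write_tsv(cpgs, path)
  invisible(path)
}

#' Write DMRs as BED6+
#'
#' Emits one line per DMR with 0-based half-open coordinates and extra
#' columns `n_cpg`, `origin` and the maximum parental methylation delta,
#' sorted by (chrom, start).
#'
#' @param dmrs Data.frame with columns `chrom`, `start`, `end`, `n_cpg`,
#'   `origin`, `delta` (percentage points).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) > 0L && any(dmrs$start >= dmrs$end)) {
    stop("DMR BED: start must be < end", call. = FALSE)
  }
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start), , drop = FALSE]
  bed <- data.frame(
    chrom = dmrs$chrom,
    start = as.integer(dmrs$start),
    end   = as.integer(dmrs$end),
    name  = if (nrow(dmrs) > 0L) {
      sprintf("dmr_%s_%d", dmrs$chrom, as.integer(dmrs$start))
    } else character(0),
    score = if (nrow(dmrs) > 0L) round(dmrs$delta, 2) else numeric(0),
    strand = rep(".", nrow(dmrs)),
    n_cpg = as.integer(dmrs$n_cpg),
    origin = dmrs$origin,
    delta = if (nrow(dmrs) > 0L) round(dmrs$delta, 4) else numeric(0),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DMR BED6+ file written by [write_dmr_bed()]
#'
#' @param path BED path.
#' @return Data.frame with columns `chrom`, `start`, `end`, `n_cpg`,
#'   `origin`, `delta`.
#' @export
read_dmr_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "n_cpg", "origin", "delta")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_cpg = integer(0), origin = character(0), delta = numeric(0))
    return(out)
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(ncol(df))]
  df[c("chrom", "start", "end", "n_cpg", "origin", "delta")]
}

#' Read a bedGraph track of binned signal
#'
#' @param path bedGraph file (`chrom  start  end  value`, 0-based half-open).
#' @return Data.frame with columns `chrom`, `start`, `end`, `level`.
#' @export
read_bedgraph <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), level = numeric(0)))
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("bedGraph: expected 4 columns", call. = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "level")
  if (any(df$level < 0)) stop("bedGraph: negative level", call. = FALSE)
  df[c("chrom", "start", "end", "level")]
}

#' Write a bedGraph track
#'
#' @param track Data.frame with columns `chrom`, `start`, `end`, `level`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(track[c("chrom", "start", "end", "level")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a two-genome synteny map of paired 1-kb bins
#'
#' @param path TSV with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b` (0-based half-open, one row per syntenic pair).
#' @return Data.frame of validated pairs.
#' @export
read_synteny_map <- function(path) {
  df <- .read_tsv(path)
  req <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b", "end_b")
  .require_columns(df, req, "synteny map")
  if (any(df$start_a >= df$end_a) || any(df$start_b >= df$end_b)) {
    stop("synteny map: intervals must be half-open with start < end",
         call. = FALSE)
  }
  key <- paste(df$chrom_a, df$start_a, df$chrom_b, df$start_b, sep = "\r")
  if (anyDuplicated(key)) stop("synteny map: duplicate pair", call. = FALSE)
  df[req]
}

#' Write a synteny map
#'
#' @param map Data.frame as returned by [read_synteny_map()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_synteny_map <- function(map, path) {
  .write_tsv(map, path)
  invisible(path)
}

#' Default analysis thresholds
#'
#' All tunable thresholds of the pipeline with their default values. Each
#' can be overridden via a YAML file (see [load_config()]) or per call.
#'
#' @return Named list of thresholds.
#' @export
imprint_defaults <- function() {
  list(
    rpkm_min        = 1,     # expressed transcript filter (RPKM)
    allelic_rpm_min = 0.5,   # informative allelic coverage filter (RPM)
    min_valid       = 6,     # samples with a valid ratio required to call
    alpha           = 0.05,  # adjusted p-value cutoff (both test paths)
    blood_rpkm_max  = 1,     # decidua-contamination blood expression filter
    pseudocount     = 0.5,   # added to allelic RPM before log2
    min_fc          = 4,     # fold-change gate of the linear-model path
    dmr_delta_min   = 10,    # per-CpG candidate delta (percentage points)
    dmr_p_max       = 0.001, # per-CpG candidate p-value
    dmr_min_cpgs    = 3,     # candidate CpGs per DMR
    dmr_max_gap     = 300,   # bp between candidate CpGs within one DMR
    dmr_min_len     = 50,    # bp minimum DMR span
    smooth_span     = 500,   # bp smoothing window
    min_total_cov   = 5,     # reads for total-track CpG inclusion
    min_allelic_cov = 1,     # reads for allelic-track CpG inclusion
    gamete_delta_min = 50,   # percentage points, gametic-origin call
    hyper_min       = 75,    # percentage points, both-gametes-hyper call
    final_min_cpgs  = 2,     # covered CpGs per sample in final DMR filter
    final_delta_min = 50,    # percentage points, final parental delta
    promoter_window = 5000,  # bp upstream of TSS for promoter DMR assignment
    k27_delta_min   = 0.5,   # RPKM, species-specific H3K27me3 bin call
    dname_delta_min = 75,    # percentage points, reciprocal DNAme delta
    domain_group_gap = 3000  # bp, peak-to-domain grouping distance
  )
}

#' Load analysis thresholds from a YAML file
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file of `key: value` pairs, or `NULL` for pure defaults.
#' @return Named list of thresholds.
#' @export
load_config <- function(path = NULL) {
  cfg <- imprint_defaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  utils::modifyList(cfg, user)
}
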