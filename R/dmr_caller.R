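# Parent-of-origin DMR calling from allelic CpG counts: coverage-weighted
# smoothing, per-CpG exact testing, greedy grouping of candidate CpGs,
# gamete-integrated origin classification, and the final coverage/delta
# filter.

#' Coverage-weighted moving-average smoothing of methylation fractions
#'
#' Each CpG's smoothed fraction is the coverage-weighted mean of the raw
#' fractions of all CpGs within +/- span/2 of its position (equivalently,
#' summed methylated reads over summed coverage in the window). An isolated
#' CpG keeps its raw fraction.
#'
#' @param pos Sorted CpG positions (one chromosome).
#' @param meth,unmeth Read counts per CpG.
#' @param span Window width in bp.
#' @return Smoothed methylation fractions in \[0, 1\].
#' @export
smooth_methylation <- function(pos, meth, unmeth, span = 500) {
  n <- length(pos)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(pos)) stop("positions must be sorted", call. = FALSE)
  cov <- meth + unmeth
  half <- span / 2
  cm <- cumsum(meth)
  cc <- cumsum(cov)
  right <- findInterval(pos + half, pos)
  left <- findInterval(pos - half - 1e-9, pos) + 1L
  wm <- cm[right] - c(0, cm)[left]
  wc <- cc[right] - c(0, cc)[left]
  ifelse(wc > 0, wm / wc, NA_real_)
}

.fisher_p <- function(m1, u1, m2, u2) {
  stats::fisher.test(matrix(c(m1, u1, m2, u2), nrow = 2L))$p.value
}

#' Per-CpG parental methylation difference test
#'
#' Delta is the absolute difference of the smoothed maternal and paternal
#' fractions, in percentage points; the p-value comes from Fisher's exact
#' test on the pooled raw counts. CpGs with zero coverage on either side
#' are skipped (never candidates).
#'
#' @param m_meth,m_unmeth Maternal pooled counts.
#' @param p_meth,p_unmeth Paternal pooled counts.
#' @param m_smooth,p_smooth Smoothed fractions (defaults: raw fractions).
#' @return List with `delta` (percentage points) and `p`.
#' @export
test_cpg_diff <- function(m_meth, m_unmeth, p_meth, p_unmeth,
                          m_smooth = NULL, p_smooth = NULL) {
  if (m_meth + m_unmeth < 1 || p_meth + p_unmeth < 1) {
    stop("both alleles need coverage >= 1", call. = FALSE)
  }
  if (is.null(m_smooth)) m_smooth <- m_meth / (m_meth + m_unmeth)
  if (is.null(p_smooth)) p_smooth <- p_meth / (p_meth + p_unmeth)
  list(delta = abs(m_smooth - p_smooth) * 100,
       p = .fisher_p(m_meth, m_unmeth, p_meth, p_unmeth))
}

#' Per-CpG statistics for one sample's parental alleles
#'
#' Aligns the maternal and paternal tracks of one sample on shared covered
#' CpGs, smooths each track, and computes delta and Fisher p per CpG.
#'
#' @param cpgs CpG record table (see [read_cpg_report()]).
#' @param sample_id Sample (tissue) whose maternal/paternal tracks to use.
#' @param span Smoothing window (bp).
#' @return Data.frame `chrom`, `pos`, maternal/paternal counts, smoothed
#'   fractions, `delta` (percentage points), `p`.
#' @export
compute_cpg_stats <- function(cpgs, sample_id, span = 500) {
  m <- cpgs[cpgs$sample_id == sample_id & cpgs$allele == "maternal", ]
  p <- cpgs[cpgs$sample_id == sample_id & cpgs$allele == "paternal", ]
  key_m <- paste(m$chrom, m$pos)
  key_p <- paste(p$chrom, p$pos)
  shared <- intersect(key_m, key_p)
  m <- m[match(shared, key_m), ]
  p <- p[match(shared, key_p), ]
  covered <- (m$meth_reads + m$unmeth_reads) >= 1 &
    (p$meth_reads + p$unmeth_reads) >= 1
  m <- m[covered, ]; p <- p[covered, ]
  o <- order(m$chrom, m$pos)
  m <- m[o, ]; p <- p[o, ]
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    m_meth = m$meth_reads, m_unmeth = m$unmeth_reads,
                    p_meth = p$meth_reads, p_unmeth = p$unmeth_reads,
                    stringsAsFactors = FALSE)
  sm <- unlist(lapply(split(seq_len(nrow(out)), out$chrom), function(i) {
    smooth_methylation(out$pos[i], out$m_meth[i], out$m_unmeth[i], span)
  }), use.names = FALSE)
  sp <- unlist(lapply(split(seq_len(nrow(out)), out$chrom), function(i) {
    smooth_methylation(out$pos[i], out$p_meth[i], out$p_unmeth[i], span)
  }), use.names = FALSE)
  out$m_smooth <- sm
  out$p_smooth <- sp
  out$delta <- abs(out$m_smooth - out$p_smooth) * 100
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    .fisher_p(out$m_meth[i], out$m_unmeth[i], out$p_meth[i], out$p_unmeth[i])
  }, numeric(1))
  rownames(out) <- NULL
  out
}

#' Group candidate CpGs into DMRs
#'
#' Candidate CpGs (delta above `delta_min` and p below `p_max`) are grouped
#' greedily along each chromosome whenever consecutive candidates are within
#' `max_gap` bp; groups with at least `min_cpgs` candidates spanning at
#' least `min_len` bp become DMRs. DMR bounds run from the first candidate
#' position to the last candidate position + 2 (half-open, covering the CpG
#' dinucleotide). Output is sorted and invariant to input row order.
#'
#' @param stats Per-CpG statistics from [compute_cpg_stats()].
#' @param delta_min Candidate delta threshold (percentage points).
#' @param p_max Candidate p-value threshold.
#' @param min_cpgs Minimum candidate CpGs per DMR.
#' @param max_gap Maximum gap between candidate CpGs within a DMR (bp).
#' @param min_len Minimum DMR span (bp).
#' @return A `dmr_set` data.frame: `chrom`, `start`, `end`, `n_cpg`, `delta`
#'   (maximum candidate delta).
#' @export
call_dmrs <- function(stats, delta_min = 10, p_max = 0.001, min_cpgs = 3L,
                      max_gap = 300, min_len = 50) {
  cand <- stats[!is.na(stats$p) & stats$delta > delta_min & stats$p < p_max, ]
  cand <- cand[order(cand$chrom, cand$pos), ]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0),
                      delta = numeric(0))
  class(empty) <- c("dmr_set", "data.frame")
  if (nrow(cand) == 0L) return(empty)
  out <- lapply(split(cand, cand$chrom), function(cc) {
    gap <- c(Inf, diff(cc$pos))
    grp <- cumsum(gap > max_gap)
    do.call(rbind, lapply(split(cc, grp), function(g) {
      data.frame(chrom = g$chrom[1L], start = min(g$pos),
                 end = max(g$pos) + 2L, n_cpg = nrow(g),
                 delta = max(g$delta), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_cpg >= min_cpgs & (out$end - out$start) >= min_len, ]
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Merge DMR sets across tissues by interval union
#'
#' Epiblast and EPC DMR calls are merged: overlapping or bookended
#' intervals collapse into one. `n_cpg` and `delta` carry the constituent
#' maxima (allelic methylation is re-summarised over the merged intervals
#' afterwards).
#'
#' @param ... `dmr_set` data.frames.
#' @return Merged `dmr_set`.
#' @export
merge_dmr_sets <- function(...) {
  all <- do.call(rbind, lapply(list(...), function(d) {
    d[c("chrom", "start", "end", "n_cpg", "delta")]
  }))
  if (nrow(all) == 0L) {
    class(all) <- c("dmr_set", "data.frame")
    return(all)
  }
  out <- do.call(rbind, lapply(split(all, all$chrom), function(cc) {
    ir <- IRanges::reduce(IRanges::IRanges(cc$start + 1L, cc$end))
    hits <- IRanges::findOverlaps(IRanges::IRanges(cc$start + 1L, cc$end), ir)
    grp <- S4Vectors::subjectHits(hits)
    data.frame(chrom = cc$chrom[1L], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir),
               n_cpg = as.integer(tapply(cc$n_cpg, grp, max)),
               delta = as.numeric(tapply(cc$delta, grp, max)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Mean allelic methylation of one DMR per sample/track
#'
#' Per (sample, allele) track, the mean of per-CpG methylation fractions
#' over covered CpGs inside the interval, with coverage filters of 5 reads
#' for pooled tracks (total, oocyte, sperm) and 1 read for allelic tracks.
#'
#' @param dmr One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param cpgs CpG record table.
#' @param min_total_cov,min_allelic_cov Coverage thresholds.
#' @return Data.frame `sample_id`, `allele`, `mean_meth` (percent; NA when
#'   no CpG passes), `n_cpg`.
#' @export
summarize_dmr_allelic_meth <- function(dmr, cpgs, min_total_cov = 5,
                                       min_allelic_cov = 1) {
  stopifnot(dmr$start < dmr$end)
  sub <- cpgs[cpgs$chrom == dmr$chrom & cpgs$pos >= dmr$start &
                cpgs$pos < dmr$end, ]
  cov <- sub$meth_reads + sub$unmeth_reads
  need <- ifelse(sub$allele %in% c("maternal", "paternal"),
                 min_allelic_cov, min_total_cov)
  sub <- sub[cov >= need, ]
  cov <- sub$meth_reads + sub$unmeth_reads
  if (nrow(sub) == 0L) {
    return(data.frame(sample_id = character(0), allele = character(0),
                      mean_meth = numeric(0), n_cpg = integer(0)))
  }
  frac <- sub$meth_reads / cov
  agg <- stats::aggregate(frac, by = list(sample_id = sub$sample_id,
                                          allele = sub$allele), FUN = mean)
  cnt <- stats::aggregate(frac, by = list(sample_id = sub$sample_id,
                                          allele = sub$allele), FUN = length)
  data.frame(sample_id = agg$sample_id, allele = agg$allele,
             mean_meth = agg$x * 100, n_cpg = as.integer(cnt$x),
             stringsAsFactors = FALSE)
}

#' Classify a DMR's parental origin by integrating gamete methylomes
#'
#' Decision table (evaluated in order of precedence):
#' \enumerate{
#'   \item gametic_maternal: oocyte - sperm >= `gamete_delta_min` and some
#'     tissue shows maternal - paternal >= `gamete_delta_min`;
#'   \item gametic_paternal: the mirror image;
#'   \item gametes_hypermethylated: both gametes >= `hyper_min`;
#'   \item somatic_maternal / somatic_paternal: gametes similar
#'     (|oocyte - sperm| < `gamete_delta_min`) but some tissue shows a
#'     parental difference >= `gamete_delta_min`;
#'   \item ambiguous otherwise (including missing gamete summaries, which
#'     set attribute `missing_gametes`).
#' }
#'
#' @param summary Track summary from [summarize_dmr_allelic_meth()].
#' @param tissues Tissue sample ids to consider.
#' @param gamete_delta_min,hyper_min Thresholds in percentage points.
#' @return Character origin label, with attribute `tissues_supporting`.
#' @export
classify_dmr_origin <- function(summary, tissues = c("epiblast", "EPC"),
                                gamete_delta_min = 50, hyper_min = 75) {
  get <- function(sid, allele) {
    v <- summary$mean_meth[summary$sample_id == sid &
                             summary$allele == allele]
    if (length(v) == 0L) NA_real_ else v[1L]
  }
  oo <- get("oocyte", "oocyte")
  sp <- get("sperm", "sperm")
  mat <- vapply(tissues, get, numeric(1), allele = "maternal")
  pat <- vapply(tissues, get, numeric(1), allele = "paternal")
  tdelta <- mat - pat
  if (is.na(oo) || is.na(sp)) {
    out <- "ambiguous"
    attr(out, "missing_gametes") <- TRUE
    return(out)
  }
  sup_m <- tissues[!is.na(tdelta) & tdelta >= gamete_delta_min]
  sup_p <- tissues[!is.na(tdelta) & -tdelta >= gamete_delta_min]
  out <-
    if (oo - sp >= gamete_delta_min && length(sup_m) > 0L) "gametic_maternal"
    else if (sp - oo >= gamete_delta_min && length(sup_p) > 0L) "gametic_paternal"
    else if (oo >= hyper_min && sp >= hyper_min) "gametes_hypermethylated"
    else if (abs(oo - sp) < gamete_delta_min && length(sup_m) > 0L) "somatic_maternal"
    else if (abs(oo - sp) < gamete_delta_min && length(sup_p) > 0L) "somatic_paternal"
    else "ambiguous"
  attr(out, "tissues_supporting") <-
    if (grepl("paternal$", out)) sup_p else sup_m
  out
}

#' Attach allelic summaries and origin labels to a DMR set
#'
#' @param dmrs A `dmr_set`.
#' @param cpgs CpG record table covering tissues and gametes.
#' @param tissues Tissue sample ids.
#' @param min_total_cov,min_allelic_cov Coverage thresholds per track.
#' @param gamete_delta_min,hyper_min Origin-classification thresholds.
#' @return `dmr_set` with per-track mean columns (`oocyte`, `sperm`, and
#'   `<tissue>_maternal` / `<tissue>_paternal`), per-track covered-CpG
#'   minima (`min_track_cpgs`), `parental_delta` (max over tissues, signed
#'   maternal - paternal magnitude reported as absolute), `origin` and
#'   `tissues_supporting`.
#' @export
annotate_dmrs <- function(dmrs, cpgs, tissues = c("epiblast", "EPC"),
                          min_total_cov = 5, min_allelic_cov = 1,
                          gamete_delta_min = 50, hyper_min = 75) {
  n <- nrow(dmrs)
  dmrs$oocyte <- dmrs$sperm <- NA_real_
  for (tis in tissues) {
    dmrs[[paste0(tis, "_maternal")]] <- NA_real_
    dmrs[[paste0(tis, "_paternal")]] <- NA_real_
  }
  dmrs$min_track_cpgs <- NA_integer_
  dmrs$parental_delta <- NA_real_
  dmrs$origin <- NA_character_
  dmrs$tissues_supporting <- NA_character_
  if (n == 0L) return(dmrs)
  tracks <- c("oocyte|oocyte", "sperm|sperm",
              unlist(lapply(tissues, function(t) paste(t, c("maternal",
                                                            "paternal"),
                                                       sep = "|"))))
  for (i in seq_len(n)) {
    sm <- summarize_dmr_allelic_meth(dmrs[i, ], cpgs, min_total_cov,
                                     min_allelic_cov)
    key <- paste(sm$sample_id, sm$allele, sep = "|")
    dmrs$oocyte[i] <- if ("oocyte|oocyte" %in% key)
      sm$mean_meth[key == "oocyte|oocyte"] else NA_real_
    dmrs$sperm[i] <- if ("sperm|sperm" %in% key)
      sm$mean_meth[key == "sperm|sperm"] else NA_real_
    deltas <- numeric(0)
    for (tis in tissues) {
      km <- paste(tis, "maternal", sep = "|")
      kp <- paste(tis, "paternal", sep = "|")
      mm <- if (km %in% key) sm$mean_meth[key == km] else NA_real_
      pp <- if (kp %in% key) sm$mean_meth[key == kp] else NA_real_
      dmrs[[paste0(tis, "_maternal")]][i] <- mm
      dmrs[[paste0(tis, "_paternal")]][i] <- pp
      if (!is.na(mm) && !is.na(pp)) deltas <- c(deltas, abs(mm - pp))
    }
    present <- intersect(tracks, key)
    cnt <- sm$n_cpg[match(present, key)]
    dmrs$min_track_cpgs[i] <- if (length(present) < length(tracks)) 0L
                              else min(cnt)
    dmrs$parental_delta[i] <- if (length(deltas) > 0L) max(deltas) else NA_real_
    org <- classify_dmr_origin(sm, tissues, gamete_delta_min, hyper_min)
    dmrs$origin[i] <- as.character(org)
    ts <- attr(org, "tissues_supporting")
    dmrs$tissues_supporting[i] <- if (length(ts) > 0L)
      paste(ts, collapse = ",") else ""
  }
  class(dmrs) <- c("dmr_set", "data.frame")
  dmrs
}

#' Final DMR filter on coverage and parental delta
#'
#' Keeps DMRs in which every required track (gametes and both parental
#' alleles of every tissue) is covered by at least `min_cpgs_all` CpGs and
#' the tissue parental methylation difference reaches `delta_min`.
#'
#' @param dmrs Annotated `dmr_set` from [annotate_dmrs()].
#' @param min_cpgs_all Covered CpGs required in every track.
#' @param delta_min Parental delta threshold (percentage points).
#' @return Filtered `dmr_set`.
#' @export
final_filter <- function(dmrs, min_cpgs_all = 2L, delta_min = 50) {
  keep <- !is.na(dmrs$min_track_cpgs) & dmrs$min_track_cpgs >= min_cpgs_all &
    !is.na(dmrs$parental_delta) & dmrs$parental_delta >= delta_min
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Tabulate DMR origins
#'
#' @param origin Character vector of origin labels (or an annotated
#'   `dmr_set`, whose `origin` column is used).
#' @return Data.frame `origin`, `n`, `pct` (percent of all DMRs).
#' @export
dmr_origin_summary <- function(origin) {
  if (is.data.frame(origin)) origin <- origin$origin
  tab <- table(origin)
  data.frame(origin = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set: %d region(s)", nrow(x)))
  if (nrow(x) > 0L && !is.null(x$origin) && !all(is.na(x$origin))) {
    tb <- table(x$origin)
    cat(" [", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "]",
        sep = "")
  }
  cat("\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
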