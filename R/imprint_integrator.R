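# Joins expression calls, DMRs, oocyte H3K27me3 domains and sequence
# features into a per-gene atlas with canonical / non-canonical mode labels.
#
# Canonical imprints carry a gametic DMR; non-canonical imprints show
# paternal-specific expression restricted to extraembryonic tissue with no
# germline DMR, supported by a post-fertilization (somatic) maternal DMR or
# an oocyte H3K27me3 domain over the promoter.

#' Assign the nearest DMR to a gene TSS
#'
#' The nearest DMR by distance to the TSS is assigned (ties broken by the
#' smaller start coordinate). The relation is `promoter` when the DMR
#' overlaps the TSS or the `promoter_window` bp immediately upstream
#' (strand-aware), `intragenic` when it lies within the gene body, and
#' `distal` otherwise, with the signed distance reported.
#'
#' @param gene One-row data.frame (or list) with `chrom`, `strand`, `tss`,
#'   `tx_start`, `tx_end`.
#' @param dmrs A `dmr_set` (annotated or not).
#' @param promoter_window Upstream window in bp.
#' @return List with `dmr` (the assigned row, or `NULL` when no DMR shares
#'   the chromosome), `relation` and `distance` (bp; 0 when overlapping).
#' @export
assign_dmr_to_gene <- function(gene, dmrs, promoter_window = 5000) {
  d <- dmrs[dmrs$chrom == gene$chrom, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(list(dmr = NULL, relation = NA_character_, distance = NA_real_))
  }
  # distance from the TSS point to each half-open interval
  dist <- ifelse(gene$tss < d$start, d$start - gene$tss,
                 ifelse(gene$tss >= d$end, gene$tss - d$end + 1L, 0L))
  best <- which(dist == min(dist))
  best <- best[which.min(d$start[best])]
  dmr <- d[best, , drop = FALSE]
  prom <- if (gene$strand == "+") {
    c(gene$tss - promoter_window, gene$tss + 1L)
  } else {
    c(gene$tss, gene$tss + promoter_window + 1L)
  }
  overlaps <- function(s, e, ws, we) s < we && e > ws
  relation <- if (overlaps(dmr$start, dmr$end, prom[1L], prom[2L])) {
    "promoter"
  } else if (overlaps(dmr$start, dmr$end, gene$tx_start, gene$tx_end)) {
    "intragenic"
  } else {
    "distal"
  }
  signed <- if (gene$tss < dmr$start) dmr$start - gene$tss
            else -(gene$tss - dmr$end + 1L)
  list(dmr = dmr, relation = relation,
       distance = if (relation == "distal") signed else 0L)
}

#' Scan a sequence for ZFP57 binding motifs
#'
#' Reports every occurrence of the hexamer TGCCGC on the plus strand and of
#' its reverse complement GCGGCA (a TGCCGC site on the minus strand).
#' Overlapping matches are all reported; offsets are 0-based.
#'
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @return Data.frame with `offset` and `strand`, sorted by offset.
#' @export
scan_zfp57_motifs <- function(sequence) {
  seq <- toupper(sequence)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N", call. = FALSE)
  }
  find_all <- function(motif) {
    hits <- integer(0)
    from <- 1L
    repeat {
      i <- regexpr(motif, substr(seq, from, nchar(seq)), fixed = TRUE)
      if (i == -1L) break
      hits <- c(hits, from + i - 1L)
      from <- from + i  # advance one base: overlapping matches count
    }
    hits
  }
  plus <- find_all("TGCCGC")
  minus <- find_all("GCGGCA")
  out <- data.frame(
    offset = c(plus, minus) - 1L,
    strand = rep(c("+", "-"), c(length(plus), length(minus))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a gene's imprinting mode
#'
#' Deterministic rules given upstream calls:
#' \itemize{
#'   \item `canonical`: imprinted in at least one tissue and the assigned
#'     DMR is gametic;
#'   \item `non_canonical`: paternal in the extraembryonic tissue, not
#'     paternal in the embryonic tissue (a weak, non-significant
#'     same-direction bias is tolerated), no gametic DMR, and either a
#'     somatic maternal DMR is assigned or the promoter overlaps an oocyte
#'     H3K27me3 domain;
#'   \item `transient_candidate`: biallelic in both tissues but the promoter
#'     overlaps an oocyte H3K27me3 domain (primed for imprinting);
#'   \item `unclassified` otherwise.
#' }
#'
#' @param status_embryonic,status_extraembryonic Call status per tissue
#'   (`paternal`, `maternal`, `biallelic`, `not_testable`).
#' @param dmr_origin Origin label of the assigned DMR, or `NA`.
#' @param oocyte_k27_overlap Logical: promoter overlaps an oocyte H3K27me3
#'   domain.
#' @return Mode label.
#' @export
classify_imprinting_mode <- function(status_embryonic,
                                     status_extraembryonic,
                                     dmr_origin = NA_character_,
                                     oocyte_k27_overlap = FALSE) {
  imprinted <- c("paternal", "maternal")
  gametic <- !is.na(dmr_origin) &&
    dmr_origin %in% c("gametic_maternal", "gametic_paternal")
  somatic_mat <- !is.na(dmr_origin) && dmr_origin == "somatic_maternal"
  if ((status_embryonic %in% imprinted ||
       status_extraembryonic %in% imprinted) && gametic) {
    return("canonical")
  }
  if (status_extraembryonic == "paternal" &&
      status_embryonic != "paternal" && !gametic &&
      (somatic_mat || isTRUE(oocyte_k27_overlap))) {
    return("non_canonical")
  }
  if (isTRUE(oocyte_k27_overlap) && status_embryonic == "biallelic" &&
      status_extraembryonic == "biallelic") {
    return("transient_candidate")
  }
  "unclassified"
}

.overlaps_any <- function(chrom, start, end, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(FALSE)
  sub <- intervals[intervals$chrom == chrom, , drop = FALSE]
  any(sub$start < end & sub$end > start)
}

#' Build the per-gene imprinting atlas
#'
#' Joins the per-tissue expression calls, the annotated DMR set, oocyte
#' H3K27me3 domains and (optionally) promoter sequences into one row per
#' gene that is imprinted or flagged in either tissue. Maternal
#' extraembryonic calls flagged `blood_expressed` are kept in the table but
#' labelled by flag and never counted as imprinted (so they cannot drive a
#' canonical/non-canonical mode).
#'
#' @param calls_embryonic,calls_extraembryonic `imprint_calls` for the two
#'   tissues (after [decidua_filter()] for the extraembryonic one).
#' @param dmrs Annotated `dmr_set` (may have zero rows).
#' @param k27_domains Data.frame `chrom`, `start`, `end` of oocyte H3K27me3
#'   domains (or `NULL`).
#' @param genes Gene table with `gene_id`, `chrom`, `strand`, `tss`,
#'   `tx_start`, `tx_end`.
#' @param sequences Optional named character vector of promoter sequences
#'   per gene for ZFP57 scanning.
#' @param promoter_window Upstream window for DMR assignment and H3K27me3
#'   overlap (bp).
#' @return An `imprint_atlas` data.frame.
#' @export
build_atlas <- function(calls_embryonic, calls_extraembryonic, dmrs,
                        k27_domains = NULL, genes, sequences = NULL,
                        promoter_window = 5000) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene ids in gene table", call. = FALSE)
  }
  st <- function(calls, id) {
    i <- match(id, calls$transcript_id)
    if (is.na(i)) return(list(status = "not_testable", flagged = FALSE))
    s <- calls$status[i]
    fl <- isTRUE(calls$blood_expressed[i])
    if (fl) s <- "biallelic"  # excluded from the maternal list
    list(status = s, flagged = fl)
  }
  rows <- lapply(genes$gene_id, function(id) {
    g <- genes[genes$gene_id == id, ]
    emb <- st(calls_embryonic, id)
    epc <- st(calls_extraembryonic, id)
    asg <- assign_dmr_to_gene(g, dmrs, promoter_window)
    prom <- if (g$strand == "+") c(g$tss - promoter_window, g$tss + 1L)
            else c(g$tss, g$tss + promoter_window + 1L)
    k27 <- .overlaps_any(g$chrom, prom[1L], prom[2L], k27_domains)
    origin <- if (is.null(asg$dmr)) NA_character_ else asg$dmr$origin
    nz <- if (!is.null(sequences) && id %in% names(sequences)) {
      nrow(scan_zfp57_motifs(sequences[[id]]))
    } else NA_integer_
    mode <- classify_imprinting_mode(emb$status, epc$status, origin, k27)
    keep <- emb$status %in% c("paternal", "maternal") ||
      epc$status %in% c("paternal", "maternal") || emb$flagged ||
      epc$flagged || mode == "transient_candidate"
    if (!keep) return(NULL)
    data.frame(
      gene_id = id, status_embryonic = emb$status,
      status_extraembryonic = epc$status,
      dmr_chrom = if (is.null(asg$dmr)) NA_character_ else asg$dmr$chrom,
      dmr_start = if (is.null(asg$dmr)) NA_integer_ else asg$dmr$start,
      dmr_end = if (is.null(asg$dmr)) NA_integer_ else asg$dmr$end,
      dmr_relation = asg$relation, dmr_distance = asg$distance,
      dmr_origin = origin, oocyte_k27_overlap = k27,
      zfp57_motifs = nz, mode = mode,
      blood_expressed = emb$flagged || epc$flagged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), status_embryonic = character(0),
                      status_extraembryonic = character(0),
                      dmr_chrom = character(0), dmr_start = integer(0),
                      dmr_end = integer(0), dmr_relation = character(0),
                      dmr_distance = numeric(0), dmr_origin = character(0),
                      oocyte_k27_overlap = logical(0),
                      zfp57_motifs = integer(0), mode = character(0),
                      blood_expressed = logical(0))
  }
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("imprint_atlas", "data.frame")
  out
}

#' @export
print.imprint_atlas <- function(x, ...) {
  cat(sprintf("imprint_atlas: %d gene(s)", nrow(x)))
  if (nrow(x) > 0L) {
    tb <- table(x$mode)
    cat(" [", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "]",
        sep = "")
  }
  cat("\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
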