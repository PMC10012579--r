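# DMR-to-gene assignment, mode classification, ZFP57 motif scanning and
# atlas assembly.

mk_gene <- function(chrom = "chr1", strand = "+", tss = 10000,
                    tx_start = 10000, tx_end = 20000) {
  list(chrom = chrom, strand = strand, tss = tss, tx_start = tx_start,
       tx_end = tx_end)
}

mk_dmrs <- function(starts, ends, chrom = "chr1",
                    origin = "gametic_maternal") {
  n <- length(starts)
  d <- data.frame(chrom = rep_len(chrom, n), start = starts, end = ends,
                  n_cpg = rep_len(5L, n), delta = rep_len(80, n),
                  origin = rep_len(origin, n), stringsAsFactors = FALSE)
  class(d) <- c("dmr_set", "data.frame")
  d
}

test_that("DMR assignment is strand-aware within the 5-kb promoter window", {
  # + strand, DMR within 5 kb upstream of the TSS
  a <- assign_dmr_to_gene(mk_gene(), mk_dmrs(6000, 7000))
  expect_equal(a$relation, "promoter")
  # - strand: upstream is to the right
  b <- assign_dmr_to_gene(mk_gene(strand = "-", tx_start = 2000,
                                  tx_end = 10000),
                          mk_dmrs(12000, 13000))
  expect_equal(b$relation, "promoter")
  # beyond the gene body: distal with signed distance
  cc <- assign_dmr_to_gene(mk_gene(), mk_dmrs(30000, 31000))
  expect_equal(cc$relation, "distal")
  expect_equal(cc$distance, 20000)
  # inside the gene body
  d <- assign_dmr_to_gene(mk_gene(), mk_dmrs(15000, 16000))
  expect_equal(d$relation, "intragenic")
  # nearest wins; ties break toward the smaller start
  e <- assign_dmr_to_gene(mk_gene(tss = 10000),
                          mk_dmrs(c(30000, 50000), c(31000, 51000)))
  expect_equal(e$dmr$start, 30000)
  tie <- assign_dmr_to_gene(
    mk_gene(tss = 50000, tx_start = 50000, tx_end = 51000),
    mk_dmrs(c(30000, 60000), c(40001, 70000)))  # both 10 kb from the TSS
  expect_equal(tie$dmr$start, 30000)
  # no DMR on the chromosome
  f <- assign_dmr_to_gene(mk_gene(chrom = "chr9"), mk_dmrs(1000, 2000))
  expect_null(f$dmr)
})

test_that("ZFP57 hexamer scan reports both strands and overlaps", {
  h1 <- scan_zfp57_motifs("AATGCCGCAA")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$offset, 2L)
  expect_equal(h1$strand, "+")

  # the gained motif: GCGGCA is TGCCGC on the minus strand
  h2 <- scan_zfp57_motifs("TTGCGGCATT")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")

  # one substitution away (the consensus and the reverted variant): no hit
  expect_equal(nrow(scan_zfp57_motifs("TTGCAGCGTT")), 0L)
  expect_equal(nrow(scan_zfp57_motifs("TTGCGACATT")), 0L)

  # overlapping occurrences are all reported
  h3 <- scan_zfp57_motifs("TGCCGCGGCA")
  expect_equal(nrow(h3), 2L)
  expect_equal(sort(h3$offset), c(0L, 4L))

  expect_error(scan_zfp57_motifs("ACGTX"), "A/C/G/T/N")
  expect_equal(nrow(scan_zfp57_motifs("tgccgc")), 1L)  # case-insensitive
})

test_that("mode classification implements the canonical / non-canonical rules", {
  expect_equal(classify_imprinting_mode("paternal", "paternal",
                                        "gametic_maternal", FALSE),
               "canonical")
  expect_equal(classify_imprinting_mode("biallelic", "paternal",
                                        "somatic_maternal", TRUE),
               "non_canonical")
  expect_equal(classify_imprinting_mode("not_testable", "paternal",
                                        NA, TRUE),
               "non_canonical")
  expect_equal(classify_imprinting_mode("biallelic", "biallelic", NA, TRUE),
               "transient_candidate")
  # paternal in both tissues without any DMR or K27 support: unclassified
  expect_equal(classify_imprinting_mode("paternal", "paternal", NA, FALSE),
               "unclassified")
  # non-canonical requires extraembryonic restriction
  expect_equal(classify_imprinting_mode("paternal", "paternal",
                                        "somatic_maternal", TRUE),
               "unclassified")
  # and requires one line of epigenetic evidence
  expect_equal(classify_imprinting_mode("biallelic", "paternal", NA, FALSE),
               "unclassified")
})

mk_calls <- function(ids, status, tissue, blood = FALSE) {
  df <- data.frame(transcript_id = ids, tissue = tissue, status = status,
                   mean_ratio = NA_real_, raw_p = NA_real_, adj_p = NA_real_,
                   n_valid_samples = 6L, test = "t_test",
                   blood_expressed = blood, stringsAsFactors = FALSE)
  class(df) <- c("imprint_calls", "data.frame")
  df
}

test_that("atlas assembly joins calls, DMRs and H3K27me3 with correct modes", {
  genes <- data.frame(
    gene_id = c("can", "noncan", "trans", "plain", "bloodflag"),
    chrom = "chr1", strand = "+",
    tss = c(10000, 50000, 90000, 130000, 170000),
    tx_start = c(10000, 50000, 90000, 130000, 170000),
    tx_end = c(20000, 60000, 100000, 140000, 180000),
    stringsAsFactors = FALSE)
  epi <- mk_calls(genes$gene_id,
                  c("paternal", "biallelic", "biallelic", "biallelic",
                    "biallelic"), "epiblast")
  epc <- mk_calls(genes$gene_id,
                  c("paternal", "paternal", "biallelic", "biallelic",
                    "maternal"), "EPC",
                  blood = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  dmrs <- mk_dmrs(c(8000, 48000), c(9000, 49000),
                  origin = c("gametic_maternal", "somatic_maternal"))
  k27 <- data.frame(chrom = "chr1", start = 46000, end = 52000)
  seqs <- c(can = "AATGCCGCAA", noncan = "ACGTACGT")
  atlas <- build_atlas(epi, epc, dmrs, k27, genes, sequences = seqs)
  expect_equal(atlas$mode[atlas$gene_id == "can"], "canonical")
  expect_equal(atlas$mode[atlas$gene_id == "noncan"], "non_canonical")
  # biallelic everywhere with no K27 support: nothing to report
  expect_false("trans" %in% atlas$gene_id)
  expect_false("plain" %in% atlas$gene_id)
  # blood-flagged maternal call is retained with the flag but not imprinted
  bf <- atlas[atlas$gene_id == "bloodflag", ]
  expect_true(bf$blood_expressed)
  expect_equal(bf$status_extraembryonic, "biallelic")
  expect_equal(atlas$zfp57_motifs[atlas$gene_id == "can"], 1L)
  # mode invariants hold for every emitted row
  nc <- atlas[atlas$mode == "non_canonical", ]
  expect_true(all(nc$status_extraembryonic == "paternal" &
                    nc$status_embryonic != "paternal" &
                    (is.na(nc$dmr_origin) |
                       !grepl("^gametic", nc$dmr_origin))))
  can <- atlas[atlas$mode == "canonical", ]
  expect_true(all(grepl("^gametic", can$dmr_origin)))

  expect_error(build_atlas(epi, epc, dmrs, k27, rbind(genes, genes[1, ])),
               "duplicate")
  # no imprinted calls -> empty atlas
  none <- mk_calls(genes$gene_id, rep("biallelic", 5), "epiblast")
  empty <- build_atlas(none, mk_calls(genes$gene_id, rep("biallelic", 5),
                                      "EPC"),
                       mk_dmrs(integer(0), integer(0)), NULL, genes)
  expect_equal(nrow(empty), 0L)
})

test_that("transient candidates need K27 overlap with biallelic expression", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      tss = 10000, tx_start = 10000, tx_end = 20000,
                      stringsAsFactors = FALSE)
  epi <- mk_calls("g", "biallelic", "epiblast")
  epc <- mk_calls("g", "biallelic", "EPC")
  k27 <- data.frame(chrom = "chr1", start = 7000, end = 11000)
  atlas <- build_atlas(epi, epc, mk_dmrs(integer(0), integer(0)), k27, genes)
  expect_equal(atlas$mode, "transient_candidate")
})
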