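# Smoothing, per-CpG exact testing, grouping, origin classification and
# the final DMR filter.

test_that("coverage-weighted smoothing has the expected fixed points", {
  pos <- seq(0, 900, by = 100)
  # constant 80% over 10 CpGs stays 80%
  sm <- smooth_methylation(pos, meth = rep(8, 10), unmeth = rep(2, 10))
  expect_equal(sm, rep(0.8, 10))
  # a single CpG keeps its raw fraction
  expect_equal(smooth_methylation(500, 3, 7), 0.3)
  # step 0% -> 100% at a window edge: hand-computed coverage-weighted mean
  pos2 <- c(0, 200, 400, 600)
  meth2 <- c(0, 0, 10, 10); unmeth2 <- c(10, 10, 0, 0)
  sm2 <- smooth_methylation(pos2, meth2, unmeth2, span = 500)
  # CpG at 400 sees 200 (0/10), 400 (10/10), 600 (10/10): 20/30
  expect_equal(sm2[3], 20 / 30)
  expect_equal(sm2[2], 10 / 30)
  expect_equal(smooth_methylation(numeric(0), numeric(0), numeric(0)),
               numeric(0))
  expect_error(smooth_methylation(c(5, 1), c(1, 1), c(1, 1)), "sorted")
})

test_that("per-CpG test agrees with the Fisher exact oracle", {
  r1 <- test_cpg_diff(20, 0, 0, 20)
  expect_equal(r1$delta, 100)
  expect_lt(r1$p, 1e-9)
  expect_equal(r1$p, fisher.test(matrix(c(20, 0, 0, 20), 2))$p.value)

  r2 <- test_cpg_diff(10, 10, 10, 10)
  expect_equal(r2$delta, 0)
  expect_equal(r2$p, 1)

  # full delta but hopeless power: never a candidate at p < 0.001
  r3 <- test_cpg_diff(1, 0, 0, 1)
  expect_equal(r3$delta, 100)
  expect_gt(r3$p, 0.001)

  expect_error(test_cpg_diff(0, 0, 5, 5), "coverage")
})

mk_stats <- function(pos, delta, p, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, m_meth = 9, m_unmeth = 1,
             p_meth = 1, p_unmeth = 9, m_smooth = 0.9, p_smooth = 0.1,
             delta = delta, p = p, stringsAsFactors = FALSE)
}

test_that("candidate CpGs group into DMRs by gap, count and span", {
  # 6 candidates 50 bp apart -> one DMR spanning them
  st <- mk_stats(seq(1000, 1250, by = 50), delta = 90, p = 1e-8)
  d <- call_dmrs(st)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 1000L)
  expect_equal(d$end, 1252L)
  expect_equal(d$n_cpg, 6L)

  # no candidates -> empty
  st2 <- mk_stats(seq(1000, 1250, by = 50), delta = 2, p = 0.8)
  expect_equal(nrow(call_dmrs(st2)), 0L)

  # two blocks 1 kb apart (> max_gap) -> two DMRs
  st3 <- rbind(mk_stats(seq(1000, 1200, by = 50), 90, 1e-8),
               mk_stats(seq(2200, 2400, by = 50), 90, 1e-8))
  expect_equal(nrow(call_dmrs(st3)), 2L)

  # row order does not matter
  st4 <- st3[sample(nrow(st3)), ]
  expect_equal(call_dmrs(st4), call_dmrs(st3))

  # fewer than min_cpgs or too short a span is rejected
  expect_equal(nrow(call_dmrs(mk_stats(c(1000, 1100), 90, 1e-8))), 0L)
  expect_equal(nrow(call_dmrs(mk_stats(c(1000, 1010, 1020), 90, 1e-8),
                              min_len = 50)), 0L)
})

test_that("DMR sets merge by interval union across tissues", {
  a <- data.frame(chrom = "chr1", start = c(100L, 5000L), end = c(300L, 5400L),
                  n_cpg = c(5L, 4L), delta = c(60, 70))
  class(a) <- c("dmr_set", "data.frame")
  b <- data.frame(chrom = "chr1", start = 250L, end = 600L, n_cpg = 8L,
                  delta = 90)
  class(b) <- c("dmr_set", "data.frame")
  m <- merge_dmr_sets(a, b)
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(100L, 5000L))
  expect_equal(m$end, c(600L, 5400L))
  expect_equal(m$delta[1], 90)
})

test_that("allelic summaries respect per-track coverage thresholds", {
  cpgs <- data.frame(
    chrom = "chr1", pos = c(100L, 150L, 200L, 100L, 150L, 200L, 100L, 150L),
    sample_id = c(rep("EPC", 6), "EPC", "EPC"),
    allele = c(rep("maternal", 3), rep("paternal", 3), "total", "total"),
    meth_reads = c(1L, 1L, 1L, 0L, 0L, 0L, 4L, 10L),
    unmeth_reads = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  dmr <- data.frame(chrom = "chr1", start = 50L, end = 250L)
  sm <- summarize_dmr_allelic_meth(dmr, cpgs)
  mat <- sm[sm$allele == "maternal", ]
  expect_equal(mat$mean_meth, 100)
  expect_equal(mat$n_cpg, 3L)
  # total track needs coverage >= 5: the 4-read CpG drops, one remains
  tot <- sm[sm$allele == "total", ]
  expect_equal(tot$n_cpg, 1L)
  # empty overlap
  sm2 <- summarize_dmr_allelic_meth(data.frame(chrom = "chr1", start = 1000L,
                                               end = 2000L), cpgs)
  expect_equal(nrow(sm2), 0L)
})

mk_summary <- function(oo, sp, epi_m = NA, epi_p = NA, epc_m = NA,
                       epc_p = NA) {
  df <- data.frame(
    sample_id = c("oocyte", "sperm", "epiblast", "epiblast", "EPC", "EPC"),
    allele = c("oocyte", "sperm", "maternal", "paternal", "maternal",
               "paternal"),
    mean_meth = c(oo, sp, epi_m, epi_p, epc_m, epc_p),
    n_cpg = 5L, stringsAsFactors = FALSE)
  df[!is.na(df$mean_meth), ]
}

test_that("origin classification follows the gamete-integrated decision table", {
  expect_equal(as.character(classify_dmr_origin(
    mk_summary(95, 5, epi_m = 90, epi_p = 10))), "gametic_maternal")
  expect_equal(as.character(classify_dmr_origin(
    mk_summary(5, 95, epi_m = 10, epi_p = 90))), "gametic_paternal")
  # lack of a germline difference with an EPC-only parental difference is
  # the non-canonical (somatic) signature
  expect_equal(as.character(classify_dmr_origin(
    mk_summary(5, 5, epc_m = 80, epc_p = 5))), "somatic_maternal")
  expect_equal(as.character(classify_dmr_origin(
    mk_summary(90, 88, epc_m = 90, epc_p = 10))), "gametes_hypermethylated")
  expect_equal(as.character(classify_dmr_origin(
    mk_summary(50, 45, epc_m = 55, epc_p = 40))), "ambiguous")
  # missing gametes flag
  out <- classify_dmr_origin(mk_summary(NA, NA, epc_m = 90, epc_p = 5))
  expect_equal(as.character(out), "ambiguous")
  expect_true(attr(out, "missing_gametes"))
  # supporting tissues are recorded
  g <- classify_dmr_origin(mk_summary(95, 5, epi_m = 90, epi_p = 10,
                                      epc_m = 85, epc_p = 20))
  expect_setequal(attr(g, "tissues_supporting"), c("epiblast", "EPC"))
})

test_that("the final filter enforces CpG coverage and the 50-point delta", {
  dmrs <- data.frame(chrom = "chr1", start = c(1L, 100L, 200L),
                     end = c(50L, 150L, 250L), n_cpg = 5L, delta = 90,
                     min_track_cpgs = c(1L, 3L, 3L),
                     parental_delta = c(80, 45, 60),
                     origin = "gametic_maternal")
  class(dmrs) <- c("dmr_set", "data.frame")
  out <- final_filter(dmrs)
  expect_equal(out$start, 200L)  # low coverage and low delta both dropped
})

test_that("planted DMRs are recovered with matching origin labels", {
  sm <- simulate_methylomes(small_meth_config(seed = 11))
  called <- merge_dmr_sets(
    call_dmrs(compute_cpg_stats(sm$cpgs, "epiblast")),
    call_dmrs(compute_cpg_stats(sm$cpgs, "EPC")))
  expect_equal(nrow(called), nrow(sm$truth))
  expect_gte(interval_jaccard(called, sm$truth), 0.8)
  ann <- annotate_dmrs(called, sm$cpgs)
  # match each called DMR to the planted one it overlaps
  planted <- sm$truth$origin[vapply(seq_len(nrow(ann)), function(i) {
    which(sm$truth$start < ann$end[i] & sm$truth$end > ann$start[i])[1]
  }, integer(1))]
  expect_equal(ann$origin, planted)
  expect_equal(nrow(final_filter(ann)), nrow(sm$truth))
})

test_that("identical parental methylomes yield no DMRs", {
  cfg <- sim_config(seed = 23, n_cpg = 1500,
                    dmrs = data.frame(start = integer(0), end = integer(0),
                                      type = character(0),
                                      tissues = character(0)))
  sm <- simulate_methylomes(cfg)
  st <- compute_cpg_stats(sm$cpgs, "EPC")
  expect_equal(nrow(call_dmrs(st)), 0L)
})

test_that("origin tabulation reports counts and percentages", {
  tab <- dmr_origin_summary(c(rep("gametic_maternal", 3),
                              rep("somatic_maternal", 1)))
  expect_equal(tab$n[tab$origin == "gametic_maternal"], 3L)
  expect_equal(tab$pct[tab$origin == "gametic_maternal"], 75)
  expect_equal(sum(tab$pct), 100)
})
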