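# Synthetic reciprocal F1 hybrid data with known truth.
#
# The generator emulates the statistical structure the inference downstream
# assumes: negative-binomial total counts, beta-binomial allelic splits whose
# parent-of-origin target depends on the gene class, strain-biased genes whose
# bias flips between reciprocal crosses, maternal-decidua contamination in
# extraembryonic samples, planted gametic and post-fertilization DMRs, paired
# species mark tracks with anticorrelated H3K27me3/H3K36me3, and paternal-X
# silencing on a synthetic chrX in EPC samples.

#' Simulation configuration
#'
#' Holds every parameter of the three generators. Defaults describe a
#' two-cross design with three replicates per cross per tissue (12 samples
#' over epiblast and EPC), strongly imprinted classes (paternal ratio
#' 0.95/0.05), a beta-binomial allelic concentration of 200, and a paternal-X
#' expression ratio of 0.2 in EPC.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param n_genes Named integer vector of gene counts per class. Classes:
#'   `biallelic`, `paternal_imprint`, `maternal_imprint`, `strain_biased`,
#'   `decidua_contaminated`, `chrX`.
#' @param replicates Replicates per cross per tissue (>= 1).
#' @param crosses Two cross labels, maternal strain listed first.
#' @param tissues Tissue labels; first is embryonic, second extraembryonic.
#' @param nb_mean,nb_size Negative-binomial mean and size of total counts.
#' @param concentration Beta-binomial concentration of the allelic split.
#' @param allelic_rate Fraction of total reads assignable to an allele.
#' @param library_size Aligned reads per sample (used for RPM/RPKM).
#' @param ratio_paternal,ratio_maternal Target paternal ratios of the
#'   imprinted classes.
#' @param strain_bias Fraction of allelic reads drawn by the favoured strain
#'   (the second strain letter) for `strain_biased` genes.
#' @param xci_paternal_ratio Paternal ratio of chrX transcripts in the
#'   extraembryonic tissue (imprinted XCI skew).
#' @param decidua_rate Maternal contamination reads per allelic read per
#'   blood RPKM unit, applied to `decidua_contaminated` genes in EPC only.
#' @param n_cpg Number of simulated CpGs on the methylome chromosome.
#' @param chrom,chrom_len Methylome chromosome name and length (bp).
#' @param cpg_coverage Mean per-CpG, per-track read coverage (Poisson).
#' @param meth_hyper,meth_hypo Methylation levels inside planted DMRs.
#' @param meth_kappa Beta concentration of per-CpG methylation noise.
#' @param dmrs Planted DMR table with columns `start`, `end`, `type`
#'   (`gametic_maternal`, `gametic_paternal`, `somatic_maternal`,
#'   `somatic_paternal`, `gametes_hypermethylated`) and `tissues`
#'   (`"both"` or `"EPC"`); `NULL` for the default five-DMR layout.
#' @param n_bins Syntenic 1-kb bins per genome for the mark tracks.
#' @param mark_rho Gaussian-copula correlation of H3K27me3 vs H3K36me3.
#' @param mark_sigma Log-normal sigma of mark levels.
#' @param n_domains_a,n_domains_b Planted species-specific H3K27me3 domains
#'   in genome A ("rat") and genome B ("mouse").
#' @param domain_bins Width of each planted domain, in 1-kb bins.
#' @return Object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = c(biallelic = 200L, paternal_imprint = 20L,
                                   maternal_imprint = 20L, strain_biased = 20L,
                                   decidua_contaminated = 10L, chrX = 30L),
                       replicates = 3L,
                       crosses = c("BW", "WB"),
                       tissues = c("epiblast", "EPC"),
                       nb_mean = 200, nb_size = 10,
                       concentration = 200,
                       allelic_rate = 0.5,
                       library_size = 1e6,
                       ratio_paternal = 0.95, ratio_maternal = 0.05,
                       strain_bias = 0.8,
                       xci_paternal_ratio = 0.2,
                       decidua_rate = 0.3,
                       n_cpg = 8000L, chrom = "chr1", chrom_len = 1e6,
                       cpg_coverage = 20,
                       meth_hyper = 0.92, meth_hypo = 0.08, meth_kappa = 60,
                       dmrs = NULL,
                       n_bins = 20000L, mark_rho = -0.5, mark_sigma = 0.25,
                       n_domains_a = 30L, n_domains_b = 10L,
                       domain_bins = 5L) {
  classes <- c("biallelic", "paternal_imprint", "maternal_imprint",
               "strain_biased", "decidua_contaminated", "chrX")
  full <- stats::setNames(integer(length(classes)), classes)
  full[names(n_genes)] <- as.integer(n_genes)
  if (any(full < 0)) stop("gene class counts must be >= 0", call. = FALSE)
  if (replicates < 1L) stop("need at least one replicate per cross", call. = FALSE)
  if (length(crosses) != 2L) stop("exactly two reciprocal crosses required",
                                  call. = FALSE)
  stopifnot(ratio_paternal >= 0, ratio_paternal <= 1,
            ratio_maternal >= 0, ratio_maternal <= 1,
            xci_paternal_ratio >= 0, xci_paternal_ratio <= 1)
  if (is.null(dmrs)) dmrs <- default_planted_dmrs()
  if (nrow(dmrs) > 0L) {
    o <- order(dmrs$start)
    if (any(dmrs$start[o][-1L] < dmrs$end[o][-nrow(dmrs)])) {
      stop("planted DMRs must not overlap", call. = FALSE)
    }
    if (any(dmrs$end > chrom_len)) {
      stop("planted DMRs must lie within the simulated chromosome",
           call. = FALSE)
    }
  }
  cfg <- list(seed = as.integer(seed), n_genes = full, replicates = replicates,
              crosses = crosses, tissues = tissues, nb_mean = nb_mean,
              nb_size = nb_size, concentration = concentration,
              allelic_rate = allelic_rate, library_size = library_size,
              ratio_paternal = ratio_paternal, ratio_maternal = ratio_maternal,
              strain_bias = strain_bias,
              xci_paternal_ratio = xci_paternal_ratio,
              decidua_rate = decidua_rate, n_cpg = as.integer(n_cpg),
              chrom = chrom, chrom_len = chrom_len,
              cpg_coverage = cpg_coverage, meth_hyper = meth_hyper,
              meth_hypo = meth_hypo, meth_kappa = meth_kappa, dmrs = dmrs,
              n_bins = as.integer(n_bins), mark_rho = mark_rho,
              mark_sigma = mark_sigma, n_domains_a = as.integer(n_domains_a),
              n_domains_b = as.integer(n_domains_b),
              domain_bins = as.integer(domain_bins))
  class(cfg) <- "sim_config"
  cfg
}

#' Default planted DMR layout
#'
#' Five non-overlapping DMRs on the simulated chromosome: two maternal
#' gametic, one paternal gametic, one EPC-restricted somatic (maternal),
#' and one hypermethylated in both gametes.
#'
#' @return Data.frame with columns `start`, `end`, `type`, `tissues`.
#' @export
default_planted_dmrs <- function() {
  data.frame(
    start = c(100000L, 300000L, 500000L, 700000L, 880000L),
    end   = c(102000L, 302000L, 502000L, 702000L, 882000L),
    type  = c("gametic_maternal", "gametic_maternal", "gametic_paternal",
              "somatic_maternal", "gametes_hypermethylated"),
    tissues = c("both", "both", "both", "EPC", "both"),
    stringsAsFactors = FALSE
  )
}

.rbetabinom <- function(n, size, prob, concentration) {
  # degenerate targets (0 or 1) have no beta draw
  p <- ifelse(prob <= 0 | prob >= 1, prob,
              stats::rbeta(n, prob * concentration, (1 - prob) * concentration))
  stats::rbinom(n, size, p)
}

#' Simulate reciprocal-cross allelic expression with known truth
#'
#' Generates one record per transcript x sample. Total counts are negative
#' binomial; the maternal/paternal split of allele-assignable reads is
#' beta-binomial around the class target. Strain-biased genes follow strain
#' identity, so their paternal ratio flips between the reciprocal crosses.
#' Decidua-contaminated genes receive extra maternal reads in EPC samples
#' only, proportional to their (simulated) adult blood RPKM. chrX genes are
#' balanced in epiblast and paternally silenced in EPC.
#'
#' @param config A [sim_config()].
#' @return List with elements `records` (allelic count table, ready for
#'   [paternal_ratio_matrix()]), `annotation` (transcript model table with
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`, `tx_start`,
#'   `tx_end`, `exonic_kb`), `truth` (per-gene class, target paternal ratio
#'   per tissue, blood RPKM) and `blood` (blood expression table).
#' @export
simulate_reciprocal_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  total_n <- sum(n)
  classes <- rep(names(n), n)
  gene_id <- sprintf("g%04d", seq_len(total_n))
  chrom <- ifelse(classes == "chrX", "chrX", "chr1")
  tss <- integer(total_n)
  tss[chrom == "chr1"] <- 50000L * seq_len(sum(chrom == "chr1"))
  tss[chrom == "chrX"] <- 50000L * seq_len(sum(chrom == "chrX"))
  annotation <- data.frame(
    transcript_id = gene_id, gene_id = gene_id, chrom = chrom,
    strand = "+", tss = tss, tx_start = tss, tx_end = tss + 5000L,
    exonic_kb = 1, stringsAsFactors = FALSE
  )
  blood_rpkm <- stats::runif(total_n, 0, 0.5)
  blood_rpkm[classes == "decidua_contaminated"] <-
    stats::runif(sum(classes == "decidua_contaminated"), 2, 10)

  # the extraembryonic tissue is the second label; single-tissue configs
  # (embryonic only) have no XCI skew or decidua contamination
  epc_tissue <- if (length(config$tissues) >= 2L) config$tissues[2L]
                else "<none>"
  target <- function(cls, tissue) {
    switch(cls,
           biallelic = 0.5,
           paternal_imprint = config$ratio_paternal,
           maternal_imprint = config$ratio_maternal,
           strain_biased = 0.5,      # parent-of-origin target; bias is by strain
           decidua_contaminated = 0.5,
           chrX = if (tissue == epc_tissue) config$xci_paternal_ratio
                  else 0.5)
  }

  samples <- expand.grid(rep = seq_len(config$replicates),
                         cross = config$crosses, tissue = config$tissues,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$tissue, samples$cross,
                               samples$rep)

  out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    tissue <- samples$tissue[s]
    cross <- samples$cross[s]
    total <- stats::rnbinom(total_n, mu = config$nb_mean, size = config$nb_size)
    allelic <- stats::rbinom(total_n, total, config$allelic_rate)
    ratio <- vapply(classes, target, numeric(1), tissue = tissue)
    # strain-biased genes: the favoured strain is the second cross letter of
    # the first cross label; its parental role flips between crosses
    sb <- classes == "strain_biased"
    if (any(sb)) {
      fav_is_paternal <- substr(cross, 2, 2) == substr(config$crosses[1L], 2, 2)
      ratio[sb] <- if (fav_is_paternal) config$strain_bias
                   else 1 - config$strain_bias
    }
    paternal <- .rbetabinom(total_n, allelic, ratio, config$concentration)
    maternal <- allelic - paternal
    dc <- classes == "decidua_contaminated"
    if (any(dc) && tissue == epc_tissue) {
      extra <- stats::rpois(sum(dc),
                            config$decidua_rate * blood_rpkm[dc] * allelic[dc])
      maternal[dc] <- maternal[dc] + extra
      total[dc] <- total[dc] + extra
    }
    out[[s]] <- data.frame(
      transcript_id = gene_id, sample_id = samples$sample_id[s],
      cross = cross, tissue = tissue, total_reads = total,
      maternal_reads = maternal, paternal_reads = paternal,
      library_size = config$library_size, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  truth <- data.frame(
    gene_id = gene_id, class = classes, chrom = chrom,
    true_ratio_embryonic = vapply(classes, target, numeric(1),
                                  tissue = config$tissues[1L]),
    true_ratio_extraembryonic = if (length(config$tissues) >= 2L) {
      vapply(classes, target, numeric(1), tissue = config$tissues[2L])
    } else NA_real_,
    blood_rpkm = blood_rpkm, stringsAsFactors = FALSE
  )
  rownames(truth) <- NULL
  blood <- data.frame(gene_id = gene_id, transcript_id = gene_id,
                      rpkm = blood_rpkm, stringsAsFactors = FALSE)
  list(records = records, annotation = annotation, truth = truth,
       blood = blood)
}

.dmr_level <- function(type, track, tissue, cfg) {
  hi <- cfg$meth_hyper; lo <- cfg$meth_hypo
  epc <- cfg$tissues[2L]
  switch(type,
    gametic_maternal = switch(track, oocyte = hi, sperm = lo,
                              maternal = hi, paternal = lo),
    gametic_paternal = switch(track, oocyte = lo, sperm = hi,
                              maternal = lo, paternal = hi),
    somatic_maternal = switch(track, oocyte = lo, sperm = lo,
                              maternal = if (tissue == epc) hi else lo,
                              paternal = lo),
    somatic_paternal = switch(track, oocyte = lo, sperm = lo,
                              maternal = lo,
                              paternal = if (tissue == epc) hi else lo),
    gametes_hypermethylated = switch(track, oocyte = hi, sperm = hi,
                                     maternal = hi, paternal = lo)
  )
}

#' Simulate allele-resolved methylomes with planted DMRs
#'
#' Emits per-CpG methylated/unmethylated counts for oocyte, sperm, and the
#' maternal, paternal and total tracks of each tissue. Background CpGs share
#' one methylation mean across all tracks; planted DMRs override the mean
#' per track according to their origin type (gametic DMRs differ between
#' gametes and are maintained on the matching parental allele in both
#' tissues; somatic DMRs are gametically symmetric and acquire the parental
#' difference only in the restricted tissue).
#'
#' @param config A [sim_config()].
#' @return List with `cpgs` (CpG record table) and `truth` (the planted DMR
#'   table with an `origin` label column).
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pos <- sample.int(config$chrom_len, config$n_cpg)
  # planted DMRs are CpG-island-like: dense CpGs (~25 bp spacing) on top of
  # the sparse genomic background
  if (nrow(config$dmrs) > 0L) {
    for (d in seq_len(nrow(config$dmrs))) {
      pos <- c(pos, seq(config$dmrs$start[d] + 5L, config$dmrs$end[d] - 5L,
                        by = 25L))
    }
  }
  pos <- sort(unique(pos))
  config$n_cpg <- length(pos)
  base_mean <- stats::rbeta(config$n_cpg, 0.8, 0.8)  # bimodal background
  dmrs <- config$dmrs
  dmr_idx <- rep(NA_integer_, config$n_cpg)
  if (nrow(dmrs) > 0L) {
    for (d in seq_len(nrow(dmrs))) {
      dmr_idx[pos >= dmrs$start[d] & pos < dmrs$end[d]] <- d
    }
  }
  kappa <- config$meth_kappa
  tracks <- list(
    list(sample_id = "oocyte", allele = "oocyte", track = "oocyte", tissue = NA),
    list(sample_id = "sperm", allele = "sperm", track = "sperm", tissue = NA)
  )
  for (tis in config$tissues) {
    tracks <- c(tracks,
                list(list(sample_id = tis, allele = "maternal",
                          track = "maternal", tissue = tis),
                     list(list(sample_id = tis, allele = "paternal",
                               track = "paternal", tissue = tis))[[1L]]))
  }
  out <- vector("list", length(tracks) + 2L * length(config$tissues))
  k <- 0L
  per_tissue <- list()
  for (tr in tracks) {
    mean_i <- base_mean
    if (nrow(dmrs) > 0L) {
      inside <- !is.na(dmr_idx)
      if (any(inside)) {
        lv <- vapply(dmr_idx[inside], function(d) {
          .dmr_level(dmrs$type[d], tr$track,
                     if (is.na(tr$tissue)) "" else tr$tissue, config)
        }, numeric(1))
        mean_i[inside] <- lv
      }
    }
    cov <- stats::rpois(config$n_cpg, config$cpg_coverage)
    p <- stats::rbeta(config$n_cpg, mean_i * kappa, (1 - mean_i) * kappa)
    meth <- stats::rbinom(config$n_cpg, cov, p)
    k <- k + 1L
    out[[k]] <- data.frame(chrom = config$chrom, pos = pos,
                           sample_id = tr$sample_id, allele = tr$allele,
                           meth_reads = meth, unmeth_reads = cov - meth,
                           stringsAsFactors = FALSE)
    if (!is.na(tr$tissue)) {
      per_tissue[[paste(tr$tissue, tr$allele)]] <- out[[k]]
    }
  }
  for (tis in config$tissues) {
    m <- per_tissue[[paste(tis, "maternal")]]
    p <- per_tissue[[paste(tis, "paternal")]]
    k <- k + 1L
    out[[k]] <- data.frame(chrom = config$chrom, pos = pos, sample_id = tis,
                           allele = "total",
                           meth_reads = m$meth_reads + p$meth_reads,
                           unmeth_reads = m$unmeth_reads + p$unmeth_reads,
                           stringsAsFactors = FALSE)
  }
  cpgs <- do.call(rbind, out[seq_len(k)])
  cpgs <- cpgs[order(cpgs$chrom, cpgs$pos, cpgs$sample_id, cpgs$allele), ]
  rownames(cpgs) <- NULL
  truth <- dmrs
  truth$chrom <- rep(config$chrom, nrow(truth))
  truth$origin <- truth$type
  list(cpgs = cpgs, truth = truth[c("chrom", "start", "end", "origin",
                                    "tissues")])
}

#' Simulate paired-species oocyte mark tracks over syntenic 1-kb bins
#'
#' Two genomes ("rat" = A, "mouse" = B) are tiled with 1-kb bins paired one
#' to one by a synteny map. H3K27me3 and H3K36me3 levels are drawn from a
#' Gaussian copula with configured correlation and log-normal margins; DNAme
#' shares a per-pair background between species. Planted species-specific
#' H3K27me3 domains raise K27 by >0.5 RPKM in one species with a reciprocal
#' DNAme difference >75 percentage points.
#'
#' @param config A [sim_config()].
#' @return List with `tracks` (nested list `tracks$rat$H3K27me3` etc., each
#'   a bedGraph-style data.frame), `synteny` (paired-bin map) and `truth`
#'   (planted domain table with `genome`, `chrom`, `start`, `end`).
#' @export
simulate_mark_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_bins
  rho <- config$mark_rho
  sig <- config$mark_sigma
  draw_marks <- function() {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    list(k27 = exp(log(0.5) + sig * z1), k36 = exp(log(0.5) + sig * z2))
  }
  a <- draw_marks()
  b <- draw_marks()
  dname_base <- stats::runif(n, 20, 80)
  dname_a <- pmin(100, pmax(0, dname_base + stats::rnorm(n, 0, 3)))
  dname_b <- pmin(100, pmax(0, dname_base + stats::rnorm(n, 0, 3)))

  w <- config$domain_bins
  n_dom <- config$n_domains_a + config$n_domains_b
  slots <- seq(1L, n - w, by = max(w * 4L, 20L))
  if (length(slots) < n_dom) stop("too many planted domains for n_bins",
                                  call. = FALSE)
  starts <- sort(sample(slots, n_dom))
  genome <- sample(rep(c("rat", "mouse"),
                       c(config$n_domains_a, config$n_domains_b)))
  for (d in seq_len(n_dom)) {
    idx <- starts[d]:(starts[d] + w - 1L)
    if (genome[d] == "rat") {
      a$k27[idx] <- a$k27[idx] + 1.5
      dname_a[idx] <- stats::runif(w, 0, 5)
      dname_b[idx] <- stats::runif(w, 90, 100)
    } else {
      b$k27[idx] <- b$k27[idx] + 1.5
      dname_b[idx] <- stats::runif(w, 0, 5)
      dname_a[idx] <- stats::runif(w, 90, 100)
    }
  }
  bin_start <- (seq_len(n) - 1L) * 1000L
  mk <- function(level) data.frame(chrom = "chr1", start = bin_start,
                                   end = bin_start + 1000L, level = level,
                                   stringsAsFactors = FALSE)
  tracks <- list(
    rat = list(H3K27me3 = mk(a$k27), H3K36me3 = mk(a$k36),
               DNAme = mk(dname_a)),
    mouse = list(H3K27me3 = mk(b$k27), H3K36me3 = mk(b$k36),
                 DNAme = mk(dname_b))
  )
  synteny <- data.frame(chrom_a = "chr1", start_a = bin_start,
                        end_a = bin_start + 1000L, chrom_b = "chr1",
                        start_b = bin_start, end_b = bin_start + 1000L,
                        stringsAsFactors = FALSE)
  truth <- data.frame(genome = genome, chrom = rep_len("chr1", n_dom),
                      start = (starts - 1L) * 1000L,
                      end = (starts - 1L + w) * 1000L,
                      stringsAsFactors = FALSE)
  list(tracks = tracks, synteny = synteny, truth = truth)
}
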