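# Linear-model path: per-gene model of allelic log-expression with
# parent-of-origin and strain covariates, empirical-Bayes variance
# moderation, BH adjustment, and a fold-change gate.
#
# Each (gene, sample) contributes two observations, one per allele. With
# reciprocal crosses, the strain identity of a fixed parental allele flips
# between crosses, which is what makes the parent and strain coefficients
# separately identifiable.

#' Build the per-allele design table
#'
#' Expands allelic count records into one observation per (gene, sample,
#' allele) with log2(allelic RPM + pseudocount) as response and parent and
#' strain covariates coded +/-1 (paternal = +1; the first letter of the
#' first cross label is the reference strain, coded +1). Genes are kept
#' only if at least one allele reaches `min_rpm` in at least `min_reps`
#' replicates in both crosses.
#'
#' @param records Allelic count table (see [read_allelic_counts()]).
#' @param pseudocount Added to allelic RPM before log2.
#' @param min_rpm,min_reps Inclusion filter thresholds.
#' @param tissue Optional: restrict to one tissue before building.
#' @return Data.frame with columns `gene_id`, `sample_id`, `allele_parent`,
#'   `allele_strain`, `parent` (+1/-1), `strain` (+1/-1), `log2_expr`.
#'   Attribute `excluded` lists gene ids failing the filter.
#' @export
build_design <- function(records, pseudocount = 0.5, min_rpm = 0.5,
                         min_reps = 2L, tissue = NULL) {
  if (!is.null(tissue)) records <- records[records$tissue == tissue, ]
  if (nrow(records) == 0L) stop("no records to build a design from",
                                call. = FALSE)
  mrpm <- compute_rpm(records$maternal_reads, records$library_size)
  prpm <- compute_rpm(records$paternal_reads, records$library_size)
  informative <- pmax(mrpm, prpm) >= min_rpm
  n_inf <- stats::aggregate(informative,
                            by = list(gene = records$transcript_id,
                                      cross = records$cross), FUN = sum)
  per_gene <- stats::aggregate(n_inf$x >= min_reps,
                               by = list(gene = n_inf$gene), FUN = all)
  n_crosses <- table(n_inf$gene)
  keep_genes <- per_gene$gene[per_gene$x &
                                n_crosses[per_gene$gene] == 2L]
  excluded <- setdiff(unique(records$transcript_id), keep_genes)
  if (length(keep_genes) == 0L) {
    stop("no testable genes: none pass the cross-coverage filter",
         call. = FALSE)
  }
  keep <- records$transcript_id %in% keep_genes
  records <- records[keep, ]
  mrpm <- mrpm[keep]; prpm <- prpm[keep]
  ref_strain <- substr(records$cross[1L], 1L, 1L)
  mk <- function(parent, rpm, strain_letter) {
    data.frame(
      gene_id = records$transcript_id, sample_id = records$sample_id,
      allele_parent = parent, allele_strain = strain_letter,
      parent = if (parent == "paternal") 1 else -1,
      strain = ifelse(strain_letter == ref_strain, 1, -1),
      log2_expr = log2(rpm + pseudocount), stringsAsFactors = FALSE
    )
  }
  obs <- rbind(mk("maternal", mrpm, substr(records$cross, 1L, 1L)),
               mk("paternal", prpm, substr(records$cross, 2L, 2L)))
  obs <- obs[order(obs$gene_id, obs$sample_id, obs$allele_parent), ]
  rownames(obs) <- NULL
  attr(obs, "excluded") <- excluded
  obs
}

#' Fit the parent + strain model for one gene
#'
#' Ordinary least squares of log2 allelic expression on intercept, parent
#' (+1 paternal / -1 maternal) and strain (+1/-1). `beta_parent` is half the
#' fitted paternal-minus-maternal contrast per unit of the +/-1 coding, i.e.
#' the coefficient reported corresponds to log2(paternal) - log2(maternal)
#' when multiplied by 2; we report the full log2 paternal-minus-maternal
#' difference directly.
#'
#' @param obs Design rows of one gene (from [build_design()]).
#' @return List with `beta_parent` (log2 paternal - maternal),
#'   `beta_strain`, `s2` (residual variance), `df` (residual df),
#'   `leverage` (unscaled variance factor of the parent contrast), or
#'   `NULL` when the design is rank deficient (gene not testable).
#' @export
fit_parental_model <- function(obs) {
  X <- cbind(intercept = 1, parent = obs$parent, strain = obs$strain)
  fit <- stats::lm.fit(X, obs$log2_expr)
  if (fit$rank < 3L) return(NULL)
  d <- nrow(X) - fit$rank
  rss <- sum(fit$residuals^2)
  XtXi <- chol2inv(chol(crossprod(X)))
  # contrast: paternal - maternal = 2 * parent coefficient
  list(beta_parent = 2 * unname(fit$coefficients["parent"]),
       beta_strain = 2 * unname(fit$coefficients["strain"]),
       s2 = if (d > 0) rss / d else NA_real_,
       df = d,
       leverage = 4 * XtXi[2L, 2L])
}

.trigamma_inverse <- function(x) {
  # Newton iteration on y -> trigamma(y); monotone decreasing on (0, Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Moderate residual variances across genes
#'
#' Fits a scaled inverse chi-square prior to the gene-wise residual
#' variances by method of moments on log s^2 (matching the classic
#' moderated-t construction): with e = log(s2) - digamma(d/2) + log(d/2),
#' the prior df d0 solves trigamma(d0/2) = var(e) - trigamma(d/2) and
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)). Posterior variances are
#' the df-weighted average (d0 s0^2 + d s2) / (d0 + d).
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar, shared design).
#' @return List with `d0`, `s0_2`, `s2_post` (moderated variances) and
#'   `df_total` = df + d0. When the log-variances show no excess spread
#'   (e.g. all s2 identical) d0 = Inf and every moderated variance equals
#'   s0^2.
#' @export
moderate_variances <- function(s2, df) {
  stopifnot(length(s2) >= 2L, df >= 1)
  s2 <- pmax(s2, 1e-12)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * length(e) / (length(e) - 1L) -
    trigamma(df / 2)
  if (excess <= 0) {
    # no excess spread beyond sampling noise: infinite prior df; the prior
    # variance is the geometric mean, which equals the common value when
    # all s2 are identical
    s0_2 <- exp(mean(log(s2)))
    return(list(d0 = Inf, s0_2 = s0_2, s2_post = rep(s0_2, length(s2)),
                df_total = Inf))
  }
  d0 <- 2 * .trigamma_inverse(excess)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_total = df + d0)
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of p-values.
#' @return Step-up adjusted values, capped at 1.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Fit and moderate the parental model across genes
#'
#' Runs [fit_parental_model()] per gene, shares a scaled inverse chi-square
#' variance prior across genes via [moderate_variances()], and computes
#' moderated t statistics and two-sided p-values for the parent effect.
#'
#' @param obs Design table from [build_design()].
#' @return A `parental_fits` data.frame with one row per testable gene:
#'   `gene_id`, `beta_parent`, `beta_strain`, `s2`, `df`, `t_mod`, `raw_p`,
#'   `adj_p`; attributes `d0` and `s0_2`.
#' @export
fit_parental_models <- function(obs) {
  genes <- split(obs, obs$gene_id)
  fits <- lapply(genes, fit_parental_model)
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (length(fits) == 0L) stop("no testable genes", call. = FALSE)
  beta <- vapply(fits, `[[`, numeric(1), "beta_parent")
  betas <- vapply(fits, `[[`, numeric(1), "beta_strain")
  s2 <- vapply(fits, `[[`, numeric(1), "s2")
  d <- fits[[1L]]$df
  lev <- vapply(fits, `[[`, numeric(1), "leverage")
  mod <- moderate_variances(s2, d)
  t_mod <- beta / sqrt(mod$s2_post * lev)
  dft <- if (is.finite(mod$df_total)) mod$df_total else 1e6
  raw_p <- 2 * stats::pt(-abs(t_mod), df = dft)
  out <- data.frame(gene_id = names(fits), beta_parent = beta,
                    beta_strain = betas, s2 = s2, df = d, t_mod = t_mod,
                    raw_p = raw_p, adj_p = bh_adjust(raw_p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- mod$d0
  attr(out, "s0_2") <- mod$s0_2
  class(out) <- c("parental_fits", "data.frame")
  out
}

#' Call imprinted genes from moderated fits
#'
#' A gene is called imprinted when its BH-adjusted p-value is below `alpha`
#' and the parental log2 difference reaches the fold-change gate
#' (|beta_parent| >= log2(`min_fc`)). Direction follows the sign of the
#' parent effect. These calls are merged with the t-test path downstream as
#' a union, with the `test` field recording the path.
#'
#' @param fits A `parental_fits` data.frame.
#' @param alpha Adjusted p-value cutoff.
#' @param min_fc Minimum allelic fold change.
#' @param tissue Optional tissue label carried into the calls.
#' @return An `imprint_calls` data.frame (`test` = `"linear_model"`).
#' @export
call_imprinted_lm <- function(fits, alpha = 0.05, min_fc = 4, tissue = NULL) {
  sig <- fits$adj_p < alpha & abs(fits$beta_parent) >= log2(min_fc)
  status <- rep("biallelic", nrow(fits))
  status[sig & fits$beta_parent > 0] <- "paternal"
  status[sig & fits$beta_parent < 0] <- "maternal"
  out <- data.frame(
    transcript_id = fits$gene_id,
    tissue = if (!is.null(tissue)) tissue else NA_character_,
    status = status, mean_ratio = NA_real_, raw_p = fits$raw_p,
    adj_p = fits$adj_p, n_valid_samples = NA_integer_,
    test = "linear_model", blood_expressed = FALSE,
    beta_parent = fits$beta_parent, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("imprint_calls", "data.frame")
  out
}
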