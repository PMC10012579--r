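# Shared fixtures: small simulation configs and interval utilities.

small_expr_config <- function(seed = 7, ...) {
  sim_config(seed = seed,
             n_genes = c(biallelic = 60, paternal_imprint = 10,
                         maternal_imprint = 10, strain_biased = 10,
                         decidua_contaminated = 5, chrX = 15),
             ...)
}

small_meth_config <- function(seed = 11, ...) {
  sim_config(seed = seed, n_cpg = 4000, ...)
}

# Jaccard overlap of two interval sets on one chromosome
interval_jaccard <- function(a, b, len = 1e6) {
  cover <- function(df) {
    x <- logical(len)
    for (i in seq_len(nrow(df))) x[(df$start[i] + 1L):df$end[i]] <- TRUE
    x
  }
  ca <- cover(a); cb <- cover(b)
  sum(ca & cb) / sum(ca | cb)
}

# restrict a ratio matrix to one tissue (and optionally a row subset),
# keeping the tissue attribute that plain `[` subsetting drops
tissue_matrix <- function(mat, tissue, rows = NULL) {
  tis <- attr(mat, "tissue")
  if (is.null(rows)) rows <- rownames(mat)
  m <- mat[rows, names(tis)[tis == tissue], drop = FALSE]
  attr(m, "tissue") <- tis[colnames(m)]
  m
}

# truth-aware call accuracy for one class
class_status <- function(calls, truth, cls) {
  ids <- truth$gene_id[truth$class == cls]
  calls$status[match(ids, calls$transcript_id)]
}
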