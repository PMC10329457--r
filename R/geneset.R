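# Gene-set resampling test: is the mean standardized expression of a named
# marker set (e.g. 12 robust auxin-responsive genes) shifted between two
# treatments, relative to equally sized random gene sets drawn from the same
# matrix?

#' Z-score each gene across samples
#'
#' Centers and scales every row to mean 0 and SD 1 across samples. The SD is
#' the sample standard deviation (denominator n - 1, the convention of base
#' R's `scale()`); this only changes results by a constant factor relative to
#' the population convention and never changes permutation p values.
#'
#' @param m an [expression_matrix] or numeric matrix (genes x samples).
#' @return Object of the same type, row-standardized.
#' @export
zscore_rows <- function(m) {
  vals <- if (inherits(m, "expression_matrix")) m$values else m
  if (!is.matrix(vals) || !is.numeric(vals)) {
    abort_arg("expected an expression_matrix or numeric matrix")
  }
  if (ncol(vals) < 2L) abort_arg("need >= 2 samples to z-score")
  sds <- apply(vals, 1L, sd)
  if (any(sds == 0)) {
    abort_arg("zero-variance gene(s): %s",
              paste(rownames(vals)[sds == 0], collapse = ", "))
  }
  out <- (vals - rowMeans(vals)) / sds
  if (inherits(m, "expression_matrix")) {
    expression_matrix(out, m$treatments)
  } else {
    out
  }
}

#' Gene-set resampling test for a between-treatment expression shift
#'
#' The observed statistic is the mean expression of the set genes over the
#' samples of treatment `t1` minus the same mean over `t2`. The null
#' distribution is that statistic for `B` uniformly random gene sets of the
#' same size, drawn without replacement from all genes of the matrix (the
#' target set is not excluded from the pool). The p value uses the standard
#' +1 permutation correction, so its minimum is `1 / (B + 1)`.
#'
#' @param m an [expression_matrix], typically z-scored ([zscore_rows()]).
#' @param set_genes character vector of marker gene ids (must all be rows
#'   of the matrix).
#' @param t1,t2 the two treatment labels being contrasted.
#' @param B number of resamplings (default 10000).
#' @param seed RNG seed (required; the draw of random sets is the only
#'   source of randomness).
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`,
#'   referring to the sign of the observed statistic (t1 minus t2).
#' @return A `geneset_test` list: `observed`, `p`, `B`, `null` (the B null
#'   statistics), `set_genes`, `t1`, `t2`, `alternative`, `seed`.
#' @export
geneset_permutation_test <- function(m, set_genes, t1, t2, B = 10000, seed,
                                     alternative = c("two_sided", "greater",
                                                     "less")) {
  alternative <- match.arg(alternative)
  if (!inherits(m, "expression_matrix")) {
    abort_arg("`m` must be an expression_matrix")
  }
  B <- check_count(B, "B")
  set_genes <- as.character(set_genes)
  missing <- setdiff(set_genes, rownames(m$values))
  if (length(missing)) {
    abort_arg("set gene(s) not in the matrix: %s",
              paste(missing, collapse = ", "))
  }
  for (t in c(t1, t2)) {
    if (!any(m$treatments == t)) abort_arg("treatment '%s' has no samples", t)
  }
  vals <- m$values
  # per-gene difference of treatment means; a set's statistic is its mean
  gdiff <- rowMeans(vals[, m$treatments == t1, drop = FALSE]) -
           rowMeans(vals[, m$treatments == t2, drop = FALSE])
  observed <- mean(gdiff[set_genes])
  s <- length(set_genes)
  n <- length(gdiff)
  null <- with_seed(seed, {
    vapply(seq_len(B), function(b) mean(gdiff[sample.int(n, s)]), numeric(1))
  })
  extreme <- switch(alternative,
    two_sided = sum(abs(null) >= abs(observed)),
    greater   = sum(null >= observed),
    less      = sum(null <= observed)
  )
  structure(
    list(observed = observed, p = (1 + extreme) / (B + 1), B = B, null = null,
         set_genes = set_genes, t1 = t1, t2 = t2, alternative = alternative,
         seed = seed),
    class = "geneset_test"
  )
}

#' @export
print.geneset_test <- function(x, ...) {
  cat(sprintf(paste0("<geneset_test> %d genes, %s vs %s: observed diff ",
                     "%.4g, p = %.4g (%s, B = %d)\n"),
              length(x$set_genes), x$t1, x$t2, x$observed, x$p,
              x$alternative, x$B))
  invisible(x)
}

#' Per-treatment mean expression trajectory of a gene set
#'
#' For each treatment, averages each set gene over that treatment's samples,
#' then reports the mean of those gene-level means with a normal-approximation
#' 95% confidence interval (mean +/- 1.96 standard errors over genes).
#'
#' @param m an [expression_matrix].
#' @param set_genes character vector of gene ids (>= 2, else the CI is
#'   undefined).
#' @param treatments ordered character vector of treatment labels to report.
#' @return data.frame with `treatment`, `mean`, `ci_lo`, `ci_hi`, `n_genes`.
#' @export
set_mean_trajectory <- function(m, set_genes, treatments) {
  if (!inherits(m, "expression_matrix")) {
    abort_arg("`m` must be an expression_matrix")
  }
  set_genes <- as.character(set_genes)
  if (length(set_genes) < 2L) {
    abort_arg("need >= 2 set genes for a confidence interval")
  }
  missing <- setdiff(set_genes, rownames(m$values))
  if (length(missing)) {
    abort_arg("set gene(s) not in the matrix: %s",
              paste(missing, collapse = ", "))
  }
  rows <- lapply(treatments, function(t) {
    cols <- m$treatments == t
    if (!any(cols)) abort_arg("treatment '%s' has no samples", t)
    gmeans <- rowMeans(m$values[set_genes, cols, drop = FALSE])
    se <- sd(gmeans) / sqrt(length(gmeans))
    data.frame(treatment = t, mean = mean(gmeans),
               ci_lo = mean(gmeans) - 1.96 * se,
               ci_hi = mean(gmeans) + 1.96 * se,
               n_genes = length(gmeans), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
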