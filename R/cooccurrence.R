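# Co-occurrence module detection: standardize relative abundances per strain,
# build a Pearson-based dissimilarity, cluster with Ward's criterion (the
# "ward.D2" convention of hclust), cut into k modules and test family
# overrepresentation per module with a hypergeometric test.

#' Standardize an abundance table per strain
#'
#' Divides every abundance by the mean abundance of that strain across all
#' samples, so each retained strain has row mean 1. Strains with all-zero
#' rows cannot be standardized; they are dropped with a warning and returned
#' in the `dropped` attribute.
#'
#' @param table an [abundance_table] or numeric matrix (strains x samples).
#' @return Object of the same type with row means equal to 1; the ids of
#'   dropped all-zero strains are in `attr(, "dropped")`.
#' @export
standardize_abundance <- function(table) {
  m <- as_abundance_matrix(table)
  if (nrow(m) == 0L || ncol(m) == 0L) abort_arg("empty abundance table")
  means <- rowMeans(m)
  zero <- means == 0
  dropped <- rownames(m)[zero]
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero strain(s): %s", sum(zero),
                    paste(dropped, collapse = ", ")))
    m <- m[!zero, , drop = FALSE]
    means <- means[!zero]
    if (nrow(m) == 0L) abort_arg("all strains have zero abundance")
  }
  out <- m / means
  if (inherits(table, "abundance_table")) {
    tax <- table$taxonomy
    if (!is.null(tax) && length(dropped)) {
      tax <- tax[!tax$strain %in% dropped, , drop = FALSE]
    }
    res <- abundance_table(out, sample_data = table$sample_data, taxonomy = tax)
  } else {
    res <- out
  }
  attr(res, "dropped") <- dropped
  res
}

#' Pearson correlation dissimilarity between strains
#'
#' Computes `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of
#' strain abundance profiles across samples, giving values in \[0, 2\].
#' The alternative transform `(1 - r) / 2` is available but not the default.
#'
#' @param table an [abundance_table] or numeric matrix (strains x samples),
#'   normally the output of [standardize_abundance()].
#' @param transform `"one_minus_r"` (default) or `"half_one_minus_r"`.
#' @return A symmetric square matrix with zero diagonal and class
#'   `dissimilarity_matrix`; the transform used is stored as an attribute.
#' @export
correlation_dissimilarity <- function(table,
                                      transform = c("one_minus_r",
                                                    "half_one_minus_r")) {
  transform <- match.arg(transform)
  m <- as_abundance_matrix(table)
  if (ncol(m) < 2L) abort_arg("need at least 2 samples to correlate")
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    abort_arg("zero-variance strain(s): %s (drop or jitter before correlating)",
              paste(rownames(m)[v == 0], collapse = ", "))
  }
  r <- cor(t(m))
  d <- if (transform == "one_minus_r") 1 - r else (1 - r) / 2
  # enforce exact symmetry / zero diagonal against floating-point drift
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "transform") <- transform
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Detect modules of co-occurring strains
#'
#' Agglomerative clustering with Ward's minimum-variance criterion applied to
#' the dissimilarity as if squared-Euclidean-compatible (`hclust` method
#' `"ward.D2"`: merge costs use squared dissimilarities, reported heights are
#' on the dissimilarity scale), cut into `k` modules. Strains are ordered
#' lexicographically before clustering so the result is invariant to input
#' order; module labels are assigned in order of first appearance under that
#' ordering.
#'
#' @param d square dissimilarity matrix (e.g. from
#'   [correlation_dissimilarity()]) or a `dist` object.
#' @param k number of modules to cut (default 4).
#' @return A `module_assignment`: list with `labels` (named integer vector),
#'   `k`, and `tree` (the `hclust` object holding the merge history).
#' @export
detect_modules <- function(d, k = 4) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort_arg("`d` must be a square dissimilarity matrix")
  }
  n <- nrow(d)
  k <- check_count(k, "k")
  if (k > n) abort_arg("k = %d exceeds the number of strains (%d)", k, n)
  ids <- rownames(d) %||% sprintf("strain%03d", seq_len(n))
  ord <- order(ids)
  d <- d[ord, ord, drop = FALSE]
  rownames(d) <- colnames(d) <- ids[ord]
  tree <- hclust(as.dist(d), method = "ward.D2")
  labels <- cutree(tree, k = k)
  structure(list(labels = labels, k = k, tree = tree),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d strains in %d modules: %s\n",
              length(x$labels), x$k,
              paste(sprintf("%d (n=%d)", seq_len(x$k), tabulate(x$labels, x$k)),
                    collapse = ", ")))
  invisible(x)
}

#' Family overrepresentation per module (hypergeometric test)
#'
#' For each module and each taxonomic family present in it, tests whether the
#' family is overrepresented in the module relative to all assigned strains,
#' with the upper-tail hypergeometric probability P(X >= observed).
#' P values are Benjamini-Hochberg adjusted across all tested
#' (module, family) pairs; a row is flagged significant when q < `q_threshold`.
#'
#' @param assignment a `module_assignment` from [detect_modules()].
#' @param taxonomy strain-to-family map: either a named character vector or a
#'   data.frame with `strain` and `family` columns.
#' @param q_threshold FDR significance threshold (default 0.1).
#' @return data.frame with one row per (module, family) pair: counts,
#'   hypergeometric `p`, BH-adjusted `q`, and `significant`.
#' @export
family_enrichment <- function(assignment, taxonomy, q_threshold = 0.1) {
  if (!inherits(assignment, "module_assignment")) {
    abort_arg("`assignment` must come from detect_modules()")
  }
  fam <- taxonomy_to_map(taxonomy)
  strains <- names(assignment$labels)
  missing <- setdiff(strains, names(fam))
  if (length(missing)) {
    abort_arg("strain(s) missing taxonomy: %s", paste(missing, collapse = ", "))
  }
  fam <- fam[strains]
  n_universe <- length(strains)
  fam_universe <- table(fam)
  rows <- list()
  for (mod in sort(unique(assignment$labels))) {
    in_mod <- fam[assignment$labels == mod]
    mod_size <- length(in_mod)
    for (f in sort(unique(in_mod))) {
      x <- sum(in_mod == f)
      K <- as.integer(fam_universe[[f]])
      p <- phyper(x - 1L, K, n_universe - K, mod_size, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, family = f, family_in_module = x, module_size = mod_size,
        family_in_universe = K, universe_size = n_universe, p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < q_threshold
  out[order(out$module, out$p), , drop = FALSE]
}

taxonomy_to_map <- function(taxonomy) {
  if (is.data.frame(taxonomy)) {
    check_cols(taxonomy, c("strain", "family"), "taxonomy")
    setNames(as.character(taxonomy$family), taxonomy$strain)
  } else if (is.character(taxonomy) && !is.null(names(taxonomy))) {
    taxonomy
  } else {
    abort_arg("`taxonomy` must be a named character vector or a data.frame")
  }
}
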