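# Lightweight S3 containers. The matrices stay plain base matrices so that
# vegan/stats-style workflows (cor, hclust, apply) work on them directly.

#' Construct a strain-by-sample abundance table
#'
#' Bundles a non-negative strains x samples matrix with per-sample metadata
#' (fraction, condition, replicate) and per-strain taxonomy. Row names are
#' strain ids, column names sample ids; both must be unique.
#'
#' @param abundance numeric matrix, strains in rows, samples in columns,
#'   all values >= 0, dimnames set.
#' @param sample_data optional data.frame with a `sample` column matching
#'   `colnames(abundance)`; typically carries `fraction` (substrate, root,
#'   shoot), `condition` and `replicate`.
#' @param taxonomy optional data.frame with a `strain` column matching
#'   `rownames(abundance)`; typically carries `family`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(abundance, sample_data = NULL, taxonomy = NULL) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    abort_arg("`abundance` must be a numeric matrix")
  }
  if (nrow(abundance) == 0L || ncol(abundance) == 0L) {
    abort_arg("`abundance` must have at least one strain and one sample")
  }
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    abort_arg("`abundance` needs strain row names and sample column names")
  }
  if (anyDuplicated(rownames(abundance))) abort_arg("duplicate strain ids")
  if (anyDuplicated(colnames(abundance))) abort_arg("duplicate sample ids")
  if (any(abundance < 0)) abort_arg("abundances must be non-negative")
  if (!is.null(sample_data)) {
    check_cols(sample_data, "sample", "sample_data")
    if (!setequal(sample_data$sample, colnames(abundance))) {
      abort_arg("sample_data does not match the sample ids of the matrix")
    }
    sample_data <- sample_data[match(colnames(abundance), sample_data$sample), ,
                               drop = FALSE]
    rownames(sample_data) <- NULL
  }
  if (!is.null(taxonomy)) {
    check_cols(taxonomy, "strain", "taxonomy")
  }
  structure(
    list(abundance = abundance, sample_data = sample_data, taxonomy = taxonomy),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d strains x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$sample_data)) {
    cat("  sample metadata:", paste(setdiff(names(x$sample_data), "sample"),
                                    collapse = ", "), "\n")
  }
  if (!is.null(x$taxonomy)) {
    cat("  taxonomy:", paste(setdiff(names(x$taxonomy), "strain"),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

as_abundance_matrix <- function(x) {
  if (inherits(x, "abundance_table")) x$abundance
  else if (is.matrix(x) && is.numeric(x)) x
  else abort_arg("expected an abundance_table or numeric matrix")
}

#' Construct a genes-by-samples expression matrix with treatment labels
#'
#' @param values numeric matrix (genes x samples) of normalized expression
#'   (e.g. variance-stabilized counts); dimnames required.
#' @param treatments character vector of treatment labels, one per sample,
#'   either named by sample id or in column order.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, treatments) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_arg("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_arg("`values` needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) abort_arg("duplicate gene ids")
  if (anyDuplicated(colnames(values))) abort_arg("duplicate sample ids")
  treatments <- as.character(treatments)
  if (!is.null(names(treatments))) {
    if (!setequal(names(treatments), colnames(values))) {
      abort_arg("treatment names do not match sample ids")
    }
    treatments <- treatments[colnames(values)]
  } else if (length(treatments) != ncol(values)) {
    abort_arg("need one treatment label per sample")
  } else {
    names(treatments) <- colnames(values)
  }
  if (anyNA(treatments)) abort_arg("every sample needs a treatment label")
  structure(list(values = values, treatments = treatments),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples; treatments: %s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$treatments), collapse = ", ")))
  invisible(x)
}

# Validate the long-format phenotype table used by the RGI functions.
validate_phenotype_table <- function(table) {
  check_cols(table, c("treatment", "elongation_cm"), "phenotype table")
  if (!is.numeric(table$elongation_cm)) {
    abort_arg("`elongation_cm` must be numeric")
  }
  if (any(table$elongation_cm < 0, na.rm = TRUE)) {
    abort_arg("root elongation cannot be negative")
  }
  invisible(table)
}

# Validate the long-format survey table used by the prevalence functions.
# `site` doubles as the plant-species column for the per-species rules.
validate_survey_table <- function(table) {
  check_cols(table, c("site", "sample", "asv", "relative_abundance"),
             "survey table")
  ra <- table$relative_abundance
  if (!is.numeric(ra)) abort_arg("`relative_abundance` must be numeric")
  if (any(ra < 0 | ra > 1, na.rm = TRUE)) {
    abort_arg("relative abundances must lie in [0, 1]")
  }
  invisible(table)
}
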