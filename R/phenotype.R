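# Root-growth-inhibition (RGI) phenotyping: classify inducer strains by a
# strict mean-elongation cutoff, test reversion of RGI by co-inoculated
# partner strains (Welch t-test + BH-FDR), standardize elongation to the
# no-bacteria control of each genotype, and summarize IQR bands.

#' Classify RGI-inducing strains
#'
#' Pools all seedlings per mono-association treatment (across plates and
#' experiments) and flags a strain as RGI-inducing when its mean primary-root
#' elongation is strictly below the cutoff.
#'
#' @param table phenotype data.frame with at least `treatment` and
#'   `elongation_cm` columns; one treatment per strain, plus controls.
#' @param cutoff_cm RGI cutoff in cm (default 3.0; strict `<`).
#' @param exclude treatment labels that are not mono-associations (default
#'   `"NB"`, the no-bacteria control).
#' @return data.frame with `strain`, `mean_cm`, `n`, `rgi`, `cutoff_cm`.
#' @export
classify_rgi <- function(table, cutoff_cm = 3.0, exclude = "NB") {
  validate_phenotype_table(table)
  cutoff_cm <- check_number(cutoff_cm, "cutoff_cm", min = 0)
  tab <- table[!table$treatment %in% exclude, , drop = FALSE]
  tab <- tab[!is.na(tab$elongation_cm), , drop = FALSE]
  if (nrow(tab) == 0L) abort_arg("no mono-association measurements left")
  strains <- sort(unique(as.character(tab$treatment)))
  empty <- setdiff(sort(unique(as.character(table$treatment[!table$treatment %in%
                                                            exclude]))), strains)
  if (length(empty)) {
    warning(sprintf("omitting strain(s) with no usable measurements: %s",
                    paste(empty, collapse = ", ")))
  }
  means <- tapply(tab$elongation_cm, tab$treatment, mean)[strains]
  ns <- tapply(tab$elongation_cm, tab$treatment, length)[strains]
  data.frame(strain = strains, mean_cm = as.numeric(means),
             n = as.integer(ns), rgi = as.numeric(means) < cutoff_cm,
             cutoff_cm = cutoff_cm, stringsAsFactors = FALSE, row.names = NULL)
}

#' Test reversion of RGI by partner strains
#'
#' For each partner, compares primary-root elongation of seedlings
#' co-inoculated with the inducer plus the partner (treatment label
#' `"<inducer>+<partner>"`, or as given by `combined_labels`) against the
#' inducer alone, with a Welch two-sample t-test. The default alternative is
#' one-sided (combined > alone) because a reversion claim is directional.
#' P values are BH-adjusted across the partners of the inducer; a partner
#' reverts when `q < alpha_q` and the combined mean is at least the
#' alone mean.
#'
#' @param table phenotype data.frame (`treatment`, `elongation_cm`).
#' @param inducer treatment label of the RGI inducer alone.
#' @param partners character vector of partner strain ids.
#' @param alpha_q FDR threshold for calling reversion (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param combined_labels optional explicit treatment labels for the
#'   combined inoculations, parallel to `partners`.
#' @return data.frame with one row per partner: group means, `n`, `t`, `p`,
#'   `q`, `reverted`.
#' @export
reversion_test <- function(table, inducer, partners, alpha_q = 0.05,
                           alternative = c("greater", "two.sided"),
                           combined_labels = NULL) {
  validate_phenotype_table(table)
  alternative <- match.arg(alternative)
  alpha_q <- check_number(alpha_q, "alpha_q", min = 0)
  combined_labels <- combined_labels %||% paste0(inducer, "+", partners)
  if (length(combined_labels) != length(partners)) {
    abort_arg("`combined_labels` must be parallel to `partners`")
  }
  grab <- function(label) {
    x <- table$elongation_cm[table$treatment == label]
    x <- x[!is.na(x)]
    if (length(x) < 2L) abort_arg("treatment '%s' needs >= 2 measurements", label)
    x
  }
  alone <- grab(inducer)
  rows <- lapply(seq_along(partners), function(i) {
    comb <- grab(combined_labels[i])
    tt <- t.test(comb, alone, alternative = alternative, var.equal = FALSE)
    data.frame(inducer = inducer, partner = partners[i],
               mean_alone = mean(alone), mean_combined = mean(comb),
               n_alone = length(alone), n_combined = length(comb),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$reverted <- out$q < alpha_q & out$mean_combined >= out$mean_alone
  out
}

#' Standardize root elongation to the no-bacteria control
#'
#' Divides every measurement by the mean elongation of the control treatment
#' within its group (genotype by default), so the control group's
#' standardized mean is exactly 1. Idempotent once the control mean is 1.
#'
#' @param table phenotype data.frame; needs the grouping column.
#' @param control_label treatment label of the control (default `"NB"`).
#' @param by name of the grouping column (default `"genotype"`).
#' @return The table with `elongation_cm` replaced by the standardized value
#'   (dimensionless, control mean = 1).
#' @export
standardize_to_control <- function(table, control_label = "NB",
                                   by = "genotype") {
  validate_phenotype_table(table)
  check_cols(table, by, "phenotype table")
  groups <- unique(as.character(table[[by]]))
  ctrl_means <- vapply(groups, function(g) {
    x <- table$elongation_cm[table[[by]] == g & table$treatment == control_label]
    if (length(x) == 0L) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(ctrl_means)) {
    abort_arg("control '%s' missing in group(s): %s", control_label,
              paste(groups[is.na(ctrl_means)], collapse = ", "))
  }
  if (any(ctrl_means == 0)) {
    abort_arg("control mean is zero in group(s): %s",
              paste(groups[ctrl_means == 0], collapse = ", "))
  }
  table$elongation_cm <- table$elongation_cm /
    ctrl_means[as.character(table[[by]])]
  table
}

#' Interquartile range of a treatment group
#'
#' 25th and 75th percentiles of primary-root elongation for one treatment,
#' using the linear-interpolation percentile convention (R quantile type 7).
#' These bands back the shaded IQR ribbons in reversion figures.
#'
#' @param table phenotype data.frame.
#' @param treatment treatment label.
#' @return Named numeric vector `c(q25 = , q75 = )`.
#' @export
group_iqr <- function(table, treatment) {
  validate_phenotype_table(table)
  x <- table$elongation_cm[table$treatment == treatment]
  x <- x[!is.na(x)]
  if (length(x) < 4L) {
    abort_arg("treatment '%s' has %d measurement(s); need >= 4", treatment,
              length(x))
  }
  q <- quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
  c(q25 = q[1], q75 = q[2])
}
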