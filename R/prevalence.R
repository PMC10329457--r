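# Prevalence rules for amplicon surveys: strict thresholds throughout,
# matching the census re-analysis conventions — samples kept when reads
# > 1,000; an ASV present in a sample when RA > 0.01%; widespread when
# present in > 80% of sites; present in a plant species when present in
# > 70% of its samples; core when present in every species.

#' Filter survey samples by read depth
#'
#' Keeps samples with strictly more than `min_reads` reads. A sample with
#' exactly `min_reads` reads is removed.
#'
#' @param table survey data.frame (`site`, `sample`, `asv`,
#'   `relative_abundance`) with a `reads` column (per-sample read count).
#' @param min_reads read-depth threshold (default 1000; strict `>`).
#' @return The filtered survey table.
#' @export
filter_samples <- function(table, min_reads = 1000) {
  validate_survey_table(table)
  if (!"reads" %in% names(table)) {
    abort_arg("read-depth filtering requested but no `reads` column present")
  }
  if (anyNA(table$reads)) abort_arg("`reads` contains missing values")
  table[table$reads > min_reads, , drop = FALSE]
}

#' Per-sample presence calls for ASVs
#'
#' An ASV is present in a sample when its relative abundance is strictly
#' greater than `min_ra` (default 0.0001, i.e. RA > 0.01%; a sample at
#' exactly the threshold is absent).
#'
#' @param table survey data.frame.
#' @param min_ra presence threshold as a fraction (default 1e-4).
#' @return Logical matrix, ASVs x samples. Samples never mentioned for an
#'   ASV are absent.
#' @export
presence_calls <- function(table, min_ra = 0.0001) {
  validate_survey_table(table)
  min_ra <- check_number(min_ra, "min_ra", min = 0)
  asvs <- sort(unique(as.character(table$asv)))
  samples <- sort(unique(as.character(table$sample)))
  pres <- matrix(FALSE, length(asvs), length(samples),
                 dimnames = list(asvs, samples))
  hit <- table$relative_abundance > min_ra
  pres[cbind(match(as.character(table$asv[hit]), asvs),
             match(as.character(table$sample[hit]), samples))] <- TRUE
  pres
}

#' Mean relative abundance over present samples only
#'
#' For each ASV, averages relative abundance across the samples in which the
#' ASV is called present, so prevalence does not dilute the abundance
#' estimate. ASVs present nowhere are omitted.
#'
#' @param table survey data.frame.
#' @param presence logical matrix from [presence_calls()].
#' @return Named numeric vector, mean RA per present ASV.
#' @export
mean_ra_present <- function(table, presence) {
  validate_survey_table(table)
  out <- vapply(rownames(presence), function(a) {
    smp <- colnames(presence)[presence[a, ]]
    if (length(smp) == 0L) return(NA_real_)
    rows <- table$asv == a & table$sample %in% smp
    mean(table$relative_abundance[rows])
  }, numeric(1))
  out[!is.na(out)]
}

# Per-unit (site or species) presence fraction matrix: ASVs x units,
# fraction of the unit's samples in which the ASV is present.
unit_presence_fraction <- function(table, presence) {
  units <- sort(unique(as.character(table$site)))
  sample_unit <- unique(data.frame(sample = as.character(table$sample),
                                   site = as.character(table$site),
                                   stringsAsFactors = FALSE))
  if (anyDuplicated(sample_unit$sample)) {
    abort_arg("sample id(s) appear under more than one site/species: %s",
              paste(sample_unit$sample[duplicated(sample_unit$sample)],
                    collapse = ", "))
  }
  frac <- matrix(NA_real_, nrow(presence), length(units),
                 dimnames = list(rownames(presence), units))
  for (u in units) {
    smp <- sample_unit$sample[sample_unit$site == u]
    smp <- intersect(colnames(presence), smp)
    if (length(smp) == 0L) abort_arg("site/species '%s' has zero samples", u)
    frac[, u] <- rowMeans(presence[, smp, drop = FALSE])
  }
  frac
}

#' Classify widespread ASVs across sites
#'
#' An ASV occupies a site when it is present in at least one of that site's
#' samples (mode `"any_sample"`, the default) or in more than
#' `sample_fraction` of them (mode `"sample_fraction"`). It is widespread
#' when its occupied-site fraction strictly exceeds `site_fraction`
#' (default 0.8, "> 80% of the sites"; 80% exactly is not widespread).
#'
#' @param table survey data.frame (the `site` column defines the sites).
#' @param presence logical matrix from [presence_calls()].
#' @param site_fraction widespread threshold (default 0.8; strict).
#' @param mode site-occupancy rule, see above.
#' @param sample_fraction per-site sample fraction for mode
#'   `"sample_fraction"` (default 0.5; strict).
#' @return Named logical vector over ASVs.
#' @export
classify_widespread <- function(table, presence, site_fraction = 0.8,
                                mode = c("any_sample", "sample_fraction"),
                                sample_fraction = 0.5) {
  mode <- match.arg(mode)
  validate_survey_table(table)
  frac <- unit_presence_fraction(table, presence)
  occupied <- if (mode == "any_sample") frac > 0 else frac > sample_fraction
  rowMeans(occupied) > site_fraction
}

#' Classify core ASVs across plant species
#'
#' An ASV is present in a plant species when it is present in strictly more
#' than `per_species_fraction` of that species' samples (default 0.7,
#' "> 70%"; exactly 70% does not count). It is core when present in every
#' species in the table.
#'
#' @param table survey data.frame (`site` column holds the species labels).
#' @param presence logical matrix from [presence_calls()].
#' @param per_species_fraction per-species presence threshold (default 0.7;
#'   strict).
#' @return Named logical vector over ASVs.
#' @export
classify_core <- function(table, presence, per_species_fraction = 0.7) {
  validate_survey_table(table)
  frac <- unit_presence_fraction(table, presence)
  rowSums(frac > per_species_fraction) == ncol(frac)
}

#' Prevalence summary table
#'
#' One row per ASV: overall prevalence (fraction of sites/species occupied),
#' mean RA among present samples, and the widespread and core calls. This is
#' the table behind prevalence-versus-abundance scatter plots.
#'
#' @inheritParams classify_widespread
#' @param min_ra presence threshold passed to [presence_calls()].
#' @param per_species_fraction threshold passed to [classify_core()].
#' @return data.frame with `asv`, `prevalence`, `mean_ra_present`,
#'   `widespread`, `core`.
#' @export
prevalence_summary <- function(table, min_ra = 0.0001, site_fraction = 0.8,
                               per_species_fraction = 0.7) {
  presence <- presence_calls(table, min_ra = min_ra)
  frac <- unit_presence_fraction(table, presence)
  mra <- mean_ra_present(table, presence)
  asvs <- rownames(presence)
  data.frame(
    asv = asvs,
    prevalence = rowMeans(frac > 0),
    mean_ra_present = unname(mra[asvs]),
    widespread = unname(classify_widespread(table, presence,
                                            site_fraction = site_fraction)),
    core = unname(classify_core(table, presence,
                                per_species_fraction = per_species_fraction)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
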