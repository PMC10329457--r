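# Simulators for every input of the pipeline, each returning the generated
# object together with the recorded ground truth. All are deterministic
# given `seed` and leave the caller's RNG stream untouched.

#' Simulate a strain-by-sample abundance table with planted modules
#'
#' Log-normal latent-factor model: strains are split into `k_modules`
#' blocks; each module m has one latent factor per sample,
#' `f_m(s) ~ N(0, module_sd)`, plus a module-specific plant-enrichment
#' effect added to root and shoot samples. A strain's abundance is
#' `exp(b_i + f_m(s) + e_m * plant(s) + eps)` with strain baseline
#' `b_i ~ N(0, 1)` and noise `eps ~ N(0, noise_sd)`. With `noise_sd = 0`,
#' rows of a module are exactly proportional, so their Pearson correlation
#' is 1. Sample metadata cycles fraction over substrate/root/shoot,
#' condition over two levels, and replicate over 1:3; a taxonomy table
#' assigns families loosely aligned with modules so that family enrichment
#' has signal.
#'
#' @param n_strains,n_samples table dimensions (`n_strains >= k_modules`,
#'   `n_samples >= 2`).
#' @param k_modules number of planted co-occurrence modules (>= 1).
#' @param module_sd SD of the per-sample module latent factor (default 1).
#' @param noise_sd log-scale SD of strain-level noise (default 0.3; >= 0).
#' @param seed RNG seed (required).
#' @return list with `table` (an [abundance_table]) and `truth` (list:
#'   `modules` named strain -> label, `fraction_effect` per module,
#'   `module_sd`, `noise_sd`).
#' @export
simulate_abundance <- function(n_strains, n_samples, k_modules,
                               module_sd = 1, noise_sd = 0.3, seed) {
  n_strains <- check_count(n_strains, "n_strains")
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  k_modules <- check_count(k_modules, "k_modules")
  if (k_modules > n_strains) {
    abort_arg("k_modules (%d) exceeds n_strains (%d)", k_modules, n_strains)
  }
  module_sd <- check_number(module_sd, "module_sd", min = 0, strict = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  with_seed(seed, {
    strains <- sprintf("S%03d", seq_len(n_strains))
    samples <- sprintf("smp%03d", seq_len(n_samples))
    labels <- setNames(sort(rep_len(seq_len(k_modules), n_strains)), strains)
    fraction <- rep_len(c("substrate", "root", "shoot"), n_samples)
    meta <- data.frame(
      sample = samples, fraction = fraction,
      condition = rep_len(c("low", "high"), n_samples),
      replicate = rep_len(1:3, n_samples), stringsAsFactors = FALSE
    )
    latent <- matrix(rnorm(k_modules * n_samples, sd = module_sd),
                     k_modules, n_samples)
    frac_eff <- rnorm(k_modules, sd = 1)       # plant-enrichment per module
    plant <- as.numeric(fraction %in% c("root", "shoot"))
    baseline <- rnorm(n_strains, sd = 1)
    eta <- latent[labels, , drop = FALSE] +
      outer(frac_eff[labels], plant) + baseline
    noise <- matrix(rnorm(n_strains * n_samples, sd = noise_sd),
                    n_strains, n_samples)
    abun <- exp(eta + noise)
    dimnames(abun) <- list(strains, samples)
    # families loosely aligned with modules (70% fidelity)
    fam_pool <- sprintf("family%02d", seq_len(k_modules))
    fam <- ifelse(runif(n_strains) < 0.7, fam_pool[labels],
                  sample(fam_pool, n_strains, replace = TRUE))
    taxonomy <- data.frame(strain = strains, family = fam,
                           stringsAsFactors = FALSE)
    list(
      table = abundance_table(abun, sample_data = meta, taxonomy = taxonomy),
      truth = list(modules = labels, fraction_effect = frac_eff,
                   module_sd = module_sd, noise_sd = noise_sd)
    )
  })
}

#' Simulate a pangenome with a planted clade-specific hotspot
#'
#' Generates `n_background + n_focal` single-scaffold genome annotations and
#' an orthogroup membership table. Housekeeping orthogroups are present in
#' every genome; `hotspot_size` hotspot orthogroups and `decoy_count` decoy
#' orthogroups are carried by all focal genomes and by no background genome
#' (background prevalence 0 < any sensible threshold). On the reference
#' genome (the first focal genome) the hotspot genes are physically
#' contiguous with small inter-gene gaps, while each decoy is separated from
#' every other clade-specific gene by at least `gap_bp + 1` intervening
#' bases, so a correct assembler must reject it. Gene intervals never
#' overlap within a genome.
#'
#' @param n_background,n_focal genome counts (`n_focal >= 1`).
#' @param hotspot_size number of contiguous planted orthogroups (>= 0).
#' @param decoy_count number of isolated clade-specific orthogroups (>= 0).
#' @param gap_bp the assembly gap threshold being emulated (default 10000);
#'   planted intra-hotspot gaps stay far below it, decoy isolation gaps
#'   above it.
#' @param genes_per_genome total genes per genome (housekeeping fills the
#'   remainder; must exceed `hotspot_size + decoy_count`).
#' @param seed RNG seed (required).
#' @return list with `genomes` (named list of gene tables), `orthogroups`
#'   (data.frame `gene_id`, `genome_id`, `orthogroup_id`), `focal`,
#'   `background` (genome id vectors) and `truth` (reference genome,
#'   scaffold, ordered hotspot gene ids, interval, decoy gene ids,
#'   hotspot/decoy orthogroup ids).
#' @export
simulate_pangenome <- function(n_background, n_focal, hotspot_size,
                               decoy_count = 0, gap_bp = 10000,
                               genes_per_genome = 60, seed) {
  n_background <- check_count(n_background, "n_background", min = 0L)
  n_focal <- check_count(n_focal, "n_focal")
  hotspot_size <- check_count(hotspot_size, "hotspot_size", min = 0L)
  decoy_count <- check_count(decoy_count, "decoy_count", min = 0L)
  gap_bp <- check_number(gap_bp, "gap_bp", min = 1)
  genes_per_genome <- check_count(genes_per_genome, "genes_per_genome")
  n_special <- hotspot_size + decoy_count
  if (genes_per_genome <= n_special) {
    abort_arg("genes_per_genome (%d) must exceed hotspot_size + decoy_count (%d)",
              genes_per_genome, n_special)
  }
  with_seed(seed, {
    bg_ids <- if (n_background) sprintf("BG%03d", seq_len(n_background))
              else character(0)
    fc_ids <- sprintf("FC%03d", seq_len(n_focal))
    reference <- fc_ids[1L]
    n_hk <- genes_per_genome - n_special
    hk_ogs <- sprintf("HK%04d", seq_len(n_hk))
    hs_ogs <- if (hotspot_size) sprintf("HS%04d", seq_len(hotspot_size))
              else character(0)
    dc_ogs <- if (decoy_count) sprintf("DC%04d", seq_len(decoy_count))
              else character(0)

    # lay `ogs` along one scaffold; `gaps[i]` = intervening bp before gene i
    layout_genome <- function(genome, ogs, gaps) {
      n <- length(ogs)
      lens <- round(runif(n, 800, 1200))
      start <- numeric(n); end <- numeric(n)
      pos <- 0
      for (i in seq_len(n)) {
        start[i] <- pos + gaps[i] + 1
        end[i] <- start[i] + lens[i] - 1
        pos <- end[i]
      }
      data.frame(
        gene_id = sprintf("%s_g%04d", genome, seq_len(n)),
        genome_id = genome,
        scaffold = paste0("scf_", genome, "_1"),
        start = start, end = end,
        strand = sample(c("+", "-"), n, replace = TRUE),
        orthogroup_id = ogs, stringsAsFactors = FALSE
      )
    }
    # intra-run gaps stay well below the gap threshold
    small_gap <- function(n) round(runif(n, 0.1, 0.4) * min(1000, gap_bp))

    genomes <- list()
    for (g in bg_ids) {
      ogs <- sample(hk_ogs)
      genomes[[g]] <- layout_genome(g, ogs, small_gap(length(ogs)))
    }
    for (g in setdiff(fc_ids, reference)) {
      ogs <- sample(c(hk_ogs, hs_ogs, dc_ogs))
      genomes[[g]] <- layout_genome(g, ogs, small_gap(length(ogs)))
    }
    # reference genome: leading housekeeping, decoys isolated by wide gaps,
    # a wide gap, the contiguous hotspot block, trailing housekeeping.
    hk_split <- split(sample(hk_ogs),
                      rep_len(seq_len(max(1L, min(3L, n_hk))), n_hk))
    lead_hk <- hk_split[[1L]]
    mid_hk <- if (length(hk_split) >= 2L) hk_split[[2L]] else character(0)
    tail_hk <- if (length(hk_split) >= 3L) hk_split[[3L]] else character(0)
    iso <- gap_bp + round(runif(1, 2000, 5000))  # > gap_bp intervening bases
    ref_ogs <- character(0); ref_gaps <- numeric(0)
    add <- function(ogs_new, gap_first) {
      n <- length(ogs_new)
      if (n == 0L) return()
      gaps <- small_gap(n)
      gaps[1L] <- gap_first
      ref_ogs <<- c(ref_ogs, ogs_new)
      ref_gaps <<- c(ref_gaps, gaps)
    }
    add(lead_hk, small_gap(1))
    for (d in dc_ogs) add(d, iso)          # each decoy preceded by a wide gap
    add(mid_hk, if (decoy_count) iso else small_gap(1)) # close the last decoy
    add(hs_ogs, iso)                        # hotspot starts after a wide gap
    add(tail_hk, if (hotspot_size) iso else small_gap(1))
    genomes[[reference]] <- layout_genome(reference, ref_ogs, ref_gaps)

    orthogroups <- do.call(rbind, lapply(genomes, function(g) {
      data.frame(gene_id = g$gene_id, genome_id = g$genome_id,
                 orthogroup_id = g$orthogroup_id, stringsAsFactors = FALSE)
    }))
    rownames(orthogroups) <- NULL
    ref <- genomes[[reference]]
    hs_rows <- ref[match(hs_ogs, ref$orthogroup_id), , drop = FALSE]
    truth <- list(
      reference = reference,
      scaffold = paste0("scf_", reference, "_1"),
      hotspot_genes = hs_rows$gene_id,
      hotspot_orthogroups = hs_ogs,
      interval = if (hotspot_size) c(min(hs_rows$start), max(hs_rows$end))
                 else NULL,
      decoy_genes = ref$gene_id[ref$orthogroup_id %in% dc_ogs],
      decoy_orthogroups = dc_ogs,
      gap_bp = gap_bp
    )
    list(genomes = genomes, orthogroups = orthogroups, focal = fc_ids,
         background = bg_ids, truth = truth)
  })
}

#' Simulate per-seedling root-elongation phenotypes
#'
#' Draws `n_plants` primary-root elongation measurements per treatment from
#' Normal(mean, sd) truncated at 0 (negative draws are set to 0; with
#' realistic means and SDs this is vanishingly rare). Treatments are the
#' supplied strains, optional combined inoculations, and a no-bacteria
#' control `"NB"`. Seedlings are spread over plates of 10 and two
#' experiments, mirroring plate-replicated assays.
#'
#' @param strain_means named numeric vector, mono-association mean
#'   elongation (cm) per strain.
#' @param sd_cm common measurement SD in cm (default 0.5; > 0).
#' @param n_plants seedlings per treatment (>= 2).
#' @param seed RNG seed (required).
#' @param control_mean_cm mean of the no-bacteria control (default 7 cm).
#' @param combined_means optional named numeric vector of additional
#'   treatments, e.g. `c("CL28+CL14" = 6.5)`, for reversion designs.
#' @param rgi_cutoff_cm cutoff recorded in the truth (default 3).
#' @return list with `table` (data.frame: `seedling`, `plate`, `experiment`,
#'   `genotype`, `treatment`, `elongation_cm`) and `truth` (data.frame of
#'   planted means and RGI labels, plus `pairs` for combined treatments).
#' @export
simulate_phenotypes <- function(strain_means, sd_cm = 0.5, n_plants = 20,
                                seed, control_mean_cm = 7,
                                combined_means = NULL, rgi_cutoff_cm = 3) {
  if (!is.numeric(strain_means) || is.null(names(strain_means)) ||
      anyNA(strain_means)) {
    abort_arg("`strain_means` must be a named numeric vector without NAs")
  }
  sd_cm <- check_number(sd_cm, "sd_cm", min = 0, strict = TRUE)
  n_plants <- check_count(n_plants, "n_plants", min = 2L)
  means <- c(strain_means, NB = control_mean_cm, combined_means)
  with_seed(seed, {
    rows <- lapply(names(means), function(trt) {
      x <- rnorm(n_plants, mean = means[[trt]], sd = sd_cm)
      x[x < 0] <- 0
      data.frame(
        seedling = sprintf("%s_sdl%03d", trt, seq_len(n_plants)),
        plate = sprintf("%s_p%02d", trt, (seq_len(n_plants) - 1L) %/% 10L + 1L),
        experiment = rep_len(c("exp1", "exp2"), n_plants),
        genotype = "Col-0", treatment = trt, elongation_cm = x,
        stringsAsFactors = FALSE
      )
    })
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    truth_strains <- data.frame(
      strain = names(strain_means),
      mean_elongation_cm = unname(strain_means),
      sd_cm = sd_cm,
      rgi = unname(strain_means) < rgi_cutoff_cm,
      stringsAsFactors = FALSE
    )
    pairs <- NULL
    if (!is.null(combined_means)) {
      parts <- strsplit(names(combined_means), "+", fixed = TRUE)
      pairs <- data.frame(
        inducer = vapply(parts, `[`, character(1), 1L),
        partner = vapply(parts, function(p) p[min(2L, length(p))], character(1)),
        combined_mean_cm = unname(combined_means),
        stringsAsFactors = FALSE
      )
      pairs$reverted <- pairs$combined_mean_cm >
        unname(strain_means[pairs$inducer])
    }
    list(table = table,
         truth = list(strains = truth_strains, pairs = pairs,
                      rgi_cutoff_cm = rgi_cutoff_cm, sd_cm = sd_cm))
  })
}

#' Simulate an expression matrix with a planted marker-set shift
#'
#' Null genes are iid Normal(0, 1) in every sample; a randomly chosen marker
#' set of `marker_size` genes is shifted by `delta` (z-score units) in the
#' samples of the second treatment.
#'
#' @param n_genes,samples_per_treatment matrix dimensions.
#' @param marker_size size of the planted marker set (default 12;
#'   `<= n_genes`).
#' @param delta planted shift between treatments (treatment 2 minus
#'   treatment 1), in SD units.
#' @param seed RNG seed (required).
#' @param treatments the two treatment labels (default
#'   `c("full", "dropout")`).
#' @return list with `matrix` (an [expression_matrix]) and `truth` (list:
#'   `markers`, `delta`, `treatments`).
#' @export
simulate_expression <- function(n_genes, samples_per_treatment,
                                marker_size = 12, delta = 0, seed,
                                treatments = c("full", "dropout")) {
  n_genes <- check_count(n_genes, "n_genes")
  samples_per_treatment <- check_count(samples_per_treatment,
                                       "samples_per_treatment", min = 2L)
  marker_size <- check_count(marker_size, "marker_size", min = 1L)
  if (marker_size > n_genes) {
    abort_arg("marker_size (%d) exceeds n_genes (%d)", marker_size, n_genes)
  }
  if (length(treatments) != 2L || anyDuplicated(treatments)) {
    abort_arg("need exactly two distinct treatment labels")
  }
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    n_samples <- 2L * samples_per_treatment
    samples <- sprintf("rna%03d", seq_len(n_samples))
    trt <- rep(treatments, each = samples_per_treatment)
    vals <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                   dimnames = list(genes, samples))
    markers <- sort(sample(genes, marker_size))
    vals[markers, trt == treatments[2L]] <-
      vals[markers, trt == treatments[2L]] + delta
    list(
      matrix = expression_matrix(vals, setNames(trt, samples)),
      truth = list(markers = markers, delta = delta, treatments = treatments)
    )
  })
}

#' Simulate a multi-site ASV relative-abundance survey
#'
#' Plants `core_count` core ASVs that are present (RA well above the 0.01%
#' presence threshold) in every sample of every site. Each non-core ASV is
#' guaranteed absent from at least one site (so it can never be called core
#' or fully prevalent) and otherwise occupies sites and samples at the given
#' probabilities, with below-threshold trace abundances sprinkled in to
#' exercise the strict presence rule. The `site` column doubles as the
#' plant-species label for the per-species core rules.
#'
#' @param n_sites,samples_per_site,n_asvs survey dimensions.
#' @param core_count number of planted core ASVs (`<= n_asvs`).
#' @param seed RNG seed (required).
#' @param site_occupancy probability a non-core ASV occupies a given
#'   (non-excluded) site (default 0.6).
#' @param sample_occupancy probability an occupied site's sample carries the
#'   ASV above threshold (default 0.6).
#' @param reads_per_sample nominal read depth written to the `reads` column
#'   (default 5000).
#' @return list with `table` (survey data.frame: `site`, `sample`, `asv`,
#'   `relative_abundance`, `reads`) and `truth` (list: `core`,
#'   `site_occupancy`, `sample_occupancy`).
#' @export
simulate_survey <- function(n_sites, samples_per_site, n_asvs, core_count,
                            seed, site_occupancy = 0.6,
                            sample_occupancy = 0.6,
                            reads_per_sample = 5000) {
  n_sites <- check_count(n_sites, "n_sites")
  samples_per_site <- check_count(samples_per_site, "samples_per_site")
  n_asvs <- check_count(n_asvs, "n_asvs")
  core_count <- check_count(core_count, "core_count", min = 0L)
  if (core_count > n_asvs) {
    abort_arg("core_count (%d) exceeds n_asvs (%d)", core_count, n_asvs)
  }
  with_seed(seed, {
    sites <- sprintf("site%02d", seq_len(n_sites))
    asvs <- sprintf("asv%04d", seq_len(n_asvs))
    core <- if (core_count) asvs[seq_len(core_count)] else character(0)
    detect_ra <- function(n) exp(runif(n, log(5e-4), log(5e-2)))
    rows <- list()
    excluded_site <- setNames(sample(sites, n_asvs, replace = TRUE), asvs)
    for (si in seq_along(sites)) {
      site <- sites[si]
      occupied <- setNames(runif(n_asvs) < site_occupancy, asvs)
      for (sj in seq_len(samples_per_site)) {
        smp <- sprintf("%s_smp%02d", site, sj)
        ra <- numeric(n_asvs)
        ra[asvs %in% core] <- detect_ra(core_count)
        noncore <- !(asvs %in% core)
        hit <- noncore & occupied & site != excluded_site &
          runif(n_asvs) < sample_occupancy
        ra[hit] <- detect_ra(sum(hit))
        # occasional sub-threshold traces among the misses
        trace <- noncore & !hit & runif(n_asvs) < 0.1 &
          site != excluded_site
        ra[trace] <- runif(sum(trace), 0, 1e-4)
        keep <- ra > 0
        if (any(keep)) {
          rows[[length(rows) + 1L]] <- data.frame(
            site = site, sample = smp, asv = asvs[keep],
            relative_abundance = ra[keep], reads = reads_per_sample,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    list(table = table,
         truth = list(core = core, site_occupancy = site_occupancy,
                      sample_occupancy = sample_occupancy,
                      excluded_site = excluded_site))
  })
}
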