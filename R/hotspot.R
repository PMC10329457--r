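# Clade-specific genomic hotspot discovery. An orthogroup is clade-specific
# when it is present in every focal genome and in strictly fewer than
# max_bg_prev * n_background background genomes. On a chosen reference genome
# the genes of selected orthogroups are assembled, per scaffold, into maximal
# runs whose intervening gaps are below a bp threshold; runs with enough
# members are reported as hotspots.

# Gene tables are plain data.frames with columns
#   gene_id, genome_id, scaffold, start, end, strand [, orthogroup_id]
# (1-based inclusive coordinates, as in GFF3).

validate_gene_table <- function(genes) {
  check_cols(genes, c("gene_id", "genome_id", "scaffold", "start", "end",
                      "strand"), "gene table")
  if (!is.numeric(genes$start) || !is.numeric(genes$end)) {
    abort_arg("gene coordinates must be numeric")
  }
  bad <- genes$start < 1 | genes$start > genes$end
  if (any(bad)) {
    abort_arg("invalid coordinates (need 1 <= start <= end) for gene(s): %s",
              paste(genes$gene_id[bad], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort_arg("strand must be '+' or '-'")
  }
  invisible(genes)
}

#' Select clade-specific orthogroups
#'
#' Keeps orthogroups present in 100% of focal-clade genomes (clade core) and
#' in strictly fewer than `max_bg_prev * length(background)` background
#' genomes. Prevalence counts genomes carrying at least one member gene, not
#' gene copies.
#'
#' @param orthogroups data.frame with `gene_id`, `genome_id`,
#'   `orthogroup_id` columns (one row per gene).
#' @param focal,background disjoint character vectors of genome ids; genomes
#'   without any row in `orthogroups` still count towards prevalence
#'   denominators.
#' @param max_bg_prev maximum background prevalence, as a fraction
#'   (default 0.05, i.e. "< 5%"; the inequality is strict).
#' @return A `clade_selection`: list with `selected` (orthogroup ids),
#'   `prevalence` (per-orthogroup focal/background fractions), `focal`,
#'   `background`, `max_bg_prev`.
#' @export
select_clade_specific <- function(orthogroups, focal, background,
                                  max_bg_prev = 0.05) {
  check_cols(orthogroups, c("gene_id", "genome_id", "orthogroup_id"),
             "orthogroup table")
  focal <- unique(as.character(focal))
  background <- unique(as.character(background))
  if (length(focal) == 0L) abort_arg("focal clade must be non-empty")
  if (length(intersect(focal, background))) {
    abort_arg("focal and background genome sets overlap: %s",
              paste(intersect(focal, background), collapse = ", "))
  }
  max_bg_prev <- check_number(max_bg_prev, "max_bg_prev", min = 0)
  og <- unique(orthogroups[, c("genome_id", "orthogroup_id")])
  ogs <- sort(unique(og$orthogroup_id))
  focal_n <- vapply(ogs, function(o) {
    sum(og$genome_id[og$orthogroup_id == o] %in% focal)
  }, integer(1))
  bg_n <- vapply(ogs, function(o) {
    sum(og$genome_id[og$orthogroup_id == o] %in% background)
  }, integer(1))
  prevalence <- data.frame(
    orthogroup_id = ogs,
    focal_prevalence = if (length(focal)) focal_n / length(focal) else NA_real_,
    background_prevalence = if (length(background)) bg_n / length(background)
                            else 0,
    stringsAsFactors = FALSE
  )
  selected <- ogs[focal_n == length(focal) & bg_n < max_bg_prev * length(background)]
  structure(
    list(selected = selected, prevalence = prevalence, focal = focal,
         background = background, max_bg_prev = max_bg_prev),
    class = "clade_selection"
  )
}

#' @export
print.clade_selection <- function(x, ...) {
  cat(sprintf(paste0("<clade_selection> %d orthogroup(s) core in %d focal ",
                     "genome(s) and < %.1f%% prevalent in %d background ",
                     "genome(s)\n"),
              length(x$selected), length(x$focal), 100 * x$max_bg_prev,
              length(x$background)))
  invisible(x)
}

#' Assemble clade-specific hotspots on a reference genome
#'
#' Restricts the reference genome's genes to those in selected orthogroups,
#' sorts them by start per scaffold and greedily extends a run while the gap
#' to the next selected gene — intervening bases,
#' `next start - running max end - 1` — is strictly below `gap_bp`.
#' Overlapping genes (negative gap) always merge. Runs whose size passes the
#' filter are reported as hotspots, numbered in genome order.
#'
#' @param genes gene table of the reference genome (single `genome_id`),
#'   with an `orthogroup_id` column or joined through `selection`'s table.
#' @param selection a `clade_selection` from [select_clade_specific()], or a
#'   character vector of selected orthogroup ids.
#' @param gap_bp maximum intervening distance within a run (default 10000,
#'   "less than 10 kb"; strict).
#' @param min_genes minimum size of a reported hotspot (default 10,
#'   inclusive: a run of exactly 10 passes; set `strict = TRUE` for "> 10").
#' @param count_by whether the size filter counts distinct `"orthogroups"`
#'   (default; paralogs collapse) or member `"genes"`.
#' @param strict if `TRUE` the size filter is `> min_genes` instead of `>=`.
#' @return A `hotspot_set`: list of hotspots, each with `hotspot_id`,
#'   `scaffold`, `start`, `end`, `genes` (ordered gene table),
#'   `orthogroup_ids`, `n_genes`, `n_orthogroups`.
#' @export
assemble_hotspots <- function(genes, selection, gap_bp = 10000, min_genes = 10,
                              count_by = c("orthogroups", "genes"),
                              strict = FALSE) {
  count_by <- match.arg(count_by)
  validate_gene_table(genes)
  gap_bp <- check_number(gap_bp, "gap_bp", min = 0)
  min_genes <- check_count(min_genes, "min_genes", min = 0L)
  if (length(unique(genes$genome_id)) > 1L) {
    abort_arg("gene table mixes genomes (%s); pass one reference genome",
              paste(unique(genes$genome_id), collapse = ", "))
  }
  selected <- if (inherits(selection, "clade_selection")) selection$selected
              else as.character(selection)
  if (!"orthogroup_id" %in% names(genes)) {
    abort_arg("gene table needs an `orthogroup_id` column")
  }
  sel_genes <- genes[!is.na(genes$orthogroup_id) &
                     genes$orthogroup_id %in% selected, , drop = FALSE]
  runs <- list()
  for (scf in sort(unique(sel_genes$scaffold))) {
    g <- sel_genes[sel_genes$scaffold == scf, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    run_start <- 1L
    run_end_bp <- g$end[1L]
    for (i in seq_len(nrow(g))[-1L]) {
      gap <- g$start[i] - run_end_bp - 1
      if (gap < gap_bp) {
        run_end_bp <- max(run_end_bp, g$end[i])
      } else {
        runs[[length(runs) + 1L]] <- g[run_start:(i - 1L), , drop = FALSE]
        run_start <- i
        run_end_bp <- g$end[i]
      }
    }
    if (nrow(g)) runs[[length(runs) + 1L]] <- g[run_start:nrow(g), , drop = FALSE]
  }
  # genome order: scaffold, then position
  if (length(runs)) {
    ord <- order(vapply(runs, function(r) r$scaffold[1L], character(1)),
                 vapply(runs, function(r) min(r$start), numeric(1)))
    runs <- runs[ord]
  }
  hotspots <- list()
  for (r in runs) {
    size <- if (count_by == "orthogroups") length(unique(r$orthogroup_id))
            else nrow(r)
    keep <- if (strict) size > min_genes else size >= min_genes
    if (!keep) next
    hotspots[[length(hotspots) + 1L]] <- list(
      hotspot_id = sprintf("hotspot_%02d", length(hotspots) + 1L),
      scaffold = r$scaffold[1L],
      start = min(r$start), end = max(r$end),
      genes = r,
      orthogroup_ids = unique(r$orthogroup_id),
      n_genes = nrow(r),
      n_orthogroups = length(unique(r$orthogroup_id))
    )
  }
  structure(list(hotspots = hotspots, gap_bp = gap_bp, min_genes = min_genes,
                 count_by = count_by, strict = strict),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %d hotspot(s) (gap < %g bp, size filter %s %d %s)\n",
              length(x$hotspots), x$gap_bp, if (x$strict) ">" else ">=",
              x$min_genes, x$count_by))
  for (h in x$hotspots) {
    cat(sprintf("  %s %s:%d-%d  %d genes / %d orthogroups\n", h$hotspot_id,
                h$scaffold, h$start, h$end, h$n_genes, h$n_orthogroups))
  }
  invisible(x)
}

#' Interval length in kilobases
#'
#' Length of a 1-based inclusive interval, `end - start + 1` bp, rounded to
#' the nearest integer kb (R's round-half-to-even).
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return Integer-valued length in kb.
#' @export
interval_length_kb <- function(start, end) {
  if (any(start < 1) || any(start > end)) {
    abort_arg("need 1 <= start <= end")
  }
  round((end - start + 1) / 1000)
}

#' Intersect two 1-based inclusive genomic intervals
#'
#' Returns `c(max(starts), min(ends))`, or `NULL` when the intervals are
#' disjoint. If scaffold ids are supplied and differ, the intersection is
#' empty with a warning.
#'
#' @param a,b numeric length-2 vectors `(start, end)`.
#' @param scaffold_a,scaffold_b optional scaffold ids.
#' @return Numeric length-2 vector or `NULL`.
#' @export
interval_intersect <- function(a, b, scaffold_a = NULL, scaffold_b = NULL) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (a[1] > a[2] || b[1] > b[2]) abort_arg("intervals need start <= end")
  if (!is.null(scaffold_a) && !is.null(scaffold_b) &&
      !identical(scaffold_a, scaffold_b)) {
    warning("intervals lie on different scaffolds; intersection is empty")
    return(NULL)
  }
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (lo > hi) NULL else c(lo, hi)
}

#' Genes fully contained in an interval
#'
#' Companion to [interval_intersect()]: lists the gene records whose spans
#' lie entirely within `[start, end]` on `scaffold`.
#'
#' @param genes gene table (see [assemble_hotspots()]).
#' @param scaffold scaffold id.
#' @param start,end 1-based inclusive interval bounds.
#' @return Subset of `genes`, sorted by start.
#' @export
genes_in_interval <- function(genes, scaffold, start, end) {
  validate_gene_table(genes)
  if (start > end) abort_arg("need start <= end")
  g <- genes[genes$scaffold == scaffold & genes$start >= start &
             genes$end <= end, , drop = FALSE]
  g[order(g$start), , drop = FALSE]
}

#' Tabulate hotspots and their per-genome presence
#'
#' Produces a per-hotspot summary table and a genome x hotspot matrix of
#' presence fractions (share of the hotspot's orthogroups each genome
#' carries), plus the binarized presence/absence matrix (>= 1 orthogroup).
#'
#' @param hotspots a `hotspot_set` from [assemble_hotspots()].
#' @param orthogroups the full orthogroup membership table.
#' @param selection the `clade_selection` used for assembly (provides the
#'   genome universe).
#' @return list with `summary` (data.frame), `presence_fraction` and
#'   `presence` (matrices, genomes x hotspots).
#' @export
hotspot_report <- function(hotspots, orthogroups, selection) {
  if (!inherits(hotspots, "hotspot_set")) {
    abort_arg("`hotspots` must come from assemble_hotspots()")
  }
  genomes <- sort(c(selection$focal, selection$background))
  hs <- hotspots$hotspots
  summary <- data.frame(
    hotspot_id = vapply(hs, `[[`, character(1), "hotspot_id"),
    scaffold = vapply(hs, `[[`, character(1), "scaffold"),
    start = vapply(hs, `[[`, numeric(1), "start"),
    end = vapply(hs, `[[`, numeric(1), "end"),
    length_kb = vapply(hs, function(h) interval_length_kb(h$start, h$end),
                       numeric(1)),
    n_genes = vapply(hs, `[[`, integer(1), "n_genes"),
    n_orthogroups = vapply(hs, `[[`, integer(1), "n_orthogroups"),
    orthogroup_ids = vapply(hs, function(h) paste(h$orthogroup_ids,
                                                  collapse = ","),
                            character(1)),
    stringsAsFactors = FALSE
  )
  og <- unique(orthogroups[, c("genome_id", "orthogroup_id")])
  frac <- matrix(0, nrow = length(genomes), ncol = length(hs),
                 dimnames = list(genomes,
                                 vapply(hs, `[[`, character(1), "hotspot_id")))
  for (j in seq_along(hs)) {
    ogs <- hs[[j]]$orthogroup_ids
    carried <- table(factor(og$genome_id[og$orthogroup_id %in% ogs],
                            levels = genomes))
    frac[, j] <- as.numeric(carried) / length(ogs)
  }
  list(summary = summary, presence_fraction = frac, presence = frac > 0)
}
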