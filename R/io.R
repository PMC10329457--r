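# Readers and writers for the plain-text formats the pipeline touches:
# tab-separated tables with typed validation, GFF3 gene tables (1-based
# inclusive), BED exports (0-based half-open), Newick dendrograms and JSON
# truth/provenance records. The GFF3 handling is deliberately a thin,
# line-number-aware reader restricted to `gene` features: validation errors
# must cite the offending line, which the generic importers do not do.

#' Write a data.frame as TSV
#'
#' Plain UTF-8, tab-separated, header row, no quoting, no row names —
#' byte-stable given identical input.
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV with typed validation
#'
#' Reads a tab-separated file with a header row, checks that all
#' `required_cols` exist, and converts `numeric_cols` with an error naming
#' the first offending row and column (a literal `"NA"` in a numeric column
#' is an error, not a silent missing value).
#'
#' @param path input file.
#' @param required_cols columns that must be present.
#' @param numeric_cols columns converted to numeric with validation.
#' @return data.frame (character columns except `numeric_cols`).
#' @export
read_tsv_checked <- function(path, required_cols = character(0),
                             numeric_cols = character(0)) {
  if (!file.exists(path)) abort_arg("file not found: %s", path)
  if (file.size(path) == 0L) abort_arg("empty file: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) abort_arg("no data rows in %s", path)
  check_cols(df, required_cols, path)
  for (col in intersect(numeric_cols, names(df))) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num))
    if (length(bad)) {
      abort_arg("%s: column '%s' is not numeric at data row %d (value '%s')",
                path, col, bad[1L], df[[col]][bad[1L]])
    }
    df[[col]] <- num
  }
  df
}

#' Read gene records from a GFF3 file
#'
#' Parses `gene` features (1-based inclusive coordinates preserved), taking
#' the gene id from the `ID` attribute. Malformed lines — wrong field count,
#' non-numeric or inverted coordinates, missing `ID` — raise an error citing
#' the line number. Records are returned sorted by (scaffold, start).
#'
#' @param path GFF3 file.
#' @param genome_id genome id to record (default: file name without
#'   extension).
#' @return Gene table data.frame (`gene_id`, `genome_id`, `scaffold`,
#'   `start`, `end`, `strand`, `orthogroup_id` when an `orthogroup`
#'   attribute is present).
#' @export
read_gff3 <- function(path, genome_id = NULL) {
  if (!file.exists(path)) abort_arg("file not found: %s", path)
  genome_id <- genome_id %||% sub("\\.gff3?$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  rows <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      abort_arg("%s line %d: expected 9 tab-separated fields, got %d",
                path, i, length(fields))
    }
    if (fields[3L] != "gene") next
    start <- suppressWarnings(as.numeric(fields[4L]))
    end <- suppressWarnings(as.numeric(fields[5L]))
    if (is.na(start) || is.na(end)) {
      abort_arg("%s line %d: non-numeric coordinates", path, i)
    }
    if (start < 1 || start > end) {
      abort_arg("%s line %d: invalid interval %s-%s", path, i,
                fields[4L], fields[5L])
    }
    if (!fields[7L] %in% c("+", "-")) {
      abort_arg("%s line %d: strand must be + or -", path, i)
    }
    attrs <- parse_gff_attributes(fields[9L])
    if (is.null(attrs[["ID"]])) {
      abort_arg("%s line %d: missing ID attribute", path, i)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = attrs[["ID"]], genome_id = genome_id, scaffold = fields[1L],
      start = start, end = end, strand = fields[7L],
      orthogroup_id = attrs[["orthogroup"]] %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) abort_arg("%s: no gene features found", path)
  out <- do.call(rbind, rows)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_gff_attributes <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  setNames(
    lapply(kv, function(p) if (length(p) >= 2L) p[2L] else NA_character_),
    vapply(kv, `[`, character(1), 1L)
  )
}

#' Write gene records as GFF3
#'
#' Emits `gene` features with 1-based inclusive coordinates and `ID` (plus
#' `orthogroup` when known) attributes; round-trips with [read_gff3()].
#'
#' @param genes gene table (see [assemble_hotspots()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  validate_gene_table(genes)
  attrs <- sprintf("ID=%s", genes$gene_id)
  has_og <- "orthogroup_id" %in% names(genes) & !is.na(genes$orthogroup_id)
  attrs[has_og] <- sprintf("ID=%s;orthogroup=%s", genes$gene_id[has_og],
                           genes$orthogroup_id[has_og])
  lines <- sprintf("%s\tsyncomr\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$scaffold, as.integer(genes$start),
                   as.integer(genes$end), genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Export hotspot intervals as BED
#'
#' Converts the 1-based inclusive hotspot intervals to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param hotspots a `hotspot_set`.
#' @return data.frame with `chrom`, `start`, `end`, `name` (BED columns).
#' @export
hotspots_to_bed <- function(hotspots) {
  if (!inherits(hotspots, "hotspot_set")) {
    abort_arg("`hotspots` must come from assemble_hotspots()")
  }
  hs <- hotspots$hotspots
  data.frame(
    chrom = vapply(hs, `[[`, character(1), "scaffold"),
    start = vapply(hs, function(h) h$start - 1, numeric(1)),
    end = vapply(hs, `[[`, numeric(1), "end"),
    name = vapply(hs, `[[`, character(1), "hotspot_id"),
    stringsAsFactors = FALSE
  )
}

#' Convert BED intervals back to 1-based inclusive coordinates
#'
#' @param bed data.frame with `chrom`, `start`, `end` in BED convention.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
bed_to_intervals <- function(bed) {
  check_cols(bed, c("chrom", "start", "end"), "BED table")
  data.frame(scaffold = bed$chrom, start = bed$start + 1, end = bed$end,
             stringsAsFactors = FALSE)
}

#' Export a module dendrogram as Newick
#'
#' Writes the clustering tree of a module assignment with merge heights as
#' branch lengths, via [ape::as.phylo()].
#'
#' @param assignment a `module_assignment` from [detect_modules()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(assignment, path) {
  if (!inherits(assignment, "module_assignment")) {
    abort_arg("`assignment` must come from detect_modules()")
  }
  phy <- ape::as.phylo(assignment$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Write an abundance table (matrix + metadata + taxonomy) as TSVs
#'
#' @param table an [abundance_table].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"abundance"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_abundance <- function(table, dir, prefix = "abundance") {
  if (!inherits(table, "abundance_table")) {
    abort_arg("`table` must be an abundance_table")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, ".tsv")))
  m <- data.frame(strain = rownames(table$abundance), table$abundance,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(m, paths[["matrix"]])
  if (!is.null(table$sample_data)) {
    paths[["samples"]] <- file.path(dir, paste0(prefix, "_samples.tsv"))
    write_tsv(table$sample_data, paths[["samples"]])
  }
  if (!is.null(table$taxonomy)) {
    paths[["taxonomy"]] <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
    write_tsv(table$taxonomy, paths[["taxonomy"]])
  }
  invisible(paths)
}

#' Read an abundance table written by [write_abundance()]
#'
#' @param matrix_path abundance TSV (first column `strain`).
#' @param samples_path,taxonomy_path optional metadata TSVs.
#' @return An [abundance_table].
#' @export
read_abundance <- function(matrix_path, samples_path = NULL,
                           taxonomy_path = NULL) {
  df <- read_tsv_checked(matrix_path, required_cols = "strain")
  strains <- df$strain
  if (anyDuplicated(strains)) abort_arg("%s: duplicate strain ids", matrix_path)
  m <- as.matrix(df[, setdiff(names(df), "strain"), drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) abort_arg("%s: non-numeric abundance values", matrix_path)
  rownames(m) <- strains
  samples <- if (!is.null(samples_path)) {
    read_tsv_checked(samples_path, required_cols = "sample")
  }
  taxonomy <- if (!is.null(taxonomy_path)) {
    read_tsv_checked(taxonomy_path, required_cols = "strain")
  }
  abundance_table(m, sample_data = samples, taxonomy = taxonomy)
}

#' Read a phenotype table TSV
#'
#' @param path TSV with at least `treatment` and `elongation_cm` columns.
#' @return Validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path, required_cols = c("treatment", "elongation_cm"),
                         numeric_cols = "elongation_cm")
  validate_phenotype_table(df)
  df
}

#' Read a survey table TSV
#'
#' @param path TSV with `site`, `sample`, `asv`, `relative_abundance`
#'   (optionally `reads`) columns.
#' @return Validated survey data.frame.
#' @export
read_survey <- function(path) {
  df <- read_tsv_checked(
    path,
    required_cols = c("site", "sample", "asv", "relative_abundance"),
    numeric_cols = c("relative_abundance", "reads")
  )
  validate_survey_table(df)
  df
}

#' Read an expression matrix plus treatment labels
#'
#' @param matrix_path genes x samples TSV, first column `gene`.
#' @param treatments_path TSV with `sample` and `treatment` columns.
#' @return An [expression_matrix].
#' @export
read_expression <- function(matrix_path, treatments_path) {
  df <- read_tsv_checked(matrix_path, required_cols = "gene")
  genes <- df$gene
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) abort_arg("%s: non-numeric expression values", matrix_path)
  rownames(m) <- genes
  trt <- read_tsv_checked(treatments_path,
                          required_cols = c("sample", "treatment"))
  expression_matrix(m, setNames(trt$treatment, trt$sample))
}

#' Write an expression matrix and its treatment labels as TSVs
#'
#' @param m an [expression_matrix].
#' @param dir output directory.
#' @param prefix file-name prefix (default `"expression"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_expression <- function(m, dir, prefix = "expression") {
  if (!inherits(m, "expression_matrix")) {
    abort_arg("`m` must be an expression_matrix")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, paste0(prefix, ".tsv")),
             treatments = file.path(dir, paste0(prefix, "_treatments.tsv")))
  write_tsv(data.frame(gene = rownames(m$values), m$values,
                       check.names = FALSE, stringsAsFactors = FALSE),
            paths[["matrix"]])
  write_tsv(data.frame(sample = names(m$treatments),
                       treatment = unname(m$treatments),
                       stringsAsFactors = FALSE),
            paths[["treatments"]])
  invisible(paths)
}
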