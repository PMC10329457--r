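# Helper: gene table on one scaffold from (start, end) pairs.
gene_tab <- function(coords, og = NULL, genome = "G1", scaffold = "scf1") {
  n <- nrow(coords)
  data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), genome_id = genome,
    scaffold = scaffold, start = coords[, 1], end = coords[, 2],
    strand = "+", orthogroup_id = og %||% sprintf("OG%02d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("select_clade_specific enforces core and strict background rules", {
  # 10 focal, 175 background; OG_a in all focal & 8 bg (4.57% -> in),
  # OG_b in all focal & 9 bg (5.14% -> out), OG_c in 9/10 focal (out).
  focal <- sprintf("F%02d", 1:10)
  bg <- sprintf("B%03d", 1:175)
  mk <- function(og, genomes) data.frame(
    gene_id = paste0(og, "_", genomes), genome_id = genomes,
    orthogroup_id = og, stringsAsFactors = FALSE
  )
  og <- rbind(mk("OG_a", c(focal, bg[1:8])),
              mk("OG_b", c(focal, bg[1:9])),
              mk("OG_c", c(focal[1:9])))
  sel <- select_clade_specific(og, focal, bg, max_bg_prev = 0.05)
  expect_identical(sel$selected, "OG_a")
  prev <- sel$prevalence
  expect_equal(prev$background_prevalence[prev$orthogroup_id == "OG_a"], 8 / 175)
  expect_equal(prev$focal_prevalence[prev$orthogroup_id == "OG_c"], 0.9)
  # monotone in max_bg_prev: selections nest
  sel2 <- select_clade_specific(og, focal, bg, max_bg_prev = 0.06)
  expect_true(all(sel$selected %in% sel2$selected))
  expect_setequal(sel2$selected, c("OG_a", "OG_b"))
  expect_error(select_clade_specific(og, focal, c(bg, focal[1])),
               class = "syncomr_arg_error")
})

test_that("assemble_hotspots honors the strict intervening-gap boundary", {
  # gene 1 ends at 1000; 9,999 intervening bases -> next starts at 11000
  one <- gene_tab(rbind(c(1, 1000), c(11000, 12000)))
  hs <- assemble_hotspots(one, c("OG01", "OG02"), gap_bp = 10000, min_genes = 1)
  expect_length(hs$hotspots, 1L)
  expect_equal(hs$hotspots[[1]]$n_genes, 2L)
  # exactly 10,000 intervening bases -> two runs
  two <- gene_tab(rbind(c(1, 1000), c(11001, 12000)))
  hs2 <- assemble_hotspots(two, c("OG01", "OG02"), gap_bp = 10000, min_genes = 1)
  expect_length(hs2$hotspots, 2L)
  # run of 9 below min_genes = 10 is not reported
  nine <- gene_tab(cbind(seq(1, by = 2000, length.out = 9),
                         seq(1000, by = 2000, length.out = 9)))
  expect_length(assemble_hotspots(nine, nine$orthogroup_id,
                                  min_genes = 10)$hotspots, 0L)
  expect_length(assemble_hotspots(nine, nine$orthogroup_id,
                                  min_genes = 9)$hotspots, 1L)
  # overlapping genes always merge (negative gap)
  ovl <- gene_tab(rbind(c(1, 5000), c(4000, 6000)))
  expect_length(assemble_hotspots(ovl, ovl$orthogroup_id,
                                  min_genes = 1)$hotspots, 1L)
  expect_error(assemble_hotspots(rbind(one, gene_tab(rbind(c(1, 10)),
                                                     genome = "G2")),
                                 "OG01"), class = "syncomr_arg_error")
})

test_that("assembly equals the brute-force component oracle and is order-invariant", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    gaps <- sample(c(50, 500, 5000, 9999, 10000, 20000), n, replace = TRUE)
    lens <- sample(500:1500, n, replace = TRUE)
    starts <- cumsum(gaps + c(0, lens[-n]))
    coords <- cbind(starts + 1, starts + lens)
    g <- gene_tab(coords)
    hs <- assemble_hotspots(g, g$orthogroup_id, gap_bp = 10000, min_genes = 1)
    got <- lapply(hs$hotspots, function(h) h$genes$gene_id)
    oracle <- oracle_hotspot_components(g, gap_bp = 10000)[["scf1"]]
    expect_equal(length(got), length(oracle))
    for (i in seq_along(got)) expect_setequal(got[[i]], oracle[[i]])
    # permutation invariance of input gene order
    perm <- g[sample(nrow(g)), , drop = FALSE]
    hs_p <- assemble_hotspots(perm, g$orthogroup_id, gap_bp = 10000,
                              min_genes = 1)
    expect_identical(lapply(hs_p$hotspots, function(h) h$genes$gene_id), got)
    # every selected gene lands in exactly one run before size filtering
    expect_setequal(unlist(got), g$gene_id)
  }
})

test_that("hotspot counts are monotone in gap_bp and min_genes", {
  set.seed(21)
  gaps <- sample(c(100, 8000, 12000, 30000), 25, replace = TRUE)
  lens <- rep(1000, 25)
  starts <- cumsum(gaps + c(0, lens[-25]))
  g <- gene_tab(cbind(starts + 1, starts + lens))
  runs_at <- function(gap) length(assemble_hotspots(g, g$orthogroup_id,
                                                    gap_bp = gap,
                                                    min_genes = 1)$hotspots)
  gaps_grid <- c(100, 5000, 10001, 12001, 30001, 1e6)
  expect_true(all(diff(vapply(gaps_grid, runs_at, numeric(1))) <= 0))
  n_at <- function(mg) length(assemble_hotspots(g, g$orthogroup_id,
                                                gap_bp = 10000,
                                                min_genes = mg)$hotspots)
  expect_true(all(diff(vapply(1:6, n_at, numeric(1))) <= 0))
})

test_that("planted pangenome yields exactly the planted hotspot, decoys rejected", {
  pg <- simulate_pangenome(20, 3, hotspot_size = 12, decoy_count = 5, seed = 3)
  sel <- select_clade_specific(pg$orthogroups, pg$focal, pg$background)
  expect_setequal(sel$selected, c(pg$truth$hotspot_orthogroups,
                                  pg$truth$decoy_orthogroups))
  ref <- pg$genomes[[pg$truth$reference]]
  hs <- assemble_hotspots(ref, sel, gap_bp = 10000, min_genes = 10)
  expect_length(hs$hotspots, 1L)
  expect_setequal(hs$hotspots[[1]]$genes$gene_id, pg$truth$hotspot_genes)
  expect_equal(c(hs$hotspots[[1]]$start, hs$hotspots[[1]]$end),
               pg$truth$interval)
  expect_false(any(pg$truth$decoy_genes %in% hs$hotspots[[1]]$genes$gene_id))
  # a 9-gene planted hotspot is filtered out at min_genes = 10
  pg9 <- simulate_pangenome(20, 3, hotspot_size = 9, decoy_count = 5, seed = 3)
  sel9 <- select_clade_specific(pg9$orthogroups, pg9$focal, pg9$background)
  hs9 <- assemble_hotspots(pg9$genomes[[pg9$truth$reference]], sel9,
                           min_genes = 10)
  expect_length(hs9$hotspots, 0L)
  # nothing planted, nothing selected
  pg0 <- simulate_pangenome(10, 3, hotspot_size = 0, decoy_count = 0, seed = 5)
  sel0 <- select_clade_specific(pg0$orthogroups, pg0$focal, pg0$background)
  expect_length(sel0$selected, 0L)
})

test_that("interval helpers reproduce the printed insert arithmetic", {
  expect_equal(interval_length_kb(29100, 64406), 35)
  expect_equal(interval_length_kb(52627, 67679), 15)
  expect_equal(interval_length_kb(5, 5), 0)
  expect_error(interval_length_kb(10, 5), class = "syncomr_arg_error")

  expect_equal(interval_intersect(c(29100, 64406), c(52627, 67679)),
               c(52627, 64406))
  expect_null(interval_intersect(c(1, 10), c(20, 30)))
  expect_equal(interval_intersect(c(3, 9), c(3, 9)), c(3, 9))
  expect_warning(out <- interval_intersect(c(1, 10), c(5, 20),
                                           scaffold_a = "s1",
                                           scaffold_b = "s2"), "scaffold")
  expect_null(out)

  g <- gene_tab(rbind(c(100, 200), c(150, 400), c(500, 600)))
  inside <- genes_in_interval(g, "scf1", 90, 450)
  expect_setequal(inside$gene_id, c("g01", "g02"))
})

test_that("hotspot_report summarizes presence across the genome universe", {
  pg <- simulate_pangenome(20, 3, hotspot_size = 12, decoy_count = 0, seed = 8)
  sel <- select_clade_specific(pg$orthogroups, pg$focal, pg$background)
  hs <- assemble_hotspots(pg$genomes[[pg$truth$reference]], sel)
  rep_out <- hotspot_report(hs, pg$orthogroups, sel)
  expect_equal(nrow(rep_out$summary), 1L)
  expect_true(all(rep_out$presence[pg$focal, 1]))
  expect_lt(mean(rep_out$presence[pg$background, 1]), sel$max_bg_prev)
  # empty hotspot set -> empty but well-formed report
  empty <- assemble_hotspots(pg$genomes[[pg$truth$reference]], character(0),
                             min_genes = 1)
  rep0 <- hotspot_report(empty, pg$orthogroups, sel)
  expect_equal(nrow(rep0$summary), 0L)
  expect_named(rep0$summary,
               c("hotspot_id", "scaffold", "start", "end", "length_kb",
                 "n_genes", "n_orthogroups", "orthogroup_ids"))
  # two hotspots on one scaffold: disjoint, sorted intervals
  g <- gene_tab(rbind(c(1, 1000), c(1500, 2500), c(50000, 51000),
                      c(51500, 52500)))
  hs2 <- assemble_hotspots(g, g$orthogroup_id, min_genes = 2)
  s <- hotspot_report(hs2, data.frame(gene_id = g$gene_id, genome_id = "G1",
                                      orthogroup_id = g$orthogroup_id),
                      list(focal = "G1", background = character(0),
                           max_bg_prev = 0.05))$summary
  expect_equal(nrow(s), 2L)
  expect_true(all(diff(s$start) > 0))
  expect_true(s$end[1] < s$start[2])
})
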