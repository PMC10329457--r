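stab <- function(site, sample, asv, ra, reads = NULL) {
  df <- data.frame(site = site, sample = sample, asv = asv,
                   relative_abundance = ra, stringsAsFactors = FALSE)
  if (!is.null(reads)) df$reads <- reads
  df
}

test_that("filter_samples keeps samples with strictly more than min_reads", {
  tab <- stab(site = "s1", sample = paste0("m", 1:5), asv = "a1",
              ra = rep(0.01, 5), reads = c(999, 1000, 1001, 5000, 200))
  out <- filter_samples(tab)
  expect_setequal(out$sample, c("m3", "m4"))  # 1000 exactly is removed
  all_deep <- stab("s1", paste0("m", 1:3), "a1", rep(0.01, 3),
                   reads = rep(9000, 3))
  expect_identical(filter_samples(all_deep), all_deep)
  expect_error(filter_samples(stab("s1", "m1", "a1", 0.01)),
               class = "syncomr_arg_error")
})

test_that("presence_calls applies the strict RA > 0.01% rule", {
  tab <- stab("s1", c("m1", "m2", "m3"), "a1", c(0.0001, 0.0002, 0))
  pres <- presence_calls(tab)
  expect_identical(unname(pres["a1", c("m1", "m2", "m3")]),
                   c(FALSE, TRUE, FALSE))
  set.seed(6)
  big <- stab(site = "s1", sample = sprintf("m%03d", rep(1:20, each = 30)),
              asv = sprintf("a%03d", rep(1:30, 20)), ra = runif(600, 0, 3e-4))
  p <- presence_calls(big)
  expect_equal(sum(p), sum(big$relative_abundance > 1e-4))
  # raising the threshold never adds presences
  p_hi <- presence_calls(big, min_ra = 2e-4)
  expect_true(all(p[p_hi]))
  expect_lte(sum(p_hi), sum(p))
})

test_that("mean_ra_present averages only present samples", {
  tab <- stab("s1", c("m1", "m2", "m3"), "a1", c(0.02, 0.0, 0.03))
  pres <- presence_calls(tab)
  expect_equal(mean_ra_present(tab, pres), c(a1 = 0.025))
  gone <- stab("s1", "m1", "a2", 0.00001)
  pres2 <- presence_calls(rbind(tab, gone))
  out <- mean_ra_present(rbind(tab, gone), pres2)
  expect_false("a2" %in% names(out))
  # excluding zeros can only raise the mean
  set.seed(7)
  rnd <- stab("s1", sprintf("m%02d", rep(1:10, each = 5)),
              sprintf("a%02d", rep(1:5, 10)), ra = runif(50, 0, 4e-4))
  mp <- mean_ra_present(rnd, presence_calls(rnd))
  for (a in names(mp)) {
    expect_gte(mp[[a]], mean(rnd$relative_abundance[rnd$asv == a]))
  }
})

test_that("widespread and core rules use strict fractions", {
  # ASV present in 4 of 5 sites: 80% exactly -> not widespread
  tab <- stab(site = rep(paste0("site", 1:5), each = 1),
              sample = paste0("m", 1:5), asv = "a1",
              ra = c(0.01, 0.01, 0.01, 0.01, 0))
  pres <- presence_calls(tab)
  expect_false(classify_widespread(tab, pres)[["a1"]])
  # 17/17 sites -> widespread
  tab2 <- stab(rep(paste0("site", 1:17)), paste0("m", 1:17), "a1",
               rep(0.01, 17))
  expect_true(classify_widespread(tab2, presence_calls(tab2))[["a1"]])
  # exactly 70% of a species' samples -> not present there -> not core
  tab3 <- stab(site = rep(c("spA", "spB"), each = 10),
               sample = paste0("m", 1:20), asv = "a1",
               ra = c(rep(0.01, 7), rep(0, 3), rep(0.01, 10)))
  expect_false(classify_core(tab3, presence_calls(tab3))[["a1"]])
  tab4 <- stab(site = rep(c("spA", "spB"), each = 10),
               sample = paste0("m", 1:20), asv = "a1",
               ra = c(rep(0.01, 8), rep(0, 2), rep(0.01, 10)))
  expect_true(classify_core(tab4, presence_calls(tab4))[["a1"]])
  # one site only: widespread set = ASVs present in that site
  one <- stab("s1", rep("m1", 2), c("a1", "a2"), c(0.01, 0))
  w <- classify_widespread(one, presence_calls(one))
  expect_true(w[["a1"]]); expect_false(w[["a2"]])
})

test_that("planted core ASVs are recovered exactly", {
  sim <- simulate_survey(n_sites = 8, samples_per_site = 6, n_asvs = 40,
                         core_count = 5, seed = 19)
  pres <- presence_calls(sim$table)
  core <- classify_core(sim$table, pres)
  expect_setequal(names(core)[core], sim$truth$core)
  wide <- classify_widespread(sim$table, pres)
  expect_true(all(wide[sim$truth$core]))
  summ <- prevalence_summary(sim$table)
  expect_setequal(summ$asv[summ$core], sim$truth$core)
  expect_true(all(summ$prevalence[summ$asv %in% sim$truth$core] == 1))
  # no planted core -> empty core set
  sim0 <- simulate_survey(5, 4, 20, core_count = 0, seed = 23)
  core0 <- classify_core(sim0$table, presence_calls(sim0$table))
  expect_false(any(core0))
})

test_that("brute-force recount confirms widespread/core on random tables", {
  set.seed(29)
  for (i in 1:5) {
    sim <- simulate_survey(4, 3, 15, core_count = 2, seed = 100 + i)
    tab <- sim$table
    pres <- presence_calls(tab)
    w <- classify_widespread(tab, pres)
    core <- classify_core(tab, pres)
    sites <- unique(tab$site)
    for (a in rownames(pres)) {
      present_sites <- vapply(sites, function(s) {
        any(tab$relative_abundance[tab$asv == a & tab$site == s] > 1e-4)
      }, logical(1))
      expect_identical(w[[a]], mean(present_sites) > 0.8)
      frac <- vapply(sites, function(s) {
        smps <- unique(tab$sample[tab$site == s])
        mean(vapply(smps, function(m) {
          any(tab$relative_abundance[tab$asv == a & tab$sample == m] > 1e-4)
        }, logical(1)))
      }, numeric(1))
      expect_identical(core[[a]], all(frac > 0.7))
    }
  }
})
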