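test_that("population simulation is fully reproducible under a seed", {
  a <- simulate_population(seed = 123)
  b <- simulate_population(seed = 123)
  expect_identical(a$library, b$library)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$site_matrix, b$site_matrix)
})

test_that("the default spec reproduces the intended population structure", {
  pop <- simulate_population(seed = 1)
  expect_equal(length(unique(pop$profiles$ST)), 25L)
  eb <- eburst(pop$profiles)
  g <- glance(eb)
  expect_equal(g$n_complexes, 2L)
  expect_equal(g$n_singletons, 14L)
  expect_equal(sort(eb$complexes$n_st), c(2L, 9L))
})

test_that("concatenate diversity of the default spec lands near 0.8-1 %", {
  pis <- vapply(1:5, function(s) {
    diversity_summary(simulate_population(seed = s)$site_matrix)$pi
  }, numeric(1))
  expect_gt(mean(pis), 0.6)
  expect_lt(mean(pis), 1.3)
})

test_that("the truth table replays to the emitted sequences exactly", {
  pop <- simulate_population(seed = 77)
  ev <- pop$truth$events
  seqs <- pop$truth$sequences
  for (i in seq_len(nrow(ev))) {
    founder <- seqs[[paste0("CC", ev$complex[i], "_founder")]][[ev$locus[i]]]
    variant <- seqs[[ev$strain[i]]][[ev$locus[i]]]
    f <- strsplit(founder, "")[[1]]
    v <- strsplit(variant, "")[[1]]
    expect_equal(which(f != v), ev$snp_sites[[i]])
    expect_equal(sum(f != v), ev$snp_count[i])
  }
})

test_that("invalid specs are rejected", {
  expect_error(population_spec(import_snp_range = c(1L, 3L)), "2 <= min")
  expect_error(population_spec(rho = 1.5))
  expect_error(population_spec(slv_per_complex = c(3L)))  # needs n_complexes
})

test_that("population-source imports copy alleles found in unrelated STs", {
  pop <- simulate_population(
    population_spec(rho = 1, import_source = "population"), seed = 14)
  eb <- eburst(pop$profiles)
  rmc <- rm_classify(eb, 1, pop$profiles, pop$library)
  expect_equal(rmc$m, 0L)
  expect_true(all(grepl("unrelated ST|SNPs", tidy(rmc)$evidence)))
})

test_that("neutral coalescent alignments honour their contracts", {
  sim <- simulate_neutral_alignment(6, 100, S = 9, seed = 3)
  expect_equal(diversity_summary(sim$alignment)$S, 9L)
  expect_equal(dim(sim$alignment), c(6L, 100L))
  # byte-identical under the same seed
  sim2 <- simulate_neutral_alignment(6, 100, S = 9, seed = 3)
  expect_identical(sim$alignment, sim2$alignment)
  # S = 0 gives a monomorphic alignment
  mono <- simulate_neutral_alignment(5, 50, S = 0, seed = 1)
  expect_equal(diversity_summary(mono$alignment)$S, 0L)
  expect_error(simulate_neutral_alignment(5, 10, S = 11), "exceeds")
  expect_error(simulate_neutral_alignment(2, 10, S = 2), "n >= 3")
  expect_error(simulate_neutral_alignment(5, 10, S = 2, theta = 1), "exactly one")
})

test_that("band patterns at zero turnover are identical within lineages", {
  bp <- simulate_band_patterns(3, bands_per_strain = 12,
                               within_lineage_turnover = 0, seed = 2)
  dm <- dice_matrix(bp$bands)
  td <- tidy(dm)
  same <- bp$truth$lineage[match(td$strain_a, bp$truth$strain)] ==
    bp$truth$lineage[match(td$strain_b, bp$truth$strain)]
  expect_true(all(td$S_D[same] == 1))
})

test_that("within-lineage Dice tracks the closed-form (1-t)^2 expectation", {
  t <- 0.35  # expected S_D = 0.65^2 = 0.4225 < 0.6: the unrelated band
  reps <- vapply(1:8, function(s) {
    bp <- simulate_band_patterns(2, bands_per_strain = 25,
                                 within_lineage_turnover = t, seed = s)
    td <- tidy(dice_matrix(bp$bands))
    same <- bp$truth$lineage[match(td$strain_a, bp$truth$strain)] ==
      bp$truth$lineage[match(td$strain_b, bp$truth$strain)]
    mean(td$S_D[same])
  }, numeric(1))
  expect_lt(abs(mean(reps) - (1 - t)^2), 0.08)
  expect_lt(mean(reps), 0.6)
})

test_that("low-turnover lineages separate with high bootstrap support", {
  bp <- simulate_band_patterns(2, bands_per_strain = 20,
                               within_lineage_turnover = 0.04,
                               strains_per_lineage = 4, seed = 6)
  ub <- upgma_bootstrap(bp$bands, replicates = 150, seed = 7)
  expect_true(any(ub$support > 95))
})
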