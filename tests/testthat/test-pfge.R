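test_that("band classes form by single linkage within relative tolerance", {
  pat <- tibble::tibble(strain = c("s1", "s2"),
                        sizes = list(c(100, 200), c(200, 300)))
  m <- band_matrix(pat, tolerance = 0.015)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m["s1", ]), c(1L, 1L, 0L))
  expect_equal(unname(m["s2", ]), c(0L, 1L, 1L))

  # 200 vs 202: relative gap 2/201 = 0.995% < 1.5% -> one class
  pat2 <- tibble::tibble(strain = c("a", "b"), sizes = list(200, 202))
  m2 <- band_matrix(pat2)
  expect_equal(ncol(m2), 1L)
  expect_equal(unname(rowSums(m2)), c(1L, 1L))

  # identical size lists give identical rows
  pat3 <- tibble::tibble(strain = c("a", "b"), sizes = list(c(50, 90), c(50, 90)))
  m3 <- band_matrix(pat3)
  expect_equal(unname(m3["a", ]), unname(m3["b", ]))
})

test_that("two sizes of one strain collapsing into one class is an error", {
  pat <- tibble::tibble(strain = "s1", sizes = list(c(200, 202)))
  expect_error(band_matrix(pat), "ambiguous.*s1")
  expect_error(band_matrix(tibble::tibble(strain = "s1", sizes = list(-5))),
               "positive")
})

test_that("Dice coefficients match direct band counting", {
  m <- rbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1))
  dm <- dice_matrix(m)
  expect_equal(dm$similarity["a", "b"], 2 * 2 / (3 + 3))
  ident <- rbind(a = c(1, 1), b = c(1, 1))
  expect_equal(dice_matrix(ident)$similarity["a", "b"], 1)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(dice_matrix(disjoint)$similarity["a", "b"], 0)
  expect_error(dice_matrix(rbind(a = c(1, 0), b = c(0, 0))), "zero bands")
  td <- tidy(dice_matrix(m))
  expect_false(td$unrelated[1])  # 0.667 >= 0.6
})

test_that("Dice agrees with the independent Sorensen implementation in vegan", {
  skip_if_not_installed("vegan")
  set.seed(44)
  m <- matrix(rbinom(8 * 25, 1, 0.5), 8, 25,
              dimnames = list(paste0("s", 1:8), NULL))
  m <- m[rowSums(m) > 0, ]
  ours <- dice_matrix(m)$distance
  ref <- as.matrix(vegan::vegdist(m, method = "bray", binary = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("UPGMA bootstrap gives full support to a clean family split", {
  fam1 <- rbind(a1 = c(rep(1, 10), rep(0, 10)),
                a2 = c(rep(1, 10), rep(0, 10)))
  fam2 <- rbind(b1 = c(rep(0, 10), rep(1, 10)),
                b2 = c(rep(0, 10), rep(1, 10)))
  # small private bands so within-family distances are not all zero
  m <- rbind(fam1, fam2)
  m <- cbind(m, diag(4))
  rownames(m) <- c("a1", "a2", "b1", "b2")
  ub <- upgma_bootstrap(m, replicates = 100, seed = 9)
  expect_true(any(ub$support >= 99))
})

test_that("random independent band patterns earn only weak support", {
  set.seed(55)
  m <- matrix(rbinom(12 * 30, 1, 0.5), 12, 30,
              dimnames = list(paste0("s", 1:12), NULL))
  m <- m[rowSums(m) > 0, ]
  ub <- upgma_bootstrap(m, replicates = 120, seed = 10)
  expect_lt(stats::median(ub$support), 90)
})

test_that("chromosome size averages digests with half-range uncertainty", {
  digests <- tibble::tibble(
    strain = "X",
    digest = c("SmaI", "SmaI", "CeuI_NotI"),
    size_kb = c(1400, 1000, 2422))
  gs <- genome_size(digests)
  expect_equal(gs$chromosome_kb, (2400 + 2422) / 2)
  expect_equal(gs$uncertainty_kb, 11)
  single <- genome_size(tibble::tibble(strain = "Y", digest = "SmaI",
                                       size_kb = c(1200, 800)))
  expect_equal(single$uncertainty_kb, 0)
  expect_equal(single$chromosome_kb, 2000)
  expect_error(genome_size(tibble::tibble(strain = character(),
                                          digest = character(),
                                          size_kb = numeric())), "empty")
})

test_that("genome size adds plasmids and never falls below the chromosome", {
  digests <- tibble::tibble(strain = c("X", "X", "Y"),
                            digest = c("SmaI", "CeuI_NotI", "SmaI"),
                            size_kb = c(2400, 2420, 2500))
  plasmids <- tibble::tibble(strain = c("X", "X"), size_kb = c(50, 30))
  gs <- genome_size(digests, plasmids)
  expect_equal(gs$genome_kb[gs$strain == "X"], 2410 + 80)
  expect_equal(gs$plasmids_kb[gs$strain == "Y"], 0)
  expect_true(all(gs$genome_kb >= gs$chromosome_kb))
})

test_that("feature associations detect the constructed plasmid-genome link", {
  set.seed(12)
  n <- 30
  dat <- tibble::tibble(
    strain = paste0("s", 1:n),
    chromosome_kb = rnorm(n, 2500, 80),
    plasmid_kb = runif(n, 0, 300),
    origin = rep(c("dairy", "environmental"), length.out = n))
  res <- feature_associations(dat)
  sp_gen <- res[res$variables == "plasmid_kb ~ genome_kb", ]
  sp_chr <- res[res$variables == "plasmid_kb ~ chromosome_kb", ]
  expect_gt(sp_gen$estimate, 0.3)
  expect_lt(sp_gen$p_value, 0.05)
  expect_gt(sp_chr$p_value, 0.05)  # independent components
  # identical size distributions across origins: rank-sum p far from 0
  mw <- res[res$test == "mann_whitney" & res$variables == "chromosome_kb ~ origin", ]
  expect_gt(mw$p_value, 0.05)
})

test_that("degenerate feature inputs are flagged, not crashed", {
  dat <- tibble::tibble(strain = paste0("s", 1:6),
                        chromosome_kb = c(2400, 2410, 2420, 2430, 2440, 2450),
                        plasmid_kb = 0,
                        origin = "dairy")
  res <- feature_associations(dat)
  expect_match(res$note[res$variables == "plasmid_kb ~ genome_kb"], "constant")
  expect_match(res$note[res$test == "rank_sum"], "single origin class")
})
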