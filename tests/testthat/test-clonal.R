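test_that("a two-ST SLV pair forms one complex with a deterministic founder", {
  pm <- rbind(A = c(1, 1, 1, 1, 1, 1), B = c(1, 1, 1, 1, 1, 2))
  prof <- profiles_from_matrix(pm)
  eb <- eburst(prof)
  expect_equal(nrow(eb$complexes), 1L)
  expect_equal(sum(is.na(eb$nodes$complex)), 0L)
  # SLV and DLV degrees tie; isolate counts tie; lowest ST id founds
  expect_equal(eb$complexes$founder, 1L)
  expect_equal(eb$complexes$tie_break, "lowest_st_id")
})

test_that("the A-B-C chain is founded by the middle ST (2 SLVs)", {
  pm <- rbind(A = c(1, 1, 1, 1, 1, 1),
              B = c(1, 1, 1, 1, 1, 2),
              C = c(1, 1, 1, 1, 2, 2))
  prof <- profiles_from_matrix(pm)
  eb <- eburst(prof)
  expect_equal(nrow(eb$complexes), 1L)
  expect_equal(eb$complexes$n_st, 3L)
  expect_equal(eb$complexes$founder, 2L)  # B
  # C is a DLV of A
  dlv <- eb$edges[eb$edges$type == "dlv", ]
  expect_equal(nrow(dlv), 1L)
  expect_setequal(c(dlv$from, dlv$to), c(1L, 3L))
})

test_that("eBURST grouping is invariant under ST relabeling", {
  pop <- simulate_population(seed = 29)
  eb1 <- eburst(pop$profiles)
  set.seed(4)
  shuffled <- pop$profiles[sample(nrow(pop$profiles)), ]
  shuffled <- assign_sts(shuffled)  # fresh first-encounter ST numbering
  eb2 <- eburst(shuffled)
  expect_equal(glance(eb1), glance(eb2))
  # same partition up to labels: compare via Rand index on isolates
  key <- function(eb, prof) {
    nodes <- tidy(eb)
    cl <- ifelse(is.na(nodes$complex), -nodes$ST, nodes$complex)
    cl[match(prof$ST, nodes$ST)]
  }
  iso_order <- sort(pop$profiles$isolate)
  a <- key(eb1, pop$profiles)[match(iso_order, pop$profiles$isolate)]
  b <- key(eb2, shuffled)[match(iso_order, shuffled$isolate)]
  expect_equal(rand_index(a, b), 1)
})

test_that("DLV relaxation merges a DLV-only chain and reports only the delta", {
  # A - (DLV) - B - (DLV) - C with no SLVs
  pm <- rbind(A = c(1, 1, 1, 1, 1, 1),
              B = c(1, 1, 1, 1, 2, 2),
              C = c(1, 1, 2, 2, 2, 2))
  prof <- profiles_from_matrix(pm)
  eb <- eburst(prof)
  expect_equal(nrow(eb$complexes), 0L)
  merged <- relax_to_dlv(eb)
  expect_equal(nrow(merged), 3L)
  expect_equal(length(unique(merged$group)), 1L)

  # no DLV pairs -> grouping unchanged, empty delta
  pm2 <- rbind(A = c(1, 1, 1, 1, 1, 1), B = c(2, 2, 2, 2, 2, 2))
  expect_equal(nrow(relax_to_dlv(eburst(profiles_from_matrix(pm2)))), 0L)
})

test_that("r/m classifies a private single SNP as mutation, multi-SNP as recombination", {
  anc <- strsplit(paste(rep("A", 30), collapse = ""), "")[[1]]
  mk <- function(snps) {
    s <- anc
    for (i in seq_along(snps)) s[snps[i]] <- "T"
    paste(s, collapse = "")
  }
  # founder allele 1 everywhere; slv_m differs at locus1 by 1 private SNP;
  # slv_r differs at locus2 by 3 SNPs
  lib <- allele_library(tibble::tibble(
    locus = c("locus1", "locus1", "locus2", "locus2",
              "locus3", "locus4", "locus5", "locus6"),
    allele = c(1L, 2L, 1L, 2L, 1L, 1L, 1L, 1L),
    seq = c(mk(integer(0)), mk(5), mk(integer(0)), mk(c(2, 9, 20)),
            mk(integer(0)), mk(integer(0)), mk(integer(0)), mk(integer(0)))))
  pm <- rbind(founder = c(1, 1, 1, 1, 1, 1),
              slv_m = c(2, 1, 1, 1, 1, 1),
              slv_r = c(1, 2, 1, 1, 1, 1))
  prof <- profiles_from_matrix(pm, loci = paste0("locus", 1:6))
  eb <- eburst(prof)
  rmc <- rm_classify(eb, 1, prof, lib)
  expect_equal(rmc$m, 1L)
  expect_equal(rmc$r, 3L)
  ev <- tidy(rmc)
  expect_equal(ev$class[ev$locus == "locus1"], "mutation")
  expect_equal(ev$class[ev$locus == "locus2"], "recombination")
  expect_match(ev$evidence[ev$locus == "locus2"], "3 SNPs")
})

test_that("a variant allele present in an unrelated ST is recombination even with 1 SNP", {
  anc <- strsplit(paste(rep("A", 30), collapse = ""), "")[[1]]
  one_snp <- anc; one_snp[5] <- "T"
  lib <- allele_library(tibble::tibble(
    locus = rep(paste0("locus", 1:6), times = c(2, 1, 1, 1, 1, 1)),
    allele = c(1L, 2L, 1L, 1L, 1L, 1L, 1L),
    seq = c(paste(anc, collapse = ""), paste(one_snp, collapse = ""),
            rep(paste(anc, collapse = ""), 5))))
  # outsider carries the same locus1 allele 2 but differs at >2 loci overall
  pm <- rbind(founder = c(1, 1, 1, 1, 1, 1),
              slv = c(2, 1, 1, 1, 1, 1),
              outsider = c(2, 9, 9, 9, 1, 1))
  prof <- profiles_from_matrix(pm, loci = paste0("locus", 1:6))
  eb <- eburst(prof)
  rmc <- rm_classify(eb, 1, prof, lib)
  ev <- tidy(rmc)
  expect_equal(ev$class, "recombination")
  expect_match(ev$evidence, "unrelated ST")
  expect_equal(rmc$m, 0L)
  expect_true(is.na(rmc$rm_ratio))
})

test_that("generator truth is recovered exactly by eburst and rm_classify", {
  for (seed in c(42, 101)) {
    pop <- simulate_population(seed = seed)
    eb <- eburst(pop$profiles)
    truth <- pop$truth
    # partition recovery: complexes + singletons, Rand index 1
    nodes <- tidy(eb)
    inferred <- ifelse(is.na(nodes$complex), -nodes$ST, nodes$complex)
    true_lineage <- truth$membership$lineage[match(nodes$ST, truth$membership$ST)]
    expect_equal(rand_index(inferred, true_lineage), 1)
    # founders are the true complex founders
    founder_st <- truth$membership$ST[truth$membership$strain ==
                                        paste0("CC1_founder")]
    cc_of_founder <- nodes$complex[nodes$ST == founder_st]
    expect_equal(eb$complexes$founder[eb$complexes$complex == cc_of_founder],
                 founder_st)
    # exact r and m recovery per complex
    for (cc in unique(truth$events$complex)) {
      cc_inferred <- nodes$complex[nodes$ST ==
                                     truth$membership$ST[truth$membership$strain ==
                                                           paste0("CC", cc, "_founder")]]
      rmc <- rm_classify(eb, cc_inferred, pop$profiles, pop$library)
      ev_true <- truth$events[truth$events$complex == cc, ]
      expect_equal(rmc$m, sum(ev_true$snp_count[ev_true$event == "mutation"]))
      expect_equal(rmc$r, sum(ev_true$snp_count[ev_true$event == "recombination"]))
    }
  }
})

test_that("with rho = 0 every event is a mutation and r = 0", {
  pop <- simulate_population(population_spec(rho = 0), seed = 8)
  expect_true(all(pop$truth$events$event == "mutation"))
  eb <- eburst(pop$profiles)
  for (cc in eb$complexes$complex) {
    rmc <- rm_classify(eb, cc, pop$profiles, pop$library)
    expect_equal(rmc$r, 0L)
  }
})

test_that("rm_classify rejects a non-SLV comparison", {
  pm <- rbind(A = c(1, 1, 1, 1, 1, 1), B = c(1, 1, 1, 1, 1, 2))
  prof <- profiles_from_matrix(pm)
  eb <- eburst(prof)
  expect_error(rm_classify(eb, 99, prof, allele_library()), "no complex")
})
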