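# shared helpers for building tiny alignments and profiles in code

rand_alignment <- function(n, L, bases = c("A", "C", "G", "T")) {
  m <- matrix(sample(bases, n * L, replace = TRUE), n, L)
  rownames(m) <- paste0("s", seq_len(n))
  m
}

# brute-force pi / pi_max oracle: enumerate every pair with a character loop
brute_force_pi <- function(m) {
  n <- nrow(m)
  L <- ncol(m)
  diffs <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 0
      for (s in seq_len(L)) if (m[i, s] != m[j, s]) d <- d + 1
      diffs <- c(diffs, d)
    }
  }
  list(pi = 100 * mean(diffs) / L, pi_max = 100 * max(diffs) / L)
}

# profile table from a plain integer matrix (rows = isolates)
profiles_from_matrix <- function(pm, loci = paste0("locus", seq_len(ncol(pm)))) {
  colnames(pm) <- loci
  tibble::as_tibble(pm) |>
    dplyr::mutate(isolate = paste0("iso", dplyr::row_number()),
                  .before = 1) |>
    assign_sts(loci = loci)
}

# random allele renumbering: bijectively remap the allele ids of each locus
renumber_profiles <- function(profiles, loci = detect_loci(profiles)) {
  for (loc in loci) {
    ids <- sort(unique(profiles[[loc]]))
    remap <- stats::setNames(sample(1000L + seq_along(ids)), ids)
    profiles[[loc]] <- unname(remap[as.character(profiles[[loc]])])
  }
  profiles
}
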