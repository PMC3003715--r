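#' Specification of a synthetic clonal population
#'
#' Defines the structure the generator emulates: a set of divergent
#' singleton lineages plus clonal complexes grown from founders by
#' single-locus events — point mutations (one new private SNP) or
#' recombination imports (allele replacement differing by several SNPs,
#' or an allele copied from an unrelated lineage).  The defaults mirror
#' a small clonal dairy population: six loci of 516/453/492/504/480/489
#' bp, 14 singletons, two complexes of 9 and 2 STs (25 STs in all), a
#' per-site singleton divergence of 0.005 from the common ancestor
#' (placing concatenate diversity near 0.8-1 %), and an even split of
#' SLV events between mutation and import.
#'
#' @param loci Named integer vector of locus lengths.
#' @param n_singletons Number of singleton lineages.
#' @param singleton_divergence Per-site substitution probability from
#'   the common ancestor for each lineage founder.
#' @param n_complexes Number of clonal complexes.
#' @param slv_per_complex Integer vector: SLVs grown from each founder
#'   (complex size minus one).
#' @param rho Probability that an SLV event is a recombination import.
#' @param import_source `"external"` (novel donor allele differing by
#'   `import_snp_range` SNPs) or `"population"` (allele copied from a
#'   random unrelated lineage).
#' @param import_snp_range Min/max SNPs per external import (min >= 2 so
#'   import events are unambiguous).
#' @param isolates_per_st Isolates sampled per ST (redundancy).
#' @return A validated `population_spec` list.
#' @export
population_spec <- function(loci = mlst_loci(),
                            n_singletons = 14L,
                            singleton_divergence = 0.005,
                            n_complexes = 2L,
                            slv_per_complex = c(8L, 1L),
                            rho = 0.5,
                            import_source = c("external", "population"),
                            import_snp_range = c(2L, 4L),
                            isolates_per_st = 1L) {
  import_source <- match.arg(import_source)
  stopifnot(length(loci) >= 2L, all(loci > 0L), !is.null(names(loci)),
            n_singletons >= 0L, n_complexes >= 0L,
            length(slv_per_complex) == n_complexes,
            singleton_divergence >= 0, singleton_divergence <= 1,
            rho >= 0, rho <= 1, isolates_per_st >= 1L)
  if (import_snp_range[1] < 2L || import_snp_range[2] < import_snp_range[1]) {
    abort("import_snp_range must satisfy 2 <= min <= max")
  }
  structure(list(loci = loci, n_singletons = as.integer(n_singletons),
                 singleton_divergence = singleton_divergence,
                 n_complexes = as.integer(n_complexes),
                 slv_per_complex = as.integer(slv_per_complex),
                 rho = rho, import_source = import_source,
                 import_snp_range = as.integer(import_snp_range),
                 isolates_per_st = as.integer(isolates_per_st)),
            class = "population_spec")
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

diverge_seq <- function(seq, p) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(s)) < p)
  for (i in hit) s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  paste(s, collapse = "")
}

#' Simulate a clonal population with event truth
#'
#' Lineage founders are drawn by mutating a common ancestor at the
#' singleton divergence rate; each complex then grows SLVs from its
#' founder, one locus change per SLV.  Mutation events introduce one new
#' SNP at a site monomorphic across every allele of the locus (so the
#' SNP is provably private); external imports replace the allele with a
#' donor differing at 2 or more unused sites; population imports copy
#' the allele of an unrelated lineage.  Every event is recorded in the
#' truth table, so downstream r/m classification can be scored exactly.
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed (full reproducibility).
#' @return Object of class `mlst_population`: `library` (allele
#'   library), `profiles` (isolate-level profile table with `ST`,
#'   `origin`, `markers`), `site_matrix` (per-ST concatenate),
#'   `truth` (list: `events` tibble and `membership` tibble mapping ST
#'   to true lineage), and `spec`.
#' @export
simulate_population <- function(spec = population_spec(), seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  loci <- names(spec$loci)
  ancestor <- lapply(spec$loci, random_seq)

  n_lineages <- spec$n_singletons + spec$n_complexes
  lineage_names <- c(
    if (spec$n_complexes > 0) paste0("CC", seq_len(spec$n_complexes), "_founder"),
    if (spec$n_singletons > 0) sprintf("singleton_%02d", seq_len(spec$n_singletons))
  )
  # per-lineage founder sequences
  lineage_seqs <- lapply(lineage_names, function(nm) {
    vapply(loci, function(loc) diverge_seq(ancestor[[loc]],
                                           spec$singleton_divergence),
           character(1))
  })
  names(lineage_seqs) <- lineage_names

  # strain sequence sets: start from lineage founders
  strain_seqs <- lineage_seqs
  strain_lineage <- setNames(lineage_names, lineage_names)

  # locus pools for privacy checks: all allele sequences currently in play
  pool <- lapply(loci, function(loc) {
    unique(vapply(lineage_seqs, function(s) s[[loc]], character(1)))
  })
  names(pool) <- loci
  used_sites <- lapply(spec$loci, function(L) integer(0))

  events <- list()
  for (ci in seq_len(spec$n_complexes)) {
    founder_nm <- paste0("CC", ci, "_founder")
    founder <- strain_seqs[[founder_nm]]
    n_slv <- spec$slv_per_complex[ci]
    for (si in seq_len(n_slv)) {
      loc <- loci[((si - 1) %% length(loci)) + 1]
      L <- spec$loci[[loc]]
      f_chars <- strsplit(founder[[loc]], "")[[1]]
      is_import <- stats::runif(1) < spec$rho
      if (!is_import) {
        # point mutation: site monomorphic across the whole locus pool,
        # never used by a previous event
        pool_chars <- do.call(rbind, strsplit(pool[[loc]], ""))
        mono <- which(apply(pool_chars, 2, function(col) length(unique(col)) == 1L))
        candidates <- setdiff(mono, used_sites[[loc]])
        if (length(candidates) == 0L) abort("no monomorphic site left for a private mutation")
        site <- if (length(candidates) == 1L) candidates else sample(candidates, 1)
        new_chars <- f_chars
        new_chars[site] <- sample(setdiff(c("A", "C", "G", "T"), f_chars[site]), 1)
        variant <- paste(new_chars, collapse = "")
        used_sites[[loc]] <- c(used_sites[[loc]], site)
        ev_type <- "mutation"; sites <- site
      } else if (spec$import_source == "external") {
        k <- sample(seq(spec$import_snp_range[1], spec$import_snp_range[2]), 1)
        candidates <- setdiff(seq_len(L), used_sites[[loc]])
        sites <- sort(sample(candidates, k))
        new_chars <- f_chars
        for (s2 in sites) {
          new_chars[s2] <- sample(setdiff(c("A", "C", "G", "T"), f_chars[s2]), 1)
        }
        variant <- paste(new_chars, collapse = "")
        used_sites[[loc]] <- c(used_sites[[loc]], sites)
        ev_type <- "recombination"
      } else {
        # copy the allele of an unrelated (singleton) lineage
        donors <- grep("^singleton", names(lineage_seqs), value = TRUE)
        donor_alleles <- vapply(lineage_seqs[donors], function(s) s[[loc]],
                                character(1))
        ok <- donor_alleles != founder[[loc]]
        if (!any(ok)) abort("no distinct donor allele available for import")
        variant <- sample(donor_alleles[ok], 1)
        sites <- which(strsplit(variant, "")[[1]] != f_chars)
        ev_type <- "recombination"
      }
      if (variant %in% vapply(strain_seqs, function(s) s[[loc]], character(1))[
        startsWith(names(strain_seqs), paste0("CC", ci, "_"))]) {
        abort("event produced a duplicate allele within the complex; use another seed")
      }
      slv_nm <- paste0("CC", ci, "_slv", si)
      sv <- founder
      sv[[loc]] <- variant
      strain_seqs[[slv_nm]] <- sv
      strain_lineage[[slv_nm]] <- founder_nm
      pool[[loc]] <- unique(c(pool[[loc]], variant))
      events[[length(events) + 1]] <- tibble(
        complex = ci, strain = slv_nm, locus = loc, event = ev_type,
        snp_count = length(sites), snp_sites = list(as.integer(sites))
      )
    }
  }

  strains <- names(strain_seqs)
  # allele numbering in strain order, locus by locus
  library <- allele_library()
  assignments <- list()
  for (loc in loci) {
    calls <- tibble(isolate = strains, locus = loc,
                    seq = vapply(strain_seqs, function(s) s[[loc]], character(1)))
    res <- assign_alleles(calls, library)
    library <- res$library
    assignments[[loc]] <- res$assignments$allele
  }
  profiles <- tibble(isolate = strains)
  for (loc in loci) profiles[[loc]] <- assignments[[loc]]
  is_complex <- grepl("^CC", strains)
  origins <- c("plant", "raw milk", "animal skin", "fermented product")
  profiles$origin <- ifelse(is_complex, "dairy starter",
                            origins[(seq_along(strains) %% length(origins)) + 1])
  profiles$markers <- ifelse(is_complex, "lacE;prtP", "")
  profiles <- assign_sts(profiles, loci)

  # optional isolate redundancy
  if (spec$isolates_per_st > 1L) {
    extra <- profiles[rep(seq_len(nrow(profiles)), spec$isolates_per_st - 1L), ]
    extra$isolate <- paste0(extra$isolate, "_dup",
                            rep(seq_len(spec$isolates_per_st - 1L),
                                each = nrow(profiles)))
    profiles <- dplyr::bind_rows(profiles, extra)
  }

  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble(complex = integer(), strain = character(), locus = character(),
           event = character(), snp_count = integer(), snp_sites = list())
  st_of <- setNames(profiles$ST[match(strains, profiles$isolate)], strains)
  if (nrow(events)) events$ST <- unname(st_of[events$strain])
  membership <- tibble(
    strain = strains,
    ST = unname(st_of[strains]),
    lineage = unname(strain_lineage[strains])
  )
  m <- concatenate_sts(profiles, library, loci = loci)
  structure(list(spec = spec, library = library, profiles = profiles,
                 site_matrix = m,
                 truth = list(events = events, membership = membership,
                              sequences = strain_seqs)),
            class = "mlst_population")
}

#' @export
print.mlst_population <- function(x, ...) {
  cat(sprintf("Synthetic clonal population: %d isolates, %d STs, %d loci\n",
              nrow(x$profiles), length(unique(x$profiles$ST)),
              length(x$spec$loci)))
  if (nrow(x$truth$events)) {
    cat(sprintf("  events: %d mutation, %d recombination\n",
                sum(x$truth$events$event == "mutation"),
                sum(x$truth$events$event == "recombination")))
  }
  invisible(x)
}

#' Simulate a neutral coalescent alignment
#'
#' Standard neutral coalescent for n samples, no recombination,
#' infinite-sites mutations mapped to distinct positions of an L-site
#' alignment.  Mutations are either conditioned on a fixed segregating
#' site count S (placed multinomially on branches proportionally to
#' branch length) or Poisson with rate theta/2 per unit branch length.
#'
#' @param n Sample size (>= 3).
#' @param L Alignment length in sites.
#' @param S Segregating sites to condition on (exclusive with `theta`).
#' @param theta Population mutation rate (per locus).
#' @param seed Optional integer seed.
#' @return List: `alignment` (site matrix, rows `seq1..seqn`),
#'   `ancestral` (character vector of ancestral states, a perfect
#'   outgroup), `S` (realised segregating sites).
#' @export
simulate_neutral_alignment <- function(n, L, S = NULL, theta = NULL, seed = NULL) {
  if (n < 3L) abort("coalescent simulation needs n >= 3")
  if (is.null(S) == is.null(theta)) abort("supply exactly one of S or theta")
  if (!is.null(S) && S > L) abort("S exceeds the number of sites L")
  if (!is.null(seed)) set.seed(seed)
  # active lineages: list of leaf index vectors, with accumulated lengths
  active <- lapply(seq_len(n), function(i) i)
  lengths <- rep(0, n)
  done_sets <- list()
  done_lens <- numeric(0)
  k <- n
  while (k > 1L) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    lengths <- lengths + t_k
    pair <- sample.int(k, 2)
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    done_sets <- c(done_sets, active[pair])
    done_lens <- c(done_lens, lengths[pair])
    active <- c(active[-pair], list(merged))
    lengths <- c(lengths[-pair], 0)
    k <- k - 1L
  }
  # drop the root branch (mutations there are invisible: fixed in sample)
  informative <- vapply(done_sets, length, integer(1)) < n
  done_sets <- done_sets[informative]
  done_lens <- done_lens[informative]
  total_len <- sum(done_lens)
  n_mut <- if (!is.null(S)) S else stats::rpois(1, theta / 2 * total_len)
  n_mut <- min(n_mut, L)
  alignment <- matrix("A", n, L,
                      dimnames = list(paste0("seq", seq_len(n)), NULL))
  ancestral <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  for (j in seq_len(L)) alignment[, j] <- ancestral[j]
  if (n_mut > 0L) {
    positions <- sample.int(L, n_mut)
    branch <- sample.int(length(done_sets), n_mut, replace = TRUE,
                         prob = done_lens)
    for (i in seq_len(n_mut)) {
      pos <- positions[i]
      carriers <- done_sets[[branch[i]]]
      derived <- sample(setdiff(c("A", "C", "G", "T"), ancestral[pos]), 1)
      alignment[carriers, pos] <- derived
    }
  }
  list(alignment = alignment, ancestral = ancestral, S = n_mut)
}

#' Simulate PFGE band patterns by band gain/loss
#'
#' Each lineage receives an ancestral band set; strains derive from it
#' by losing each ancestral band with probability `within_lineage_turnover`
#' and gaining a matching binomial number of novel bands.  The expected
#' within-lineage Dice coefficient is approximately
#' \eqn{(1 - t)^2 / (1 - t + t)} = \eqn{(1-t)^2} at equal band counts,
#' so similarity decreases monotonically with turnover.
#'
#' @param n_lineages Number of lineages.
#' @param bands_per_strain Ancestral band count per lineage.
#' @param within_lineage_turnover Band gain/loss probability t in [0,1].
#' @param strains_per_lineage Strains drawn per lineage.
#' @param seed Optional integer seed.
#' @return List: `bands` (binary matrix strains x band classes) and
#'   `truth` (tibble `strain`, `lineage`).
#' @export
simulate_band_patterns <- function(n_lineages, bands_per_strain = 15L,
                                   within_lineage_turnover = 0.1,
                                   strains_per_lineage = 4L, seed = NULL) {
  t <- within_lineage_turnover
  stopifnot(t >= 0, t <= 1, n_lineages >= 1L, bands_per_strain >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pool_size <- 4L * n_lineages * bands_per_strain
  ancestral <- lapply(seq_len(n_lineages), function(li) {
    sample.int(pool_size, bands_per_strain)
  })
  rows <- list()
  truth <- list()
  for (li in seq_len(n_lineages)) {
    for (si in seq_len(strains_per_lineage)) {
      keep <- ancestral[[li]][stats::runif(bands_per_strain) >= t]
      n_gain <- stats::rbinom(1, bands_per_strain, t)
      gain <- if (n_gain > 0) {
        sample(setdiff(seq_len(pool_size), ancestral[[li]]), n_gain)
      } else integer(0)
      nm <- sprintf("L%02d_s%02d", li, si)
      rows[[nm]] <- sort(unique(c(keep, gain)))
      truth[[nm]] <- li
    }
  }
  classes <- sort(unique(unlist(rows)))
  bands <- matrix(0L, length(rows), length(classes),
                  dimnames = list(names(rows), paste0("band_", classes)))
  for (nm in names(rows)) bands[nm, match(rows[[nm]], classes)] <- 1L
  list(bands = bands,
       truth = tibble(strain = names(rows),
                      lineage = as.integer(unlist(truth))))
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two clusterings agree (co-clustered
#' in both or separated in both); 1 means identical partitions.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The Rand index in [0, 1].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  pairs <- combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
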