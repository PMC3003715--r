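tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

count_segregating <- function(m) {
  sum(apply(m, 2, function(col) {
    col <- col[col != "N"]
    length(unique(col)) > 1L
  }))
}

#' Tajima's D neutrality test statistic
#'
#' Contrasts the mean pairwise difference estimator of theta with the
#' segregating-sites (Watterson) estimator:
#' \eqn{D = (\hat k - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the
#' standard Tajima (1989) constants for the sample size.  Negative
#' values indicate an excess of rare variants (e.g. after a bottleneck
#' plus expansion), positive values an excess of intermediate-frequency
#' variants.
#'
#' @param m Site matrix (no missing states).
#' @return The D statistic (0 for the degenerate n = 2 case, where the
#'   two estimators coincide algebraically).
#' @export
tajima_d <- function(m) {
  n <- nrow(m)
  if (n < 2L) abort("Tajima's D needs at least 2 sequences")
  S <- count_segregating(m)
  if (S == 0L) abort("no polymorphism (S = 0)")
  if (n == 2L) return(0)
  k_hat <- mean(pairwise_diffs(m)[upper.tri(diag(n))])
  cst <- tajima_constants(n)
  (k_hat - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

fu_li_constants <- function(n) {
  i <- seq_len(n - 1)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / ((n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  list(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu & Li's D and F tests with an outgroup
#'
#' The outgroup polarises segregating sites: a mutation is external when
#' exactly one ingroup sequence carries the derived state (the state
#' differing from the outgroup).  \eqn{\eta} is the total mutation count
#' (infinite-sites bookkeeping: one event per segregating site),
#' \eqn{\eta_e} the external count.  Sites where the outgroup state is
#' missing or matches no ingroup state, and ingroup sites with more than
#' two states, are counted in \eqn{\eta} but excluded from the
#' \eqn{\eta_e} determination; the exclusion counts are reported.
#'
#' @param m Ingroup site matrix (`n >= 3` rows, no missing states).
#' @param outgroup A single aligned sequence (string or character
#'   vector of states) of the same length; `N` marks missing states.
#' @return One-row tibble: `n`, `eta`, `eta_e`, `excluded_sites`,
#'   `multiallelic_sites`, `D`, `F`.
#' @export
fu_li_df <- function(m, outgroup) {
  n <- nrow(m)
  if (n < 3L) abort("Fu & Li's tests need at least 3 ingroup sequences")
  if (is.character(outgroup) && length(outgroup) == 1L) {
    outgroup <- strsplit(toupper(outgroup), "")[[1]]
  }
  if (length(outgroup) != ncol(m)) {
    abort("outgroup is not aligned to the ingroup (length mismatch)")
  }
  eta <- 0L; eta_e <- 0L; excluded <- 0L; multi <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    states <- unique(col)
    if (length(states) < 2L) next
    eta <- eta + 1L
    if (length(states) > 2L) { multi <- multi + 1L; next }
    og <- outgroup[j]
    if (og == "N" || !(og %in% states)) { excluded <- excluded + 1L; next }
    derived <- setdiff(states, og)
    if (sum(col == derived) == 1L) eta_e <- eta_e + 1L
  }
  if (eta == 0L) abort("no polymorphism (eta = 0)")
  cst <- fu_li_constants(n)
  k_hat <- mean(pairwise_diffs(m)[upper.tri(diag(n))])
  D <- (eta - cst$an * eta_e) / sqrt(cst$uD * eta + cst$vD * eta^2)
  F_ <- (k_hat - eta_e) / sqrt(cst$uF * eta + cst$vF * eta^2)
  tibble(n = n, eta = eta, eta_e = eta_e, excluded_sites = excluded,
         multiallelic_sites = multi, D = D, F = F_)
}

#' Monte-Carlo significance band for a neutrality statistic
#'
#' Simulates standard neutral coalescent samples (no recombination)
#' conditioned on the observed n and S, recomputes the statistic on each
#' replicate, and returns the coarse two-tailed band used in summary
#' tables.  For the Fu & Li statistics the simulated ancestral sequence
#' serves as a perfect outgroup.
#'
#' @param stat Observed statistic value.
#' @param n Sample size.
#' @param S Segregating-site count to condition on.
#' @param statistic One of `"tajima_d"`, `"fu_li_d"`, `"fu_li_f"`.
#' @param replicates Coalescent replicates (>= 1000 recommended).
#' @param seed Optional integer seed.
#' @param L Alignment length used for the simulated sites (default
#'   `max(2 * S, 100)`; the statistics are length-free).
#' @return A list: `p_value` (two-tailed, add-one smoothed), `band`
#'   (`"ns"`, `"0.05<p<0.1"` or `"p<0.05"`), and `null` (the simulated
#'   statistic values).
#' @export
neutrality_significance <- function(stat, n, S,
                                    statistic = c("tajima_d", "fu_li_d", "fu_li_f"),
                                    replicates = 1000, seed = NULL,
                                    L = max(2L * S, 100L)) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(replicates), function(r) {
    sim <- simulate_neutral_alignment(n, L, S = S)
    switch(statistic,
      tajima_d = tajima_d(sim$alignment),
      fu_li_d = fu_li_df(sim$alignment, sim$ancestral)$D,
      fu_li_f = fu_li_df(sim$alignment, sim$ancestral)$F
    )
  }, numeric(1))
  p_lo <- (1 + sum(null <= stat)) / (1 + replicates)
  p_hi <- (1 + sum(null >= stat)) / (1 + replicates)
  p <- min(1, 2 * min(p_lo, p_hi))
  band <- if (p < 0.05) "p<0.05" else if (p < 0.1) "0.05<p<0.1" else "ns"
  list(p_value = p, band = band, null = null)
}

#' Per-locus diversity and neutrality table
#'
#' Convenience wrapper producing one row per locus plus one for the
#' concatenate: diversity summary, Tajima's D, and (when an outgroup is
#' supplied) Fu & Li's D and F.
#'
#' @param profiles Profile table with STs assigned.
#' @param library Allele library.
#' @param outgroup Optional named character vector, one aligned sequence
#'   per locus, used to polarise the Fu & Li tests.
#' @param loci Locus columns.
#' @return Tibble with one row per locus and one `concatenate` row
#'   (Fu & Li columns `NA` there and wherever preconditions fail).
#' @export
neutrality_scan <- function(profiles, library, outgroup = NULL,
                            loci = detect_loci(profiles)) {
  loci <- sort(loci)
  reps <- st_representatives(profiles)
  per_locus <- purrr::map_dfr(loci, function(loc) {
    seqs <- vapply(seq_len(nrow(reps)), function(i) {
      library$seq[library$locus == loc & library$allele == reps[[loc]][i]]
    }, character(1))
    m <- site_matrix(setNames(seqs, paste0("ST", reps$ST)))
    row <- dplyr::bind_cols(tibble(sequence = loc), diversity_summary(m))
    row$tajima_D <- tryCatch(tajima_d(m), error = function(e) NA_real_)
    if (!is.null(outgroup) && loc %in% names(outgroup)) {
      fl <- tryCatch(fu_li_df(m, outgroup[[loc]]), error = function(e) NULL)
      row$fu_li_D <- if (is.null(fl)) NA_real_ else fl$D
      row$fu_li_F <- if (is.null(fl)) NA_real_ else fl$F
    } else {
      row$fu_li_D <- NA_real_
      row$fu_li_F <- NA_real_
    }
    row
  })
  mcat <- concatenate_sts(profiles, library, loci = loci)
  cat_row <- dplyr::bind_cols(tibble(sequence = "concatenate"),
                              diversity_summary(mcat))
  cat_row$tajima_D <- tryCatch(tajima_d(mcat), error = function(e) NA_real_)
  cat_row$fu_li_D <- NA_real_
  cat_row$fu_li_F <- NA_real_
  dplyr::bind_rows(per_locus, cat_row)
}
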