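profile_mismatch_total <- function(prof_mat) {
  # sum over loci of pairwise allele-mismatch indicator matrices
  n <- nrow(prof_mat)
  total <- matrix(0, n, n)
  for (j in seq_len(ncol(prof_mat))) {
    total <- total + outer(prof_mat[, j], prof_mat[, j], "!=")
  }
  total
}

ias_from_mismatch <- function(total_mismatch, prof_mat) {
  n <- nrow(prof_mat)
  l <- ncol(prof_mat)
  pairs <- total_mismatch[upper.tri(total_mismatch)]
  V_D <- mean(pairs^2) - mean(pairs)^2  # population (biased) variance
  h <- vapply(seq_len(l), function(j) {
    p <- table(prof_mat[, j]) / n
    (n / (n - 1)) * (1 - sum(p^2))  # unbiased single-locus diversity
  }, numeric(1))
  V_e <- sum(h * (1 - h))
  list(V_D = V_D, V_e = V_e, h = h)
}

#' Standardized index of association (I_A^S)
#'
#' Linkage-disequilibrium statistic on allelic profiles (one
#' representative per ST): the pairwise distance is the number of loci
#' with differing alleles, `V_D` its observed population variance over
#' all pairs, `V_e` the variance expected under linkage equilibrium
#' (\eqn{\sum_j h_j (1 - h_j)} with \eqn{h_j} the unbiased single-locus
#' diversity), and
#' \eqn{I_A^S = (V_D/V_e - 1)/(l - 1)}.  Values significantly above 0
#' indicate clonality.
#'
#' @param profiles Profile table; reduced internally to one
#'   representative per ST when an `ST` column is present.
#' @param loci Locus columns.
#' @return One-row tibble: `n`, `l`, `V_D`, `V_e`, `ias`.
#' @export
ias <- function(profiles, loci = detect_loci(profiles)) {
  profiles <- as_tibble(profiles)
  if ("ST" %in% names(profiles)) profiles <- st_representatives(profiles)
  n <- nrow(profiles)
  l <- length(loci)
  if (n < 3L) abort("I_A^S needs at least 3 STs")
  if (l < 2L) abort("I_A^S needs at least 2 loci")
  prof_mat <- as.matrix(profiles[loci])
  if (all(apply(prof_mat, 2, function(x) length(unique(x)) == 1L))) {
    abort("monomorphic input: no polymorphic locus")
  }
  total <- profile_mismatch_total(prof_mat)
  parts <- ias_from_mismatch(total, prof_mat)
  if (parts$V_e == 0) abort("monomorphic input: V_e = 0")
  tibble(n = n, l = l, V_D = parts$V_D, V_e = parts$V_e,
         ias = (parts$V_D / parts$V_e - 1) / (l - 1))
}

#' Permutation test for the standardized index of association
#'
#' The null distribution is generated by independently permuting the
#' allele column of each locus across STs (which preserves single-locus
#' diversities and hence `V_e`); the one-sided upper-tail p-value is
#' \eqn{(1 + \#\{V_D^* \ge V_D\})/(1 + permutations)} since clonality
#' inflates `V_D`.
#'
#' @inheritParams ias
#' @param permutations Number of permutations (default 1000; fewer than
#'   100 triggers a warning).
#' @param seed Optional integer seed.
#' @return An object of class `ias_test`: the observed statistic row,
#'   `p_value`, `permutations`, and the null `V_D` draws.  [tidy()] and
#'   [glance()] return tibbles.
#' @export
ias_test <- function(profiles, loci = detect_loci(profiles),
                     permutations = 1000, seed = NULL) {
  if (permutations < 100) warn("fewer than 100 permutations: p-value is coarse")
  obs <- ias(profiles, loci)
  profiles <- as_tibble(profiles)
  if ("ST" %in% names(profiles)) profiles <- st_representatives(profiles)
  prof_mat <- as.matrix(profiles[loci])
  n <- nrow(prof_mat)
  if (!is.null(seed)) set.seed(seed)
  # per-locus mismatch matrices are permutation-equivariant: permuting a
  # locus column permutes rows+cols of its mismatch matrix
  mlist <- lapply(seq_len(ncol(prof_mat)), function(j) {
    outer(prof_mat[, j], prof_mat[, j], "!=") * 1
  })
  null_VD <- vapply(seq_len(permutations), function(b) {
    total <- matrix(0, n, n)
    for (j in seq_along(mlist)) {
      p <- sample.int(n)
      total <- total + mlist[[j]][p, p]
    }
    pairs <- total[upper.tri(total)]
    mean(pairs^2) - mean(pairs)^2
  }, numeric(1))
  p <- (1 + sum(null_VD >= obs$V_D)) / (1 + permutations)
  structure(list(observed = obs, p_value = p, permutations = permutations,
                 null_V_D = null_VD),
            class = "ias_test")
}

#' @export
tidy.ias_test <- function(x, ...) {
  dplyr::bind_cols(x$observed,
                   tibble(p_value = x$p_value, permutations = x$permutations))
}

#' @export
glance.ias_test <- function(x, ...) tidy(x)

#' @export
print.ias_test <- function(x, ...) {
  cat("Standardized index of association\n")
  cat(sprintf("  n = %d STs, l = %d loci\n", x$observed$n, x$observed$l))
  cat(sprintf("  I_A^S = %.4f  (V_D = %.4f, V_e = %.4f)\n",
              x$observed$ias, x$observed$V_D, x$observed$V_e))
  cat(sprintf("  p = %.4g (%d permutations, upper tail)\n",
              x$p_value, x$permutations))
  invisible(x)
}
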