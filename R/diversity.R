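#' Pairwise nucleotide difference counts
#'
#' Number of differing sites for every pair of rows of a site matrix,
#' computed from exact integer counts (no missing states allowed).
#'
#' @param m Site matrix (see [site_matrix()]).
#' @return An `n x n` symmetric integer matrix of pairwise difference counts.
#' @export
pairwise_diffs <- function(m) {
  if (any(m == "N")) abort("missing states not allowed in diversity statistics")
  n <- nrow(m)
  L <- ncol(m)
  shared <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    x <- (m == b) * 1
    shared <- shared + tcrossprod(x)
  }
  d <- L - shared
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  round(d)
}

#' Nucleotide diversity summary of an alignment
#'
#' Computes the segregating-site count S, the percentage of variable
#' sites, the per-site nucleotide diversity \eqn{\pi} (mean pairwise
#' difference over all pairs, in %), its standard deviation from Nei's
#' (1987, eq. 10.7) total sampling variance, the maximal diversity
#' \eqn{\pi_{MAX}} (per-site difference between the two most divergent
#' sequences, in %), and the sampling diagnostic ratio
#' \eqn{\pi_{MAX}/\pi}.  All pair arithmetic is done on exact difference
#' counts before division.
#'
#' @param m Site matrix with at least two rows (one representative per ST).
#' @return A one-row tibble: `n`, `L`, `S`, `pct_variable`, `pi`, `pi_sd`,
#'   `pi_max` (all percentages in percent units) and `ratio`
#'   (`pi_max/pi`, `NA` when `pi` is 0).
#' @export
#' @examples
#' m <- site_matrix(c(a = "AAAAAAAAAA", b = "AAAAAAAAAT", c = "AAAAAAAATT"))
#' diversity_summary(m)
diversity_summary <- function(m) {
  n <- nrow(m)
  if (n < 2L) abort("insufficient sequences (n >= 2 required)")
  L <- ncol(m)
  d <- pairwise_diffs(m)
  pairs <- d[upper.tri(d)]
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1L))
  pi <- mean(pairs) / L
  pi_max <- max(pairs) / L
  # Nei 1987 eq 10.7: total variance of pi-hat under no recombination
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  tibble(
    n = n, L = L, S = S,
    pct_variable = 100 * S / L,
    pi = 100 * pi,
    pi_sd = 100 * sqrt(v),
    pi_max = 100 * pi_max,
    ratio = if (pi > 0) pi_max / pi else NA_real_
  )
}

#' Subsampling robustness experiment
#'
#' Recomputes the diversity summary on random subsamples of k STs drawn
#' without replacement, to probe which statistics are stable in the
#' sample size (the percentage of variable sites is not; \eqn{\pi} and
#' \eqn{\pi_{MAX}} largely are).
#'
#' @param m Site matrix, one row per ST.
#' @param k Subsample size (`k <= nrow(m)`).
#' @param replicates Number of random subsamples (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of per-replicate diversity summaries (column
#'   `replicate` first) of class `subsample_result`; [glance()] gives the
#'   mean and SD of each statistic.
#' @export
subsample_experiment <- function(m, k, replicates = 1000, seed = NULL) {
  n <- nrow(m)
  if (k > n) abort("subsample size k exceeds the number of STs")
  if (!is.null(seed)) set.seed(seed)
  out <- purrr::map_dfr(seq_len(replicates), function(r) {
    idx <- sample.int(n, k, replace = FALSE)
    dplyr::bind_cols(tibble(replicate = r), diversity_summary(m[idx, , drop = FALSE]))
  })
  class(out) <- c("subsample_result", class(out))
  out
}

#' @export
glance.subsample_result <- function(x, ...) {
  stats_cols <- c("S", "pct_variable", "pi", "pi_max", "ratio")
  x %>%
    as_tibble() %>%
    tidyr::pivot_longer(dplyr::all_of(stats_cols),
                        names_to = "statistic", values_to = "value") %>%
    dplyr::group_by(.data$statistic) %>%
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
}

#' Screen for outlier STs inflating the pi_MAX/pi ratio
#'
#' Greedy removal of the ST whose deletion most reduces
#' \eqn{\pi_{MAX}}, repeated while the ratio exceeds the threshold.
#' Ratios between roughly 2 and 6 are typical of single coherent
#' populations; ratios of 8 and above flag chimeric sequences or mixed
#' lineages, and drop back once the offending STs are removed.
#'
#' @param m Site matrix, one row per ST (`n >= 3`).
#' @param ratio_threshold Ratio above which removal continues (default 8).
#' @param max_removals Safety cap (default `nrow(m) - 2`).
#' @return Tibble of removal steps: `removed`, `pi_max_before`,
#'   `ratio_before`, `pi_max_after`, `ratio_after`.  Empty when the input
#'   ratio is already below threshold or no removal reduces
#'   \eqn{\pi_{MAX}}.
#' @export
outlier_screen <- function(m, ratio_threshold = 8, max_removals = nrow(m) - 2L) {
  if (nrow(m) < 3L) abort("outlier screen needs at least 3 sequences")
  steps <- list()
  cur <- m
  for (step in seq_len(max_removals)) {
    s <- diversity_summary(cur)
    if (is.na(s$ratio) || s$ratio <= ratio_threshold) break
    reductions <- vapply(seq_len(nrow(cur)), function(i) {
      s$pi_max - diversity_summary(cur[-i, , drop = FALSE])$pi_max
    }, numeric(1))
    if (max(reductions) <= 0) break
    drop_i <- which.max(reductions)
    after <- diversity_summary(cur[-drop_i, , drop = FALSE])
    steps[[step]] <- tibble(
      removed = rownames(cur)[drop_i],
      pi_max_before = s$pi_max, ratio_before = s$ratio,
      pi_max_after = after$pi_max, ratio_after = after$ratio
    )
    cur <- cur[-drop_i, , drop = FALSE]
  }
  if (length(steps) == 0L) {
    return(tibble(removed = character(), pi_max_before = numeric(),
                  ratio_before = numeric(), pi_max_after = numeric(),
                  ratio_after = numeric()))
  }
  dplyr::bind_rows(steps)
}
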