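#' Build a binary band matrix from fragment-size lists
#'
#' Fragment sizes (kb) from all strains are pooled and clustered into
#' band classes by single linkage: consecutive sorted sizes join one
#' class while their relative difference (|a-b| / mean) stays within
#' `tolerance`.  Each strain is then scored present/absent per class.
#' An already-binary matrix passes through unchanged.
#'
#' @param patterns Either a binary matrix (strains x bands) or a tibble
#'   with columns `strain` and `sizes` (list-column of numeric kb).
#' @param tolerance Relative size-match tolerance (default 0.015).
#' @return Binary matrix, rows = strains, columns = band classes named
#'   by their median size; attribute `classes` maps class to size range.
#' @export
band_matrix <- function(patterns, tolerance = 0.015) {
  if (is.matrix(patterns)) {
    stopifnot(all(patterns %in% c(0, 1)))
    return(patterns)
  }
  patterns <- as_tibble(patterns)
  stopifnot(all(c("strain", "sizes") %in% names(patterns)))
  sizes <- unlist(patterns$sizes)
  if (any(sizes <= 0)) abort("fragment sizes must be positive")
  u <- sort(unique(sizes))
  if (length(u) == 0L) abort("no fragment sizes supplied")
  rel_gap <- abs(diff(u)) / ((u[-1] + u[-length(u)]) / 2)
  cls <- cumsum(c(1, rel_gap > tolerance))
  class_of <- setNames(cls, as.character(u))
  class_median <- tapply(u, cls, stats::median)
  k <- max(cls)
  m <- matrix(0L, nrow(patterns), k,
              dimnames = list(patterns$strain,
                              sprintf("band_%g", class_median)))
  for (i in seq_len(nrow(patterns))) {
    s <- patterns$sizes[[i]]
    ci <- class_of[as.character(s)]
    if (anyDuplicated(ci)) {
      dup <- unique(ci[duplicated(ci)])
      abort(paste0("ambiguous band classes for strain ", patterns$strain[i],
                   ": sizes ", paste(s[ci %in% dup], collapse = ", "),
                   " fall in one class at tolerance ", tolerance))
    }
    m[i, ci] <- 1L
  }
  attr(m, "classes") <- tibble(class = seq_len(k),
                               median_kb = as.numeric(class_median))
  m
}

#' Dice similarity of macrorestriction fingerprints
#'
#' \eqn{S_D = 2 n_{AB} / (n_A + n_B)} over shared band classes; the
#' genomic distance is \eqn{1 - S_D}.  Pairs with \eqn{S_D < 0.6} are
#' conventionally labelled unrelated strains.
#'
#' @param m Binary band matrix (see [band_matrix()]).
#' @return Object of class `dice_matrix`: list with `similarity` and
#'   `distance` matrices.  [tidy()] gives a long pair tibble with an
#'   `unrelated` flag (`S_D < 0.6`).
#' @export
dice_matrix <- function(m) {
  if (nrow(m) < 2L) abort("need at least 2 strains")
  nb <- rowSums(m)
  if (any(nb == 0)) {
    abort(paste0("strain(s) with zero bands: ",
                 paste(rownames(m)[nb == 0], collapse = ", ")))
  }
  shared <- tcrossprod(m)
  sd_mat <- 2 * shared / outer(nb, nb, "+")
  diag(sd_mat) <- 1
  structure(list(similarity = sd_mat, distance = 1 - sd_mat),
            class = "dice_matrix")
}

#' @export
tidy.dice_matrix <- function(x, ...) {
  s <- x$similarity
  idx <- which(upper.tri(s), arr.ind = TRUE)
  tibble(strain_a = rownames(s)[idx[, 1]],
         strain_b = colnames(s)[idx[, 2]],
         S_D = s[idx],
         distance = 1 - s[idx],
         unrelated = s[idx] < 0.6)
}

#' UPGMA dendrogram with band-resampling bootstrap
#'
#' Average-linkage clustering on the Dice distance 1 - S_D; band-class
#' columns are resampled with replacement per replicate (the character
#' resampling convention of fingerprint bootstrap programs) and each
#' internal node's support is the percentage of replicates reproducing
#' its cluster.
#'
#' @param m Binary band matrix.
#' @param replicates Bootstrap replicates (>= 100).
#' @param seed Optional integer seed.
#' @return List with `tree` (ultrametric `phylo`, `node.label` =
#'   support %) and `support`.
#' @export
upgma_bootstrap <- function(m, replicates = 1000, seed = NULL) {
  if (replicates < 100) abort("use at least 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  upgma_of <- function(mat) {
    d <- dice_matrix(mat)$distance
    ape::as.phylo(hclust(as.dist(d), method = "average"))
  }
  ref <- upgma_of(m)
  boots <- lapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncol(m), replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    mb <- mb[, colSums(mb) > 0, drop = FALSE]
    ok <- rowSums(mb) > 0
    if (!all(ok) || ncol(mb) == 0L) return(NULL)  # degenerate resample
    upgma_of(mb)
  })
  boots <- boots[!vapply(boots, is.null, logical(1))]
  counts <- ape::prop.clades(ref, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / length(boots)
  ref$node.label <- round(support, 1)
  list(tree = ref, support = support)
}

#' Chromosome and genome size from digest fragment sums
#'
#' The chromosome size of each strain is the mean over digests of the
#' summed restriction-fragment sizes, with an uncertainty of half the
#' range across digests (0 with a single digest); the genome size adds
#' the summed sizes of S1-linearised plasmids.
#'
#' @param digests Tibble with columns `strain`, `digest`, `size_kb`
#'   (one row per fragment).
#' @param plasmids Optional tibble `strain`, `size_kb` (one row per
#'   plasmid).
#' @return Tibble per strain: `chromosome_kb`, `uncertainty_kb`,
#'   `n_digests`, `plasmids_kb`, `genome_kb`.
#' @export
#' @examples
#' digests <- tibble::tibble(strain = "X", digest = rep(c("SmaI", "CeuI_NotI"), 2),
#'                           size_kb = c(1200, 1222, 1200, 1200))
#' genome_size(digests)
genome_size <- function(digests, plasmids = NULL) {
  digests <- as_tibble(digests)
  stopifnot(all(c("strain", "digest", "size_kb") %in% names(digests)))
  if (nrow(digests) == 0L) abort("empty fragment list")
  sums <- digests %>%
    dplyr::group_by(.data$strain, .data$digest) %>%
    dplyr::summarise(total_kb = sum(.data$size_kb), .groups = "drop")
  chrom <- sums %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(chromosome_kb = mean(.data$total_kb),
                     uncertainty_kb = (max(.data$total_kb) - min(.data$total_kb)) / 2,
                     n_digests = dplyr::n(), .groups = "drop")
  plas <- if (is.null(plasmids) || nrow(plasmids) == 0L) {
    tibble(strain = chrom$strain, plasmids_kb = 0)
  } else {
    as_tibble(plasmids) %>%
      dplyr::group_by(.data$strain) %>%
      dplyr::summarise(plasmids_kb = sum(.data$size_kb), .groups = "drop")
  }
  chrom %>%
    dplyr::left_join(plas, by = "strain") %>%
    dplyr::mutate(plasmids_kb = dplyr::coalesce(.data$plasmids_kb, 0),
                  genome_kb = .data$chromosome_kb + .data$plasmids_kb)
}

#' Genome-feature association tests
#'
#' Spearman rank correlations of plasmid content against genome and
#' chromosome size, and rank-sum comparisons of sizes between origin
#' classes (exact p for small samples via the base test machinery,
#' normal approximation otherwise; Kruskal-Wallis when more than two
#' classes are present).
#'
#' @param data Tibble with columns `strain`, `chromosome_kb`,
#'   `plasmid_kb`, `origin`, and optionally `genome_kb` (computed as the
#'   sum when absent).
#' @return Tibble: `test`, `variables`, `estimate`, `p_value`, `note`.
#' @export
feature_associations <- function(data) {
  data <- as_tibble(data)
  stopifnot(all(c("chromosome_kb", "plasmid_kb", "origin") %in% names(data)))
  if (nrow(data) < 5L) abort("need at least 5 strains")
  if (!"genome_kb" %in% names(data)) {
    data$genome_kb <- data$chromosome_kb + data$plasmid_kb
  }
  rows <- list()
  spearman <- function(x, y, label) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble(test = "spearman", variables = label,
                    estimate = NA_real_, p_value = NA_real_,
                    note = "a variable is constant; correlation undefined"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    tibble(test = "spearman", variables = label,
           estimate = unname(ct$estimate), p_value = ct$p.value, note = "")
  }
  rows$sp1 <- spearman(data$plasmid_kb, data$genome_kb, "plasmid_kb ~ genome_kb")
  rows$sp2 <- spearman(data$plasmid_kb, data$chromosome_kb, "plasmid_kb ~ chromosome_kb")
  classes <- unique(data$origin)
  if (length(classes) < 2L) {
    rows$rs <- tibble(test = "rank_sum", variables = "sizes ~ origin",
                      estimate = NA_real_, p_value = NA_real_,
                      note = "single origin class; comparison skipped")
  } else {
    for (v in c("chromosome_kb", "plasmid_kb", "genome_kb")) {
      if (length(classes) == 2L) {
        wt <- suppressWarnings(
          wilcox.test(data[[v]][data$origin == classes[1]],
                      data[[v]][data$origin == classes[2]]))
        rows[[v]] <- tibble(test = "mann_whitney",
                            variables = paste0(v, " ~ origin"),
                            estimate = unname(wt$statistic),
                            p_value = wt$p.value, note = "")
      } else {
        kt <- kruskal.test(data[[v]], factor(data$origin))
        rows[[v]] <- tibble(test = "kruskal_wallis",
                            variables = paste0(v, " ~ origin"),
                            estimate = unname(kt$statistic),
                            p_value = kt$p.value,
                            note = "more than two origin classes")
      }
    }
  }
  dplyr::bind_rows(rows)
}
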