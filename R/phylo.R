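purine <- c("A", "G")

#' Kimura two-parameter distance between two aligned sequences
#'
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)} with P
#' and Q the transition and transversion proportions over the sites
#' retained after pairwise deletion of missing states.
#'
#' @param a,b Aligned sequences (strings or character vectors of states).
#' @return The K2P distance (substitutions/site).
#' @export
#' @examples
#' k2p("ACGT", "ACGT")
k2p <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) abort("sequences differ in length")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  L <- length(a)
  if (L == 0L) abort("no comparable sites after pairwise deletion")
  diff <- a != b
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) abort("saturated distance")
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' K2P distance matrix for a site matrix
#'
#' Wraps [ape::dist.dna()] (model `"K80"`, pairwise deletion) on the
#' alignment; agrees with [k2p()] applied pair by pair.
#'
#' @param m Site matrix.
#' @return A symmetric `dist`-convertible matrix with row labels.
#' @export
k2p_matrix <- function(m) {
  bin <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration via [ape::nj()].  Negative branch
#' lengths (an NJ artefact) are clamped to zero for display; the raw
#' lengths are kept in the `raw_edge_length` attribute.
#'
#' @param d Symmetric distance matrix (>= 3 labels) or `dist`.
#' @param quiet Suppress the clamping message (used for bootstrap
#'   replicates).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, quiet = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(d))
  raw <- tr$edge.length
  if (any(raw < 0)) {
    if (!quiet) message(sum(raw < 0), " negative NJ branch length(s) clamped to 0")
    tr$edge.length <- pmax(raw, 0)
  }
  attr(tr, "raw_edge_length") <- raw
  tr
}

#' Bootstrap neighbor-joining tree on an alignment
#'
#' Builds the reference K2P + NJ tree, then resamples alignment columns
#' with replacement `replicates` times; the support of an internal edge
#' is the percentage of replicates containing the same bipartition,
#' stored in `node.label`.
#'
#' @param m Site matrix.
#' @param replicates Bootstrap replicates (>= 100).
#' @param seed Optional integer seed.
#' @return List with `tree` (reference `phylo`, `node.label` = support
#'   %) and `support` (numeric vector over internal nodes).
#' @export
bootstrap_tree <- function(m, replicates = 1000, seed = NULL) {
  if (replicates < 100) abort("use at least 100 bootstrap replicates")
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(k2p_matrix(m))
  boots <- lapply(seq_len(replicates), function(b) {
    cols <- sample.int(ncol(m), replace = TRUE)
    nj_tree(k2p_matrix(m[, cols, drop = FALSE]), quiet = TRUE)
  })
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / replicates
  ref$node.label <- round(support, 1)
  list(tree = ref, support = support)
}

#' Write a tree with supports as Newick
#'
#' @param tree A `phylo` tree (support values in `node.label`).
#' @param path File path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
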