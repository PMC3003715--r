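shared_loci_matrix <- function(prof_mat) {
  l <- ncol(prof_mat)
  l - profile_mismatch_total(prof_mat)
}

#' eBURST-style clonal complex inference
#'
#' Builds the single-locus-variant (SLV) graph over STs (pairs sharing
#' all but one locus), takes its connected components of size >= 2 as
#' clonal complexes, and predicts each complex's founder as the ST with
#' the highest SLV degree; ties are broken by double-locus-variant (DLV)
#' degree, then isolate count, then lowest ST id, with the tie-break
#' path recorded.
#'
#' @param profiles Profile table with `ST` assigned (isolate counts per
#'   ST are taken from the full table).
#' @param loci Locus columns.
#' @return An object of class `eburst` with elements `nodes` (tibble:
#'   `ST`, `n_isolates`, `slv_degree`, `dlv_degree`, `complex` — `NA`
#'   for singletons — and `founder`), `edges` (tibble `from`, `to`,
#'   `type` in slv/dlv), and `complexes` (tibble `complex`, `n_st`,
#'   `n_isolates`, `founder`, `tie_break`).  [tidy()] returns the nodes.
#' @export
eburst <- function(profiles, loci = detect_loci(profiles)) {
  profiles <- as_tibble(profiles)
  stopifnot("ST" %in% names(profiles))
  counts <- dplyr::count(profiles, .data$ST, name = "n_isolates")
  reps <- st_representatives(profiles)
  prof_mat <- as.matrix(reps[loci])
  sts <- reps$ST
  l <- length(loci)
  shared <- shared_loci_matrix(prof_mat)
  pair_idx <- which(upper.tri(shared), arr.ind = TRUE)
  edge_type <- shared[upper.tri(shared)]
  edges <- tibble(
    from = sts[pair_idx[, 1]], to = sts[pair_idx[, 2]],
    shared = edge_type
  ) %>%
    dplyr::filter(.data$shared >= l - 2L) %>%
    dplyr::mutate(type = ifelse(.data$shared == l - 1L, "slv", "dlv")) %>%
    dplyr::select("from", "to", "type")

  slv_edges <- edges[edges$type == "slv", ]
  g <- igraph::graph_from_data_frame(
    slv_edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = as.character(sts))
  )
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(sts)]
  comp_sizes <- table(membership)
  in_complex <- comp_sizes[as.character(membership)] >= 2

  slv_deg <- igraph::degree(g)[as.character(sts)]
  dlv_deg <- vapply(as.character(sts), function(s) {
    sum((edges$from == as.integer(s) | edges$to == as.integer(s)) &
          edges$type == "dlv")
  }, numeric(1))

  nodes <- tibble(
    ST = sts,
    n_isolates = counts$n_isolates[match(sts, counts$ST)],
    slv_degree = as.integer(slv_deg),
    dlv_degree = as.integer(dlv_deg),
    complex = as.integer(ifelse(in_complex, unname(membership), NA_integer_))
  )
  # renumber complexes by decreasing ST count (CC1 = largest), ties by
  # smallest member ST
  if (any(!is.na(nodes$complex))) {
    cc_order <- nodes %>%
      dplyr::filter(!is.na(.data$complex)) %>%
      dplyr::group_by(.data$complex) %>%
      dplyr::summarise(n_st = dplyr::n(), min_st = min(.data$ST), .groups = "drop") %>%
      dplyr::arrange(dplyr::desc(.data$n_st), .data$min_st)
    remap <- setNames(seq_len(nrow(cc_order)), cc_order$complex)
    nodes$complex <- as.integer(remap[as.character(nodes$complex)])
  }

  empty_complexes <- tibble(complex = integer(), n_st = integer(),
                            n_isolates = integer(), founder = integer(),
                            tie_break = character())
  complexes <- if (all(is.na(nodes$complex))) empty_complexes else nodes %>%
    dplyr::filter(!is.na(.data$complex)) %>%
    dplyr::group_by(.data$complex) %>%
    dplyr::group_modify(function(members, key) {
      ord <- order(-members$slv_degree, -members$dlv_degree,
                   -members$n_isolates, members$ST)
      top <- members[ord[1], ]
      tie_break <- "slv_degree"
      same_slv <- members$slv_degree == top$slv_degree
      if (sum(same_slv) > 1) {
        tie_break <- "dlv_degree"
        same_dlv <- same_slv & members$dlv_degree == top$dlv_degree
        if (sum(same_dlv) > 1) {
          tie_break <- "isolate_count"
          same_iso <- same_dlv & members$n_isolates == top$n_isolates
          if (sum(same_iso) > 1) tie_break <- "lowest_st_id"
        }
      }
      tibble(n_st = nrow(members), n_isolates = sum(members$n_isolates),
             founder = top$ST, tie_break = tie_break)
    }) %>%
    dplyr::ungroup()

  nodes$founder <- !is.na(nodes$complex) &
    nodes$ST == complexes$founder[match(nodes$complex, complexes$complex)]

  structure(list(nodes = nodes, edges = edges, complexes = complexes,
                 loci = loci),
            class = "eburst")
}

#' @export
tidy.eburst <- function(x, ...) x$nodes

#' @export
glance.eburst <- function(x, ...) {
  tibble(n_st = nrow(x$nodes),
         n_complexes = nrow(x$complexes),
         n_singletons = sum(is.na(x$nodes$complex)),
         largest_cc = if (nrow(x$complexes)) max(x$complexes$n_st) else 0L)
}

#' @export
print.eburst <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("eBURST: %d STs -> %d clonal complexes, %d singletons\n",
              g$n_st, g$n_complexes, g$n_singletons))
  if (nrow(x$complexes)) print(x$complexes)
  invisible(x)
}

#' Relax clonal-complex definition to double-locus variants
#'
#' Recomputes groups as connected components over the union of the SLV
#' and DLV relations and reports only the change relative to the SLV
#' grouping: the newly formed groups that merge STs which were not in a
#' common SLV complex.
#'
#' @param x An [eburst()] result.
#' @return Tibble `group`, `ST`, `slv_complex` listing only the merged
#'   groups (empty when relaxation changes nothing).
#' @export
relax_to_dlv <- function(x) {
  stopifnot(inherits(x, "eburst"))
  sts <- x$nodes$ST
  g <- igraph::graph_from_data_frame(
    x$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = as.character(sts))
  )
  memb <- unname(igraph::components(g)$membership[as.character(sts)])
  out <- tibble(ST = sts, group = as.integer(memb),
                slv_complex = x$nodes$complex)
  changed <- out %>%
    dplyr::group_by(.data$group) %>%
    dplyr::filter(dplyr::n() >= 2L) %>%
    # a group is "new" unless it coincides with an existing SLV complex
    dplyr::filter(dplyr::n_distinct(.data$slv_complex) > 1L |
                    anyNA(.data$slv_complex)) %>%
    dplyr::ungroup()
  if (nrow(changed) == 0L) {
    return(tibble(group = integer(), ST = integer(), slv_complex = integer()))
  }
  changed$group <- as.integer(factor(changed$group, levels = unique(changed$group)))
  dplyr::arrange(changed[, c("group", "ST", "slv_complex")], .data$group, .data$ST)
}

#' Per-site recombination vs mutation (r/m) classification
#'
#' For each SLV of a complex founder, compares the variant allele with
#' the founder allele at the single differing locus.  The SNPs are
#' counted as a point mutation (m) only when the alleles differ by
#' exactly one SNP, the variant allele sequence occurs in no ST outside
#' the complex, and the variant nucleotide at that site occurs in no
#' other allele of the locus; otherwise all differing sites are counted
#' as recombinant (r), either because the allele differs by several SNPs
#' or because the variant is found in unrelated STs.  The per-site ratio
#' r/m summarises the relative contribution of recombination.
#'
#' @param x An [eburst()] result.
#' @param complex Complex id (e.g. 1 for CC1).
#' @param profiles Profile table with `ST` assigned.
#' @param library Allele library.
#' @return Object of class `rm_classification`: `events` tibble (`ST`,
#'   `locus`, `founder_allele`, `variant_allele`, `snp_count`, `class`,
#'   `evidence`), totals `m` and `r`, and `rm_ratio` (`NA` with note when
#'   m = 0).  [tidy()] returns the events, [glance()] the totals.
#' @export
rm_classify <- function(x, complex, profiles, library) {
  stopifnot(inherits(x, "eburst"))
  loci <- x$loci
  cc <- x$complexes[x$complexes$complex == complex, ]
  if (nrow(cc) != 1L) abort(paste0("no complex ", complex))
  founder_st <- cc$founder
  members <- x$nodes$ST[!is.na(x$nodes$complex) & x$nodes$complex == complex]
  reps <- st_representatives(profiles)
  founder_prof <- reps[reps$ST == founder_st, loci]
  outside_sts <- setdiff(reps$ST, members)

  allele_seq <- function(loc, a) {
    s <- library$seq[library$locus == loc & library$allele == a]
    if (length(s) != 1L) abort(paste0("unresolvable allele ", a, " at ", loc))
    s
  }
  # SLVs of the founder only
  slv_edges <- x$edges[x$edges$type == "slv" &
                         (x$edges$from == founder_st | x$edges$to == founder_st), ]
  slv_sts <- setdiff(unique(c(slv_edges$from, slv_edges$to)), founder_st)
  events <- purrr::map_dfr(slv_sts, function(st) {
    prof <- reps[reps$ST == st, loci]
    diff_loci <- loci[as.integer(prof) != as.integer(founder_prof)]
    if (length(diff_loci) != 1L) {
      abort(paste0("ST", st, " is not an SLV of the founder (differs at ",
                   length(diff_loci), " loci)"))
    }
    loc <- diff_loci
    fa <- founder_prof[[loc]]
    va <- prof[[loc]]
    fs <- strsplit(allele_seq(loc, fa), "")[[1]]
    vs <- strsplit(allele_seq(loc, va), "")[[1]]
    sites <- which(fs != vs)
    snp_count <- length(sites)
    # evidence level 1: exact variant allele in an ST outside the complex
    outside_alleles <- reps[[loc]][reps$ST %in% outside_sts]
    allele_elsewhere <- va %in% outside_alleles
    # evidence level 2: variant nucleotide at that site in another allele
    nt_elsewhere <- FALSE
    if (snp_count == 1L) {
      other <- library[library$locus == loc & library$allele != va, ]
      nt_elsewhere <- any(substr(other$seq, sites, sites) == vs[sites])
    }
    if (snp_count == 1L && !allele_elsewhere && !nt_elsewhere) {
      cls <- "mutation"
      ev <- "single private SNP"
    } else {
      cls <- "recombination"
      ev <- paste(c(
        if (snp_count > 1L) paste0(snp_count, " SNPs"),
        if (allele_elsewhere) "variant allele found in unrelated ST",
        if (nt_elsewhere) "variant nucleotide present in another allele"
      ), collapse = "; ")
    }
    tibble(ST = st, locus = loc, founder_allele = fa, variant_allele = va,
           snp_count = snp_count, class = cls, evidence = ev,
           snp_sites = list(sites))
  })
  m <- sum(events$snp_count[events$class == "mutation"])
  r <- sum(events$snp_count[events$class == "recombination"])
  structure(list(complex = complex, founder = founder_st, events = events,
                 m = m, r = r,
                 rm_ratio = if (m > 0) r / m else NA_real_),
            class = "rm_classification")
}

#' @export
tidy.rm_classification <- function(x, ...) x$events

#' @export
glance.rm_classification <- function(x, ...) {
  tibble(complex = x$complex, founder = x$founder,
         allelic_changes = nrow(x$events),
         snps = x$m + x$r, m = x$m, r = x$r, rm_ratio = x$rm_ratio)
}

#' @export
print.rm_classification <- function(x, ...) {
  cat(sprintf("r/m classification for complex %s (founder ST%d)\n",
              x$complex, x$founder))
  cat(sprintf("  %d allelic changes, %d SNPs: m = %d, r = %d",
              nrow(x$events), x$m + x$r, x$m, x$r))
  if (is.na(x$rm_ratio)) cat("  (ratio r:0, no mutations)\n")
  else cat(sprintf("  -> r/m = %.3g\n", x$rm_ratio))
  invisible(x)
}
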