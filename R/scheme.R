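#' ST resolution of a locus subset
#'
#' Counts the distinct allelic profiles obtained when typing is
#' restricted to a subset of loci — the resolution a reduced scheme
#' would achieve.  Adding a locus can never decrease the count.
#'
#' @param profiles Profile table (isolate level).
#' @param subset Character vector of locus columns.
#' @return One-row tibble: `loci` (comma-joined, sorted), `n_loci`,
#'   `st_count`, and `alleles_per_locus` (list-column of named counts).
#' @export
st_resolution <- function(profiles, subset) {
  profiles <- as_tibble(profiles)
  if (length(subset) == 0L) abort("subset must contain at least one locus")
  missing <- setdiff(subset, names(profiles))
  if (length(missing)) {
    abort(paste0("unknown locus/loci: ", paste(missing, collapse = ", ")))
  }
  subset <- sort(unique(subset))
  key <- do.call(paste, c(profiles[subset], sep = "/"))
  alleles <- vapply(subset, function(loc) {
    length(unique(profiles[[loc]]))
  }, integer(1))
  tibble(loci = paste(subset, collapse = ","),
         n_loci = length(subset),
         st_count = length(unique(key)),
         alleles_per_locus = list(alleles))
}

#' Backbone augmentation search for scheme design
#'
#' Evaluates the ST resolution of a backbone locus set, of every single
#' candidate addition, and of every candidate pair (exhaustively — the
#' candidate sets in scheme design are tiny), and reports the smallest
#' augmentation that reaches the maximum achievable resolution.  Ties
#' are reported, never silently broken.
#'
#' @param profiles Profile table.
#' @param backbone Character vector of backbone loci.
#' @param candidates Character vector of candidate loci to add.
#' @param max_added Largest augmentation size to search (default 2;
#'   raised automatically if pairs do not reach the full-candidate
#'   resolution).
#' @return Object of class `scheme_search`: `backbone` evaluation,
#'   `evaluations` tibble over all searched subsets (`added`,
#'   `n_added`, `st_count`, `gain`, `redundant`), `max_st_count`
#'   (resolution of backbone plus all candidates), and `best` (all
#'   minimal augmentations achieving it).  [tidy()] returns the
#'   evaluations.
#' @export
augment_backbone <- function(profiles, backbone, candidates, max_added = 2L) {
  base <- st_resolution(profiles, backbone)
  full <- st_resolution(profiles, c(backbone, candidates))
  sets <- list()
  for (k in seq_len(min(max_added, length(candidates)))) {
    combos <- combn(sort(candidates), k, simplify = FALSE)
    sets <- c(sets, combos)
  }
  evaluations <- purrr::map_dfr(sets, function(add) {
    res <- st_resolution(profiles, c(backbone, add))
    tibble(added = paste(add, collapse = "+"),
           n_added = length(add),
           st_count = res$st_count,
           gain = res$st_count - base$st_count,
           redundant = res$st_count == base$st_count)
  })
  reached <- max(c(base$st_count, evaluations$st_count))
  if (reached < full$st_count && max_added < length(candidates)) {
    return(augment_backbone(profiles, backbone, candidates,
                            max_added = max_added + 1L))
  }
  hits <- evaluations[evaluations$st_count == full$st_count, ]
  best <- if (base$st_count == full$st_count) {
    tibble(added = "", n_added = 0L, st_count = base$st_count,
           gain = 0L, redundant = TRUE)
  } else if (nrow(hits) > 0L) {
    hits[hits$n_added == min(hits$n_added), ]
  } else {
    hits
  }
  structure(list(backbone = base, evaluations = evaluations,
                 max_st_count = full$st_count, best = best),
            class = "scheme_search")
}

#' @export
tidy.scheme_search <- function(x, ...) x$evaluations

#' @export
glance.scheme_search <- function(x, ...) {
  tibble(backbone_st_count = x$backbone$st_count,
         max_st_count = x$max_st_count,
         n_minimal_augmentations = nrow(x$best),
         minimal_size = if (nrow(x$best)) x$best$n_added[1] else NA_integer_)
}

#' @export
print.scheme_search <- function(x, ...) {
  cat(sprintf("Scheme search: backbone [%s] resolves %d STs; max %d\n",
              x$backbone$loci, x$backbone$st_count, x$max_st_count))
  if (nrow(x$best)) {
    cat("Minimal augmentation(s) reaching the maximum:\n")
    print(x$best)
  }
  invisible(x)
}
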