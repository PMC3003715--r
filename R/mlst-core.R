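#' Canonical MLST loci and fragment lengths
#'
#' The six-locus scheme used throughout the package examples: internal
#' fragments of `bcaT`, `glyA`, `pdp`, `pepXP`, `pgk` and `recN`.  The
#' canonical locus order is alphabetical; concatenates built in this order
#' are 2,934 bp long.
#'
#' @return A named integer vector of fragment lengths (bp), named by locus,
#'   in canonical (alphabetical) order.
#' @export
#' @examples
#' mlst_loci()
#' sum(mlst_loci())
mlst_loci <- function() {
  c(bcaT = 516L, glyA = 453L, pdp = 492L, pepXP = 504L, pgk = 480L, recN = 489L)
}

reserved_profile_cols <- c("isolate", "ST", "origin", "markers", "lineage", "complex")

#' Detect locus columns of a profile table
#'
#' Locus columns are every column of `profiles` that is not one of the
#' reserved metadata columns (`isolate`, `ST`, `origin`, `markers`,
#' `lineage`, `complex`), kept in alphabetical (canonical) order.
#'
#' @param profiles A profile data frame.
#' @return Character vector of locus names.
#' @export
detect_loci <- function(profiles) {
  loci <- setdiff(names(profiles), reserved_profile_cols)
  sort(loci)
}

#' Create an empty allele library
#'
#' An allele library is a tibble with one row per numbered allele and
#' columns `locus`, `allele` (positive integer, unique within locus) and
#' `seq` (uppercase A/C/G/T, fixed length within a locus).
#'
#' @param library Optional tibble to validate and return.
#' @return A validated allele-library tibble.
#' @export
allele_library <- function(library = NULL) {
  if (is.null(library)) {
    library <- tibble(locus = character(), allele = integer(), seq = character())
  }
  validate_allele_library(library)
}

validate_allele_library <- function(library) {
  library <- as_tibble(library)
  stopifnot(all(c("locus", "allele", "seq") %in% names(library)))
  library$allele <- as.integer(library$allele)
  if (nrow(library) == 0L) return(library)
  if (any(library$allele < 1L)) abort("allele numbers must be positive integers")
  bad <- grepl("[^ACGT]", library$seq)
  if (any(bad)) {
    abort(paste0("non-ACGT character in allele definition: ",
                 paste(unique(library$locus[bad]), collapse = ", ")))
  }
  by_locus <- split(library, library$locus)
  for (loc in names(by_locus)) {
    tab <- by_locus[[loc]]
    if (anyDuplicated(tab$allele)) {
      abort(paste0("duplicate allele numbers at locus ", loc))
    }
    if (anyDuplicated(tab$seq)) {
      abort(paste0("two allele numbers map to identical sequences at locus ", loc))
    }
    if (length(unique(nchar(tab$seq))) > 1L) {
      abort(paste0("alleles of locus ", loc, " differ in length"))
    }
  }
  library
}

#' Assign allele numbers to locus sequences
#'
#' Exact-match sequences receive the existing allele number; novel
#' sequences receive the next unused number in first-encounter order, as
#' in MLST allele databases.  Deterministic given the input row order.
#'
#' @param calls Tibble with columns `isolate`, `locus`, `seq`.
#' @param library An allele library (see [allele_library()]); may be empty.
#' @return A list with elements `library` (updated allele library) and
#'   `assignments` (tibble `isolate`, `locus`, `allele`).
#' @export
#' @examples
#' calls <- tibble::tibble(isolate = c("s1", "s2", "s3"), locus = "locusA",
#'                         seq = c("ACGT", "ACGT", "ACCT"))
#' assign_alleles(calls)$assignments
assign_alleles <- function(calls, library = allele_library()) {
  calls <- as_tibble(calls)
  stopifnot(all(c("isolate", "locus", "seq") %in% names(calls)))
  library <- validate_allele_library(library)
  calls$seq <- unname(toupper(calls$seq))
  calls$isolate <- unname(calls$isolate)
  bad <- grepl("[^ACGT]", calls$seq)
  if (any(bad)) {
    abort(paste0("non-ACGT character (ambiguity codes are rejected) for isolate(s) ",
                 paste(calls$isolate[bad], collapse = ", "), " at locus ",
                 paste(unique(calls$locus[bad]), collapse = ", ")))
  }
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    loc <- calls$locus[i]
    s <- calls$seq[i]
    lib_loc <- library[library$locus == loc, ]
    if (nrow(lib_loc) > 0L && nchar(s) != nchar(lib_loc$seq[1])) {
      abort(paste0("sequence length mismatch for isolate ", calls$isolate[i],
                   " at locus ", loc, " (", nchar(s), " vs ",
                   nchar(lib_loc$seq[1]), " bp)"))
    }
    hit <- lib_loc$allele[lib_loc$seq == s]
    if (length(hit) == 1L) {
      out[[i]] <- hit
    } else {
      new_num <- if (nrow(lib_loc) == 0L) 1L else max(lib_loc$allele) + 1L
      library <- dplyr::bind_rows(library,
                                  tibble(locus = loc, allele = new_num, seq = s))
      out[[i]] <- new_num
    }
  }
  list(
    library = library,
    assignments = tibble(isolate = calls$isolate, locus = calls$locus,
                         allele = as.integer(unlist(out)))
  )
}

#' Assign sequence types (STs) to allelic profiles
#'
#' Isolates with identical profiles share one ST; ST ids are consecutive
#' integers in first-encounter order.  Idempotent: re-running on a table
#' that already has STs reproduces the same assignment.
#'
#' @param profiles Tibble with an `isolate` column and one integer column
#'   per locus.
#' @param loci Locus columns to use; defaults to [detect_loci()].
#' @return `profiles` with an `ST` column (first-encounter numbering).
#' @export
assign_sts <- function(profiles, loci = detect_loci(profiles)) {
  profiles <- as_tibble(profiles)
  stopifnot("isolate" %in% names(profiles), length(loci) >= 1L)
  prof_mat <- profiles[loci]
  incomplete <- !stats::complete.cases(prof_mat)
  if (any(incomplete)) {
    abort(paste0("incomplete allelic profile for isolate(s): ",
                 paste(profiles$isolate[incomplete], collapse = ", ")))
  }
  key <- do.call(paste, c(prof_mat, sep = "/"))
  profiles$ST <- as.integer(factor(key, levels = unique(key)))
  dplyr::relocate(profiles, "isolate", "ST")
}

#' One representative isolate per ST
#'
#' @param profiles A profile table with an `ST` column.
#' @return The first-encountered isolate row of each ST.
#' @export
st_representatives <- function(profiles) {
  profiles %>%
    dplyr::group_by(.data$ST) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$ST)
}

#' Concatenate per-locus allele sequences for a set of STs
#'
#' Builds the aligned site matrix of one representative per ST, columns
#' ordered by canonical locus order then position within the fragment
#' (1-based).  For the six-locus scheme the concatenate is 2,934 bp.
#'
#' @param profiles Profile table with `ST` assigned.
#' @param library Allele library resolving every (locus, allele) used.
#' @param sts Optional subset of ST ids (default: all).
#' @param loci Locus columns (canonical order enforced by sorting).
#' @return A character matrix (rows `ST<k>`, columns sites) with
#'   attribute `loci_map`, a tibble of `locus`, `start`, `end`, `length`.
#' @export
concatenate_sts <- function(profiles, library, sts = NULL,
                            loci = detect_loci(profiles)) {
  loci <- sort(loci)
  reps <- st_representatives(profiles)
  if (!is.null(sts)) reps <- reps[reps$ST %in% sts, ]
  library <- validate_allele_library(library)
  rows <- lapply(seq_len(nrow(reps)), function(i) {
    pieces <- vapply(loci, function(loc) {
      a <- reps[[loc]][i]
      s <- library$seq[library$locus == loc & library$allele == a]
      if (length(s) != 1L) {
        abort(paste0("unresolvable allele ", a, " at locus ", loc,
                     " for ST", reps$ST[i]))
      }
      s
    }, character(1))
    paste(pieces, collapse = "")
  })
  m <- site_matrix(setNames(unlist(rows), paste0("ST", reps$ST)))
  lens <- vapply(loci, function(loc) {
    nchar(library$seq[library$locus == loc][1])
  }, integer(1))
  ends <- unname(cumsum(lens))
  lens <- unname(lens)
  attr(m, "loci_map") <- tibble(locus = loci, start = ends - lens + 1L,
                                end = ends, length = lens)
  m
}

#' Build a site matrix from aligned sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#'   `-`, `.` and `N` are normalised to the missing marker `N`.
#' @return Character matrix, one row per sequence, one column per site.
#' @export
site_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("sequences are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  m[m %in% c("-", ".", "?")] <- "N"
  bad <- !(m %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) abort("site matrix states must be A/C/G/T or the missing marker N")
  rownames(m) <- names(seqs)
  m
}

#' @rdname site_matrix
#' @param m A site matrix.
#' @return `site_strings()`: named character vector of the rows.
#' @export
site_strings <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# ---- I/O ------------------------------------------------------------------

#' Read and write allele libraries as FASTA
#'
#' FASTA headers follow the `>locus_allele` convention (e.g. `>bcaT_7`).
#'
#' @param library An allele library.
#' @param path File path.
#' @return `read_allele_fasta()` returns an allele library tibble.
#' @export
write_allele_fasta <- function(library, path) {
  library <- validate_allele_library(library)
  x <- Biostrings::DNAStringSet(setNames(
    library$seq, paste0(library$locus, "_", library$allele)))
  Biostrings::writeXStringSet(x, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_allele_fasta
#' @export
read_allele_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  locus <- sub("_[0-9]+$", "", nm)
  allele <- as.integer(sub("^.*_", "", nm))
  validate_allele_library(
    tibble(locus = locus, allele = allele, seq = unname(as.character(x))) %>%
      dplyr::arrange(.data$locus, .data$allele))
}

#' Read and write profile tables as TSV
#'
#' Columns: `isolate`, `ST`, one column per locus, then optional `origin`
#' and `markers` (semicolon-separated marker-gene flags, e.g.
#' `lacE;prtP`).
#'
#' @param profiles A profile table.
#' @param path File path.
#' @return `read_profiles_tsv()` returns a profile tibble.
#' @export
write_profiles_tsv <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (loc in detect_loci(out)) out[[loc]] <- as.integer(out[[loc]])
  if ("ST" %in% names(out)) out$ST <- as.integer(out$ST)
  if ("markers" %in% names(out)) {
    out$markers <- dplyr::coalesce(as.character(out$markers), "")
  }
  out
}
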