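#' List the fixtures shipped with the package
#'
#' Fixtures live under `inst/extdata/` next to a `manifest.tsv` with
#' columns `name`, `file`, `type` (`profiles` or `alleles`), `md5` and
#' `note` describing provenance.  The datasets shipped here are
#' synthetic (generated by [simulate_population()]) and are labelled as
#' such in their filenames and notes.
#'
#' @param dir Fixture directory (default: the installed `extdata`).
#' @return The manifest tibble.
#' @export
fixture_manifest <- function(dir = system.file("extdata", package = "mlstpop")) {
  path <- file.path(dir, "manifest.tsv")
  if (!file.exists(path)) abort(paste0("no fixture manifest at ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Load a named fixture, verifying its checksum
#'
#' Reads the fixture listed in the manifest, fails hard on an MD5
#' mismatch (a corrupted or edited fixture must never silently feed an
#' analysis), and validates the object against the package invariants
#' before returning it.
#'
#' @param name Fixture name as listed in the manifest.
#' @param dir Fixture directory (default: the installed `extdata`).
#' @return A profile tibble (`type = "profiles"`) or an allele library
#'   (`type = "alleles"`).
#' @export
load_fixture <- function(name, dir = system.file("extdata", package = "mlstpop")) {
  manifest <- fixture_manifest(dir)
  row <- manifest[manifest$name == name, ]
  if (nrow(row) != 1L) {
    abort(paste0("fixture '", name, "' not present (available: ",
                 paste(manifest$name, collapse = ", "), ")"))
  }
  path <- file.path(dir, row$file)
  if (!file.exists(path)) abort(paste0("fixture file missing: ", path))
  checksum <- unname(tools::md5sum(path))
  if (!is.na(row$md5) && nzchar(row$md5) && checksum != row$md5) {
    abort(paste0("checksum mismatch for fixture '", name, "': expected ",
                 row$md5, ", got ", checksum))
  }
  switch(row$type,
    profiles = {
      out <- read_profiles_tsv(path)
      assign_sts(out)  # validates completeness; idempotent on stored STs
    },
    alleles = read_allele_fasta(path),
    abort(paste0("unknown fixture type: ", row$type))
  )
}
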