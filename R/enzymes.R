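#' Restriction enzyme definitions
#'
#' An enzyme definition holds a (possibly degenerate) IUPAC recognition
#' site and the top- and bottom-strand cut offsets, counted in bases from
#' the site start with the cut falling after that base. BglI
#' (`GCCNNNN^NGGC`, top offset 7) is the marker enzyme used throughout the
#' worked examples: its interrupted-palindrome site is created by two
#' adjacent allele-specific Cs in the target species and lost in the
#' comparator species.
#'
#' @param name enzyme name.
#' @param site recognition sequence as an IUPAC string.
#' @param cut_top top-strand cut offset, `1 <= cut_top <= nchar(site)`.
#' @param cut_bottom bottom-strand cut offset in top-strand coordinates.
#' @return one-row tibble with columns `name`, `site`, `cut_top`,
#'   `cut_bottom`.
#' @export
#' @examples
#' enzyme_def("BglI", "GCCNNNNNGGC", 7, 4)
enzyme_def <- function(name, site, cut_top, cut_bottom = cut_top) {
  site <- toupper(site)
  bad <- setdiff(unique(seq_chars(site)), names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("recognition site contains non-IUPAC letter(s): %s",
                  paste(bad, collapse = ", ")),
          class = "lampdx_error_parameter")
  }
  check_number(cut_top, "cut_top", 1, nchar(site))
  tibble(name = as.character(name), site = site,
         cut_top = as.integer(cut_top), cut_bottom = as.integer(cut_bottom))
}

#' Built-in enzyme table
#'
#' Minimal set shipped with the package: BglI, EcoRI, HindIII, BamHI.
#' Users can extend or replace it via [read_enzyme_table()].
#'
#' @return tibble with one row per enzyme (`name`, `site`, `cut_top`,
#'   `cut_bottom`).
#' @export
builtin_enzymes <- function() {
  bind_rows(
    enzyme_def("BglI",    "GCCNNNNNGGC", 7, 4),
    enzyme_def("EcoRI",   "GAATTC",      1, 5),
    enzyme_def("HindIII", "AAGCTT",      1, 5),
    enzyme_def("BamHI",   "GGATCC",      1, 5)
  )
}

#' Read a user enzyme table
#'
#' @param path TSV with header `name<TAB>site<TAB>cut_top<TAB>cut_bottom`.
#' @return validated enzyme tibble.
#' @export
read_enzyme_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    name = "c", site = "c", cut_top = "i", cut_bottom = "i"
  ), progress = FALSE)
  if (!nrow(raw)) abort("empty enzyme table", class = "lampdx_error_parameter")
  purrr::pmap_dfr(raw, enzyme_def)
}
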