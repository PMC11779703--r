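# In-silico CAPS: degenerate restriction-site scanning and linear-molecule
# digestion arithmetic. Fragment lengths follow gel-band semantics: they are
# computed from top-strand cut positions only; sticky-end overhangs are part
# of the enzyme definition but do not change band lengths.

# does the IUPAC pattern match the concrete subsequence starting at pos?
.site_matches_at <- function(chars, pattern_sets, pos) {
  for (k in seq_along(pattern_sets)) {
    if (!(chars[pos + k - 1L] %in% pattern_sets[[k]])) return(FALSE)
  }
  TRUE
}

.check_digest_input <- function(sequence) {
  ch <- seq_chars(sequence)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    abort("digestion input must be unambiguous A/C/G/T sequence",
          class = "lampdx_error_digest_input")
  }
  ch
}

#' Find restriction sites in a sequence
#'
#' Scans the top strand for all (overlapping) matches of the enzyme's IUPAC
#' recognition pattern, and additionally scans with the reverse complement
#' of the pattern for non-palindromic sites. Palindromic sites (such as
#' BglI's interrupted palindrome) are reported once.
#'
#' @param sequence unambiguous A/C/G/T string (PCR product).
#' @param enzyme one-row enzyme tibble from [enzyme_def()] or a row of
#'   [builtin_enzymes()].
#' @return tibble with columns `enzyme`, `start` (1-based site start on the
#'   top strand), `strand` (`"+"` for top-strand pattern matches, `"-"` for
#'   reverse-complement matches), `cut_after` (top-strand position after
#'   which the top strand is cut).
#' @export
find_sites <- function(sequence, enzyme) {
  ch <- .check_digest_input(sequence)
  site <- enzyme$site[1]
  len <- nchar(site)
  empty <- tibble(enzyme = character(), start = integer(),
                  strand = character(), cut_after = integer())
  if (len > length(ch)) return(empty)

  pat_sets <- lapply(seq_chars(site), iupac_set)
  rc_site <- revcomp(site)
  palindromic <- identical(rc_site, site)
  rc_sets <- lapply(seq_chars(rc_site), iupac_set)

  enz_name <- enzyme$name[1]
  cut_top <- enzyme$cut_top[1]
  starts <- seq_len(length(ch) - len + 1L)
  match_starts <- function(sets) {
    ok <- rep(TRUE, length(starts))
    for (k in seq_len(len)) {
      ok <- ok & ch[starts + k - 1L] %in% sets[[k]]
    }
    starts[ok]
  }
  fwd <- match_starts(pat_sets)
  hits <- tibble(enzyme = enz_name, start = fwd, strand = "+",
                 cut_after = fwd + cut_top - 1L)
  if (!palindromic) {
    # pattern on the bottom strand: the top strand of the duplex is cut
    # cut_top bases before the site end
    rev <- match_starts(rc_sets)
    hits <- bind_rows(hits, tibble(
      enzyme = enz_name, start = rev, strand = "-",
      cut_after = rev + len - 1L - cut_top
    ))
  }
  if (!nrow(hits)) return(empty)
  arrange(hits, .data$start, .data$strand)
}

#' Digest a linear sequence with one enzyme
#'
#' Complete simultaneous digestion of a linear molecule: every top-strand
#' cut position from [find_sites()] is applied; `n` cuts give `n + 1`
#' fragments whose lengths sum to the sequence length. A sequence with no
#' site yields a single full-length fragment.
#'
#' @inheritParams find_sites
#' @param id label for the digested molecule (default `"seq"`).
#' @return tibble of class `digest_result` with columns `seq_id`, `enzyme`,
#'   `n_hits`, and list-columns `cut_after` and `fragments` (lengths in bp,
#'   sorted descending).
#' @export
digest <- function(sequence, enzyme, id = "seq") {
  ch <- .check_digest_input(sequence)
  hits <- find_sites(sequence, enzyme)
  cuts <- sort(unique(hits$cut_after))
  cuts <- cuts[cuts >= 1L & cuts < length(ch)]
  bounds <- c(0L, cuts, length(ch))
  frags <- sort(diff(bounds), decreasing = TRUE)
  out <- tibble(seq_id = id, enzyme = enzyme$name[1],
                n_hits = nrow(hits),
                cut_after = list(cuts), fragments = list(frags))
  structure(out, class = c("digest_result", class(out)))
}

#' Differential digestion of an allele pair over an enzyme table
#'
#' Digests both alleles of an amplicon pair with every enzyme in the table
#' and reports which enzymes discriminate them (different fragment
#' multisets), together with the hybrid banding pattern (the union of both
#' alleles' bands, as seen when both alleles are present in one template).
#'
#' @param allele_a,allele_b unambiguous sequences of equal length.
#' @param enzymes enzyme tibble ([builtin_enzymes()] or
#'   [read_enzyme_table()]).
#' @return tibble with one row per enzyme: `enzyme`, `n_hits_a`,
#'   `n_hits_b`, list-columns `fragments_a`, `fragments_b`,
#'   `hybrid_bands` (distinct band lengths, descending), and `diagnostic`;
#'   sorted diagnostic-first then by enzyme name.
#' @export
differential_digest <- function(allele_a, allele_b, enzymes) {
  if (!is.data.frame(enzymes) || !nrow(enzymes)) {
    abort("empty enzyme table", class = "lampdx_error_parameter")
  }
  if (nchar(allele_a) != nchar(allele_b)) {
    abort("allele sequences must have equal length (amplicon pair)",
          class = "lampdx_error_parameter")
  }
  out <- purrr::map_dfr(seq_len(nrow(enzymes)), function(i) {
    e <- enzymes[i, ]
    da <- digest(allele_a, e, id = "allele_a")
    db <- digest(allele_b, e, id = "allele_b")
    fa <- da$fragments[[1]]; fb <- db$fragments[[1]]
    tibble(enzyme = e$name,
           n_hits_a = da$n_hits, n_hits_b = db$n_hits,
           fragments_a = list(fa), fragments_b = list(fb),
           hybrid_bands = list(sort(unique(c(fa, fb)), decreasing = TRUE)),
           diagnostic = !identical(sort(fa), sort(fb)))
  })
  arrange(out, desc(.data$diagnostic), .data$enzyme)
}

#' Hybrid banding pattern for one enzyme
#'
#' Band lengths observed when a heterozygous template carries both alleles:
#' the union of the two alleles' digestion fragments with duplicates
#' collapsed.
#'
#' @inheritParams differential_digest
#' @param enzyme one-row enzyme tibble.
#' @return numeric vector of distinct band lengths, sorted descending.
#' @export
hybrid_pattern <- function(allele_a, allele_b, enzyme) {
  fa <- digest(allele_a, enzyme)$fragments[[1]]
  fb <- digest(allele_b, enzyme)$fragments[[1]]
  sort(unique(c(fa, fb)), decreasing = TRUE)
}
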