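# Allele-specific backward-loop (LB) primer enumeration and ranking.
#
# Candidates are exhaustively enumerated inside the backward loop domain
# (between B1 and B2), one per allele and placement, each a perfect match
# to its own allele. Discrimination against the other allele is scored from
# the mismatches the candidate forms on the non-target template: mismatch
# position within the primer (center mismatches disturb amplification more
# than terminal ones), the broken Watson-Crick pair (C-G costs more than
# A-T) and optional per-change multipliers (a T>A change at the center
# outweighs C>T).

#' Mismatch weight table for discrimination scoring
#'
#' Defaults encode the qualitative ordering rules: center > internal >
#' terminal position weights, broken C-G pair > A-T pair, and a center T>A
#' change boosted over other changes. All values are configurable; the
#' orderings are enforced.
#'
#' @param position named numeric weights for the position classes
#'   `five_prime_terminal`, `internal`, `center`, `three_prime_terminal`.
#' @param pair named numeric weights for broken pairs `C-G` and `A-T`.
#' @param change_multipliers tibble with columns `change` (e.g. `"T>A"`,
#'   top-strand target base > non-target base), `class` (position class or
#'   `"any"`) and `multiplier`; changes not listed multiply by 1.
#' @return list of class `mismatch_weights`.
#' @export
mismatch_weights <- function(
    position = c(five_prime_terminal = 1.0, internal = 1.5, center = 2.0,
                 three_prime_terminal = 1.0),
    pair = c("C-G" = 1.5, "A-T" = 1.0),
    change_multipliers = tibble(change = "T>A", class = "center",
                                multiplier = 1.25)) {
  need <- c("five_prime_terminal", "internal", "center", "three_prime_terminal")
  if (!all(need %in% names(position)) || !all(c("C-G", "A-T") %in% names(pair))) {
    abort("weight table is missing required entries",
          class = "lampdx_error_configuration")
  }
  terminal_max <- max(position[["five_prime_terminal"]],
                      position[["three_prime_terminal"]])
  if (position[["center"]] <= terminal_max) {
    abort("center weight must exceed terminal weights",
          class = "lampdx_error_configuration")
  }
  if (pair[["C-G"]] <= pair[["A-T"]]) {
    abort("C-G pair weight must exceed A-T pair weight",
          class = "lampdx_error_configuration")
  }
  structure(list(position = position, pair = pair,
                 change_multipliers = change_multipliers),
            class = "mismatch_weights")
}

# position class of a 1-based primer offset for a primer of length len:
# terminal = first/last 2 nt, center = middle third rounded outward,
# remainder = internal
.position_class <- function(offset, len) {
  w <- ceiling(len / 3)
  cs <- floor((len - w) / 2) + 1L
  if (offset <= 2L) "five_prime_terminal"
  else if (offset >= len - 1L) "three_prime_terminal"
  else if (offset >= cs && offset <= cs + w - 1L) "center"
  else "internal"
}

# mismatch profile of a candidate (perfect match to `own`) against `other`,
# for the top-strand interval [start, end]; primer synthesized as the
# reverse complement of the top strand, so primer offset 1 sits at `end`
.mismatch_profile <- function(own, other, start, end) {
  len <- end - start + 1L
  own_ch <- seq_chars(own)
  oth_ch <- seq_chars(other)
  pos <- (start:end)[own_ch[start:end] != oth_ch[start:end]]
  purrr::map_dfr(pos, function(p) {
    offset <- end - p + 1L
    own_base <- own_ch[p]
    tibble(
      position = p,
      offset = offset,
      position_class = .position_class(offset, len),
      pair = if (own_base %in% c("C", "G")) "C-G" else "A-T",
      change = paste0(own_base, ">", oth_ch[p])
    )
  })
}

#' Score a candidate's predicted allele discrimination
#'
#' Sum over the candidate's mismatches (against the non-target allele) of
#' position-class weight x broken-pair weight x change multiplier. Zero
#' mismatches score 0; higher scores predict stronger discrimination.
#'
#' @param candidate one row of an [enumerate_loop_candidates()] tibble, or
#'   a mismatch-profile tibble (columns `position_class`, `pair`,
#'   `change`).
#' @param weights a [mismatch_weights()] table.
#' @return numeric score `>= 0`.
#' @export
score_discrimination <- function(candidate, weights = mismatch_weights()) {
  if (!inherits(weights, "mismatch_weights")) {
    abort("weights must come from mismatch_weights()",
          class = "lampdx_error_configuration")
  }
  mm <- if (is.data.frame(candidate) && "mismatches" %in% names(candidate)) {
    candidate$mismatches[[1]]
  } else {
    candidate
  }
  if (!nrow(mm)) return(0)
  mult <- vapply(seq_len(nrow(mm)), function(i) {
    hit <- weights$change_multipliers$change == mm$change[i] &
      (weights$change_multipliers$class == mm$position_class[i] |
         weights$change_multipliers$class == "any")
    if (any(hit)) weights$change_multipliers$multiplier[which(hit)[1]] else 1
  }, numeric(1))
  sum(weights$position[mm$position_class] * weights$pair[mm$pair] * mult)
}

#' Enumerate allele-specific loop-primer candidates
#'
#' Slides windows of the requested lengths across the backward loop domain
#' and emits, for every placement covering at least one diagnostic SNP, one
#' candidate per allele: a perfect match to its own allele, reverse
#' complement of the top-strand interval (synthesis orientation), with its
#' mismatch profile computed against the other allele.
#'
#' @param alleles named character vector of the two allele amplicon
#'   sequences (equal length).
#' @param diagnostic_positions integer vector of diagnostic SNP positions
#'   in amplicon coordinates.
#' @param loop_window integer length-2 vector, the backward loop domain
#'   (top-strand interval strictly between B1 and B2).
#' @param lengths candidate primer lengths (default `c(11, 17)`, the short
#'   and long allele-specific loop designs).
#' @param weights a [mismatch_weights()] table used to score candidates.
#' @return tibble with one row per candidate: `allele`, `sequence`,
#'   `length`, `start`, `end`, `strand`, `covered_snps` (list),
#'   `n_covered`, `mismatches` (list of profile tibbles), `n_mismatches`,
#'   `tm`, `gc`, `score`.
#' @export
enumerate_loop_candidates <- function(alleles, diagnostic_positions,
                                      loop_window, lengths = c(11L, 17L),
                                      weights = mismatch_weights()) {
  if (length(alleles) != 2L || is.null(names(alleles))) {
    abort("alleles must be a named character vector of length 2",
          class = "lampdx_error_parameter")
  }
  if (nchar(alleles[[1]]) != nchar(alleles[[2]])) {
    abort("allele sequences must have equal length",
          class = "lampdx_error_parameter")
  }
  if (is.null(loop_window) || length(loop_window) != 2L ||
        loop_window[1] > loop_window[2]) {
    abort("backward loop window absent or degenerate",
          class = "lampdx_error_design")
  }
  empty <- tibble(allele = character(), sequence = character(),
                  length = integer(), start = integer(), end = integer(),
                  strand = character(), covered_snps = list(),
                  n_covered = integer(), mismatches = list(),
                  n_mismatches = integer(), tm = numeric(), gc = numeric(),
                  score = numeric())
  diagnostic_positions <- sort(unique(as.integer(diagnostic_positions)))
  if (!length(diagnostic_positions)) return(empty)

  win <- as.integer(loop_window)
  rows <- list()
  for (len in sort(unique(as.integer(lengths)))) {
    if (len > win[2] - win[1] + 1L) {
      warn(sprintf("candidate length %d exceeds the loop window; skipped", len))
      next
    }
    for (s in win[1]:(win[2] - len + 1L)) {
      e <- s + len - 1L
      covered <- diagnostic_positions[diagnostic_positions >= s &
                                        diagnostic_positions <= e]
      if (!length(covered)) next
      for (a in seq_len(2L)) {
        own <- alleles[[a]]
        other <- alleles[[3L - a]]
        mm <- .mismatch_profile(own, other, s, e)
        sq <- revcomp(substr(own, s, e))
        rows <- c(rows, list(tibble(
          allele = names(alleles)[a], sequence = sq, length = len,
          start = s, end = e, strand = "-",
          covered_snps = list(covered), n_covered = length(covered),
          mismatches = list(mm), n_mismatches = nrow(mm),
          tm = melting_temp(sq), gc = gc_fraction(sq),
          score = score_discrimination(mm, weights)
        )))
      }
    }
  }
  if (!length(rows)) return(empty)
  bind_rows(rows)
}

# total-order ranking used everywhere candidates are compared
.rank_candidates <- function(cands) {
  cands |>
    arrange(desc(.data$score), desc(.data$n_covered), desc(.data$length),
            .data$start, .data$sequence) |>
    mutate(rank = row_number())
}

#' Design the allele-specific loop-primer pair
#'
#' Enumerates candidates for both alleles and returns the top-scoring
#' candidate perfectly matching each allele, with the full ranked lists.
#' Ties are broken by more covered SNPs, then longer primer, then leftmost
#' placement, then lexicographic sequence, making the ranking a total
#' order independent of enumeration order.
#'
#' @inheritParams enumerate_loop_candidates
#' @return list with `best` (tibble, one row per allele) and `candidates`
#'   (ranked tibble of all candidates).
#' @export
design_allele_pair <- function(alleles, diagnostic_positions, loop_window,
                               lengths = c(11L, 17L),
                               weights = mismatch_weights()) {
  cands <- enumerate_loop_candidates(alleles, diagnostic_positions,
                                     loop_window, lengths, weights)
  if (!nrow(cands)) {
    abort("no loop-primer candidate covers any diagnostic site",
          class = "lampdx_error_design")
  }
  ranked <- .rank_candidates(cands)
  best <- ranked |>
    group_by(.data$allele) |>
    dplyr::slice_min(.data$rank, n = 1L) |>
    ungroup() |>
    arrange(.data$allele)
  list(best = best, candidates = ranked)
}
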