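# LAMP primer-set container and geometry validation.
#
# A LAMP set amplifies the region F3..B3 with two outer primers (F3/B3),
# two inner primers (FIP = F1c+F2, BIP = B1c+B2) and optional loop primers.
# Element intervals are stored in top-strand 1-based amplicon coordinates
# with the element order F3 < F2 < F1 < B1 < B2 < B3; the backward loop
# primer (LB) sits strictly between B1 and B2, the forward loop primer (LF)
# strictly between F2 and F1. Primer sequences are stored in synthesis
# orientation: F3, F2, B1c and LF read the top strand; F1c, B2, B3 and LB
# are reverse complements of their top-strand intervals.

.LAMP_ROLES <- tibble::tibble(
  role = c("F3", "F2", "LF", "F1c", "B1c", "LB", "B2", "B3"),
  strand = c("+", "+", "+", "-", "+", "-", "-", "-"),
  required = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
  order = 1:8
)

.element_seq <- function(amplicon, start, end, strand) {
  s <- substr(amplicon, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Build a LAMP primer set from element intervals
#'
#' @param amplicon top-strand amplicon sequence the set was designed on.
#' @param elements tibble with columns `role` (among F3, F2, LF, F1c, B1c,
#'   LB, B2, B3; LF/LB optional), `start`, `end` (1-based inclusive
#'   top-strand coordinates). Sequences and strands are derived.
#' @return tibble of class `lamp_primer_set` with one row per element
#'   (`role`, `start`, `end`, `strand`, `sequence`) plus attributes holding
#'   the composed `FIP` (F1c+F2) and `BIP` (B1c+B2) sequences.
#' @export
lamp_primer_set <- function(amplicon, elements) {
  need <- .LAMP_ROLES$role[.LAMP_ROLES$required]
  if (!all(need %in% elements$role)) {
    abort(sprintf("missing LAMP element(s): %s",
                  paste(setdiff(need, elements$role), collapse = ", ")),
          class = "lampdx_error_parameter")
  }
  if (any(elements$start < 1L | elements$end > nchar(amplicon) |
            elements$start > elements$end)) {
    abort("element interval outside the amplicon",
          class = "lampdx_error_coordinate")
  }
  out <- elements |>
    left_join(.LAMP_ROLES, by = "role") |>
    arrange(.data$order) |>
    mutate(sequence = purrr::pmap_chr(
      list(.data$start, .data$end, .data$strand),
      function(s, e, st) .element_seq(amplicon, s, e, st)
    )) |>
    select("role", "start", "end", "strand", "sequence")
  seq_of <- function(r) out$sequence[out$role == r]
  structure(out,
            amplicon = amplicon,
            fip = paste0(seq_of("F1c"), seq_of("F2")),
            bip = paste0(seq_of("B1c"), seq_of("B2")),
            class = c("lamp_primer_set", class(out)))
}

#' Composed inner-primer sequences of a LAMP set
#' @param set a [lamp_primer_set()].
#' @return named character vector with `FIP` and `BIP`.
#' @export
inner_primers <- function(set) {
  c(FIP = attr(set, "fip"), BIP = attr(set, "bip"))
}

#' Default primer-design constraints
#'
#' Tm windows per role and GC bounds used by [validate_primer_set()]:
#' 55-65 degrees C for outer/inner elements, 50-65 for loop primers (short
#' 11-nt allele-specific loops run cooler), GC fraction 0.40-0.65.
#'
#' @param tm_min,tm_max core element Tm window (degrees C).
#' @param tm_min_loop loop-primer lower Tm bound.
#' @param gc_min,gc_max GC-fraction bounds.
#' @return named list of constraint values.
#' @export
design_constraints <- function(tm_min = 55, tm_max = 65, tm_min_loop = 50,
                               gc_min = 0.40, gc_max = 0.65) {
  list(tm_min = tm_min, tm_max = tm_max, tm_min_loop = tm_min_loop,
       gc_min = gc_min, gc_max = gc_max)
}

.rule_row <- function(rule, role, pass, message) {
  tibble(rule = rule, role = role, pass = pass, message = message)
}

#' Validate LAMP primer-set geometry and thermodynamics
#'
#' Checks element ordering on the amplicon (F3 < F2 < F1 < B1 < B2 < B3,
#' non-overlapping), loop-primer placement (LB strictly between B1 and B2,
#' LF strictly between F2 and F1), strand orientation, exact sequence
#' identity with the designated amplicon strand, and per-role Tm and GC
#' windows. The set is validated, not re-designed.
#'
#' @param amplicon top-strand amplicon sequence.
#' @param set a [lamp_primer_set()].
#' @param constraints list from [design_constraints()].
#' @return tibble with one row per applied rule: `rule`, `role`, `pass`,
#'   `message`; attribute `valid` is TRUE when all rules pass.
#' @export
validate_primer_set <- function(amplicon, set,
                                constraints = design_constraints()) {
  if (any(set$start < 1L | set$end > nchar(amplicon))) {
    abort("element interval outside the amplicon",
          class = "lampdx_error_coordinate")
  }
  rows <- list()
  roles <- set$role

  # ordering and overlap along the amplicon
  core <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  starts <- setNames(set$start, roles)
  ends <- setNames(set$end, roles)
  ord_ok <- all(diff(starts[core]) > 0) &&
    all(ends[core][-length(core)] < starts[core][-1L])
  rows <- c(rows, list(.rule_row(
    "ordering", "set", ord_ok,
    if (ord_ok) "F3 < F2 < F1 < B1 < B2 < B3, non-overlapping"
    else "core elements out of order or overlapping")))

  if ("LB" %in% roles) {
    ok <- starts[["LB"]] > ends[["B1c"]] && ends[["LB"]] < starts[["B2"]]
    rows <- c(rows, list(.rule_row(
      "loop_placement", "LB", ok,
      if (ok) "LB strictly between B1 and B2"
      else "LB must lie strictly between B1 and B2")))
  }
  if ("LF" %in% roles) {
    ok <- starts[["LF"]] > ends[["F2"]] && ends[["LF"]] < starts[["F1c"]]
    rows <- c(rows, list(.rule_row(
      "loop_placement", "LF", ok,
      if (ok) "LF strictly between F2 and F1"
      else "LF must lie strictly between F2 and F1")))
  }

  expected_strand <- setNames(.LAMP_ROLES$strand, .LAMP_ROLES$role)
  for (i in seq_len(nrow(set))) {
    role <- set$role[i]
    ok <- set$strand[i] == expected_strand[[role]]
    rows <- c(rows, list(.rule_row(
      "orientation", role, ok,
      if (ok) sprintf("%s on strand %s", role, set$strand[i])
      else sprintf("%s must be on strand %s", role, expected_strand[[role]]))))

    want <- .element_seq(amplicon, set$start[i], set$end[i],
                         expected_strand[[role]])
    ok <- identical(set$sequence[i], want)
    rows <- c(rows, list(.rule_row(
      "identity", role, ok,
      if (ok) "sequence matches the amplicon"
      else "sequence does not match the designated amplicon strand")))

    tm <- melting_temp(set$sequence[i])
    tmin <- if (role %in% c("LF", "LB")) constraints$tm_min_loop
            else constraints$tm_min
    ok <- tm >= tmin && tm <= constraints$tm_max
    rows <- c(rows, list(.rule_row(
      "tm_window", role, ok,
      sprintf("Tm %.1f C (window %.0f-%.0f)", tm, tmin, constraints$tm_max))))

    gc <- gc_fraction(set$sequence[i])
    ok <- gc >= constraints$gc_min && gc <= constraints$gc_max
    rows <- c(rows, list(.rule_row(
      "gc_window", role, ok,
      sprintf("GC %.2f (window %.2f-%.2f)", gc,
              constraints$gc_min, constraints$gc_max))))
  }
  report <- bind_rows(rows)
  structure(report, valid = all(report$pass),
            class = c("lamp_validation", class(report)))
}
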