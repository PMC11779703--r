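# Delta-Cq discrimination analysis and the dual-reaction decision engine.
#
# A sample is run in two allele-specific reactions: one with the loop
# primer matching the target species (rc) and one matching the comparator
# species (rh). Positivity at the visual-read cutoff in one, the other,
# both or neither maps to the four calls target_species / other_species /
# hybrid / invalid.

#' Time gap between matched and mismatched reactions
#'
#' `delta_cq = mismatched Cq - matched Cq`, censoring-aware: when the
#' mismatched reaction never amplifies within the run limit the gap is
#' reported as a lower bound `> run_limit - matched Cq` with a censored
#' flag, never imputed.
#'
#' @param matched_cq Cq (minutes) of the perfectly matched reaction; must
#'   be observed.
#' @param mismatched_cq Cq of the mismatched reaction; NA = censored.
#' @param run_limit run length in minutes (default 90).
#' @return tibble `delta_cq` (minutes; for censored gaps the lower bound),
#'   `censored`, `label` (e.g. `"45"` or `"> 60"`).
#' @export
delta_cq <- function(matched_cq, mismatched_cq, run_limit = 90) {
  if (is.na(matched_cq)) {
    abort("matched reaction is censored; the time gap is undefined",
          class = "lampdx_error_undefined_gap")
  }
  check_number(matched_cq, "matched_cq", 0, run_limit)
  if (is.na(mismatched_cq)) {
    gap <- run_limit - matched_cq
    tibble(delta_cq = gap, censored = TRUE, label = sprintf("> %g", gap))
  } else {
    gap <- mismatched_cq - matched_cq
    tibble(delta_cq = gap, censored = FALSE, label = sprintf("%g", gap))
  }
}

#' Species call from the dual allele-specific reactions
#'
#' A reaction is positive iff its Cq is observed and `<= cutoff` (a
#' borderline Cq exactly at the cutoff counts positive). Mapping:
#' target-only positive = `target_species`; comparator-only positive =
#' `other_species`; both = `hybrid` (both alleles present); neither =
#' `invalid` (no amplifiable template - re-extract).
#'
#' @param rc_cq Cq (minutes) of the target-allele (rc) reaction; NA =
#'   no amplification.
#' @param rh_cq Cq of the comparator-allele (rh) reaction; NA = no
#'   amplification.
#' @param cutoff positive threshold in minutes (default 35, the visual
#'   read time).
#' @return tibble `rc_positive`, `rh_positive`, `call`, and the expected
#'   indicator colors `hnb_rc`, `hnb_rh`, `nred_rc`, `nred_rh`.
#' @export
#' @examples
#' call_species(28, NA)   # target_species
#' call_species(28, 30)   # hybrid
call_species <- function(rc_cq, rh_cq, cutoff = 35) {
  check_number(cutoff, "cutoff", min = 1e-9)
  rc_pos <- !is.na(rc_cq) && rc_cq <= cutoff
  rh_pos <- !is.na(rh_cq) && rh_cq <= cutoff
  call <- if (rc_pos && !rh_pos) "target_species"
  else if (!rc_pos && rh_pos) "other_species"
  else if (rc_pos && rh_pos) "hybrid"
  else "invalid"
  tibble(rc_positive = rc_pos, rh_positive = rh_pos, call = call,
         hnb_rc = expected_color("HNB", rc_pos),
         hnb_rh = expected_color("HNB", rh_pos),
         nred_rc = expected_color("N-red", rc_pos),
         nred_rh = expected_color("N-red", rh_pos))
}

#' Call a table of dual-reaction Cq measurements
#'
#' @param data tibble with columns `sample`, `rc_cq`, `rh_cq` (minutes,
#'   NA = no amplification).
#' @param cutoff positive threshold in minutes.
#' @return input tibble augmented with the [call_species()] columns.
#' @export
call_samples <- function(data, cutoff = 35) {
  as_tibble(data) |>
    mutate(purrr::map2_dfr(.data$rc_cq, .data$rh_cq, call_species,
                           cutoff = cutoff))
}

#' Expected indicator color for a reaction outcome
#'
#' Hydroxy naphthol blue (HNB) turns from blue to light blue on
#' amplification; neutral red (N-red) turns from yellow to pink.
#'
#' @param indicator `"HNB"` or `"N-red"`.
#' @param positive logical amplification outcome.
#' @return color label.
#' @export
expected_color <- function(indicator, positive) {
  colors <- list(
    "HNB" = c(positive = "light blue", negative = "blue"),
    "N-red" = c(positive = "pink", negative = "yellow")
  )
  if (!indicator %in% names(colors)) {
    abort(sprintf("unknown indicator '%s'", indicator),
          class = "lampdx_error_parameter")
  }
  unname(colors[[indicator]][if (isTRUE(positive)) "positive" else "negative"])
}
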