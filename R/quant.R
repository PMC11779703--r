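# Template quantification and reaction bookkeeping arithmetic.

AVOGADRO_PRINTED <- 6.02e23
DALTON_PER_BP <- 660

#' Copy number of a double-stranded template from mass concentration
#'
#' `copies/uL = conc(ng/uL) x 6.02e23 (copies/mol) x 1e-9 (g/ng) /
#' (length(bp) x 660 (dalton/bp))`. The rounded Avogadro constant 6.02e23
#' is used by default for fidelity with the bench formula; set
#' `exact_avogadro = TRUE` for the full-precision constant.
#'
#' @param concentration_ng_ul DNA concentration in ng/uL (>= 0).
#' @param length_bp molecule length in base pairs (>= 1).
#' @param exact_avogadro use 6.02214076e23 instead of 6.02e23.
#' @return copies per microlitre.
#' @export
#' @examples
#' copies_per_ul(1, 3000)   # about 3.04e8
copies_per_ul <- function(concentration_ng_ul, length_bp,
                          exact_avogadro = FALSE) {
  check_number(concentration_ng_ul, "concentration_ng_ul", 0)
  check_number(length_bp, "length_bp", 1)
  na <- if (exact_avogadro) 6.02214076e23 else AVOGADRO_PRINTED
  concentration_ng_ul * na * 1e-9 / (length_bp * DALTON_PER_BP)
}

#' Mass concentration back from a copy number
#'
#' Inverse of [copies_per_ul()]; useful for planning dilutions from a
#' target copy load.
#'
#' @param copies copies per microlitre.
#' @inheritParams copies_per_ul
#' @return concentration in ng/uL.
#' @export
ng_per_ul <- function(copies, length_bp, exact_avogadro = FALSE) {
  check_number(copies, "copies", 0)
  check_number(length_bp, "length_bp", 1)
  na <- if (exact_avogadro) 6.02214076e23 else AVOGADRO_PRINTED
  copies * length_bp * DALTON_PER_BP / (na * 1e-9)
}

#' Geometric dilution series
#'
#' @param stock_copies starting copy number (> 0).
#' @param fold dilution factor between levels (> 1, default 10).
#' @param levels number of levels (>= 1).
#' @return numeric vector `stock, stock/fold, ...` of length `levels`.
#' @export
#' @examples
#' dilution_series(1e8, levels = 8)   # 1e8 ... 1e1
dilution_series <- function(stock_copies, fold = 10, levels = 8L) {
  check_number(stock_copies, "stock_copies", min = .Machine$double.xmin)
  if (fold <= 1) abort("fold must be > 1", class = "lampdx_error_parameter")
  check_number(levels, "levels", 1)
  stock_copies / fold^(seq_len(levels) - 1)
}

#' Minor-template copy load in a mixed template
#'
#' Copy number contributed by the minor allele at a given fraction of a
#' fixed total copy load (e.g. 0.1% of 1e6 copies = 1e3 copies).
#'
#' @param total_copies total copies in the mixture.
#' @param minor_fraction minor-template fraction in `[0, 1]`.
#' @return minor-template copies.
#' @export
mixture_minor_copies <- function(total_copies, minor_fraction) {
  check_number(total_copies, "total_copies", 0)
  check_number(minor_fraction, "minor_fraction", 0, 1)
  total_copies * minor_fraction
}

#' Master-mix volume bookkeeping
#'
#' Computes per-component volumes to reach each component's final
#' concentration in the total reaction volume, for fold-style stocks
#' (`50x` to `1x`) or concentration-style stocks (same units for stock and
#' final). The remainder is assigned to water.
#'
#' @param total_volume_ul reaction volume in uL.
#' @param components tibble/data frame with columns `component`, `stock`,
#'   `final` (stock and final in the same unit, e.g. fold or mM or uM).
#' @return tibble `component`, `stock`, `final`, `volume_ul`, with a
#'   closing `water` row; volumes sum to `total_volume_ul`.
#' @export
#' @examples
#' master_mix(25, tibble::tibble(component = "dye", stock = 50, final = 1))
master_mix <- function(total_volume_ul, components) {
  check_number(total_volume_ul, "total_volume_ul", min = 1e-6)
  comp <- as_tibble(components)
  if (any(comp$stock < comp$final)) {
    abort("component stock more dilute than its final concentration",
          class = "lampdx_error_infeasible_mix")
  }
  comp <- mutate(comp, volume_ul = total_volume_ul * .data$final / .data$stock)
  used <- sum(comp$volume_ul)
  if (used > total_volume_ul + 1e-9) {
    abort(sprintf("component volumes (%.2f uL) exceed the total %.2f uL",
                  used, total_volume_ul),
          class = "lampdx_error_infeasible_mix")
  }
  bind_rows(comp,
            tibble(component = "water", stock = NA_real_, final = NA_real_,
                   volume_ul = total_volume_ul - used))
}
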