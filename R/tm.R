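# Nearest-neighbor duplex melting temperature.
#
# Unified nearest-neighbor parameter set (Allawi & SantaLucia 1997 /
# SantaLucia 1998 unified table): stack enthalpies in kcal/mol, entropies
# in cal/(K*mol), duplex initiation split into terminal G.C and A.T terms.
# Monovalent salt enters through the entropy correction
# dS' = dS + 0.368 * (N-1) * ln[Na+].

.NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
            "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
            "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
            "CG" = -10.6, "GC" = -9.8,
            "GG" = -8.0, "CC" = -8.0)
.NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
            "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
            "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
            "CG" = -27.2, "GC" = -24.4,
            "GG" = -19.9, "CC" = -19.9)
.INIT_GC <- c(dh = 0.1, ds = -2.8)
.INIT_AT <- c(dh = 2.3, ds = 4.1)

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex Tm from the unified nearest-neighbor thermodynamic table with
#' monovalent-salt entropy correction. Deterministic; suitable for ranking
#' and window checks of LAMP primer candidates.
#'
#' @param sequence unambiguous A/C/G/T primer sequence, length >= 6.
#' @param primer_conc primer concentration in mol/L (default 250e-9; the
#'   total strand concentration entering the two-state model is twice
#'   this, and the non-self-complementary factor 4 applies).
#' @param na_conc monovalent cation concentration in mol/L (default 0.05).
#' @return melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temp("AGCTTGGCATTGACCTAGGA")
melting_temp <- function(sequence, primer_conc = 250e-9, na_conc = 0.05) {
  ch <- seq_chars(sequence)
  if (length(ch) < 6L) {
    abort("primer shorter than 6 nt", class = "lampdx_error_parameter")
  }
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    abort("ambiguity codes not allowed in Tm calculation",
          class = "lampdx_error_input")
  }
  check_number(primer_conc, "primer_conc", 1e-12, 1)
  check_number(na_conc, "na_conc", 1e-4, 5)

  stacks <- paste0(ch[-length(ch)], ch[-1L])
  dh <- sum(.NN_DH[stacks])
  ds <- sum(.NN_DS[stacks])
  for (term in c(ch[1L], ch[length(ch)])) {
    init <- if (term %in% c("G", "C")) .INIT_GC else .INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  self_comp <- identical(paste(ch, collapse = ""), revcomp(sequence))
  if (self_comp) ds <- ds - 1.4
  ds <- ds + 0.368 * (length(ch) - 1L) * log(na_conc)

  ct <- 2 * primer_conc
  x <- if (self_comp) 1 else 4
  dh * 1000 / (ds + 1.987 * log(ct / x)) - 273.15
}
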