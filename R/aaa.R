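# IUPAC nucleotide codes and small internal helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# residues carrying no information: excluded by pairwise deletion
UNDETERMINED <- c("-", ".", "N", "?")

iupac_set <- function(base) {
  s <- IUPAC_SETS[[toupper(base)]]
  if (is.null(s)) {
    abort(sprintf("unknown residue code '%s'", base), class = "lampdx_error_residue")
  }
  s
}

#' Look up the IUPAC code covering a set of bases
#'
#' @param bases character vector of unambiguous bases (subset of A/C/G/T).
#' @return single IUPAC letter whose base set equals `bases`.
#' @keywords internal
iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  abort("no IUPAC code for the requested base set", class = "lampdx_error_residue")
}

# TRUE when two residues count as a difference: both informative and their
# IUPAC base sets are disjoint (conservative toward heterozygous calls)
residues_differ <- function(a, b) {
  length(intersect(iupac_set(a), iupac_set(b))) == 0L
}

is_informative <- function(residues) !(toupper(residues) %in% UNDETERMINED)

revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

gc_fraction <- function(x) {
  ch <- seq_chars(x)
  mean(ch %in% c("G", "C", "S"))
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
          class = "lampdx_error_parameter")
  }
  invisible(x)
}

# Derive a reproducible child seed from a parent seed and a stream label,
# staying inside the 32-bit integer range.
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream))
  as.integer((as.double(seed) * 7919 + offs) %% .Machine$integer.max)
}
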