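# Independent brute-force oracles and tiny hand-built fixtures shared
# across the test files. The oracles enumerate pairs / positions directly
# and stay independent of the package's vectorised implementations.

iupac_sets_oracle <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_informative <- function(r) !(r %in% c("-", ".", "N", "?"))

oracle_differ <- function(a, b) {
  length(intersect(iupac_sets_oracle[[a]], iupac_sets_oracle[[b]])) == 0L
}

# fraction of differing pairs at one site, enumerating every pair
oracle_pi_within <- function(residues) {
  residues <- residues[oracle_informative(residues)]
  n <- length(residues)
  if (n < 2) return(NA_real_)
  diffs <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    if (oracle_differ(residues[i], residues[j])) diffs <- diffs + 1
  }
  diffs / pairs
}

oracle_pi_between <- function(res_a, res_b) {
  res_a <- res_a[oracle_informative(res_a)]
  res_b <- res_b[oracle_informative(res_b)]
  if (!length(res_a) || !length(res_b)) return(NA_real_)
  diffs <- 0
  for (a in res_a) for (b in res_b) if (oracle_differ(a, b)) diffs <- diffs + 1
  diffs / (length(res_a) * length(res_b))
}

# position-by-position degenerate top-strand site matching
oracle_find_sites <- function(sequence, site) {
  ch <- strsplit(sequence, "")[[1]]
  pat <- strsplit(site, "")[[1]]
  hits <- integer()
  if (length(pat) > length(ch)) return(hits)
  for (s in seq_len(length(ch) - length(pat) + 1)) {
    ok <- TRUE
    for (k in seq_along(pat)) {
      if (!(ch[s + k - 1] %in% iupac_sets_oracle[[pat[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small two-species alignment used by several unit tests
tiny_alignment <- function() {
  species_alignment(
    seq_id  = c("a1", "a2", "a3", "b1", "b2", "b3"),
    species = c("A", "A", "A", "B", "B", "B"),
    residues = c("ACGTAC", "ACGTAC", "ACGTCC", "ACTTAC", "ACTTAC", "ACTTAC")
  )
}
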