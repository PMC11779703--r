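# Flat-file writers for the tabular results (TSV throughout) and readers
# for user-supplied Cq tables.

# list-columns become comma-joined strings so the TSV stays one row per
# record and re-imports cleanly
.flatten_list_cols <- function(x) {
  mutate(x, across(dplyr::where(is.list),
                   ~ vapply(.x, function(v) paste(unlist(v), collapse = ","),
                            character(1))))
}

#' Write a result tibble as TSV
#'
#' Generic writer for the package's tabular outputs (diversity profiles,
#' region and SNP tables, digest reports, candidate tables, call reports);
#' list-columns are comma-joined.
#'
#' @param x result tibble.
#' @param path output file path.
#' @return invisibly, `x`.
#' @export
write_result_tsv <- function(x, path) {
  readr::write_tsv(.flatten_list_cols(as_tibble(x)), path, progress = FALSE)
  invisible(x)
}

#' Read a Cq measurement table
#'
#' @param path TSV with columns `sample`, `rc_cq`, `rh_cq` (minutes;
#'   empty/NA = no amplification within the run limit), or `sample`,
#'   `primer`, `cq` in long form.
#' @return tibble with the file's columns, Cq columns numeric.
#' @export
read_cq_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(sample = "c",
                                                .default = "d"),
                  na = c("", "NA", "na", "-"), progress = FALSE)
}

#' Write an allele pair as FASTA
#'
#' @param pair list with `target` and `comparator` sequences (e.g. from
#'   [make_amplicon_pair()]).
#' @param path output FASTA path.
#' @return invisibly, `pair`.
#' @export
write_amplicon_fasta <- function(pair, path) {
  set <- Biostrings::DNAStringSet(c(target = pair$target,
                                    comparator = pair$comparator))
  Biostrings::writeXStringSet(set, path)
  invisible(pair)
}
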