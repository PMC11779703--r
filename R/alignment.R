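#' Species-labelled alignment tables
#'
#' A species alignment is a tibble with one row per sequence and columns
#' `seq_id`, `species` and `residues` (upper-case, gapped, all the same
#' length). It is the input container for the diversity screen. Coordinates
#' are 1-based inclusive alignment positions throughout the package.
#'
#' @param seq_id character vector of unique sequence identifiers.
#' @param species character vector of species labels, one per sequence.
#' @param residues character vector of aligned residue strings over
#'   A/C/G/T, IUPAC ambiguity codes and `-`.
#' @return a tibble of class `species_alignment` with attribute `columns`
#'   (the alignment width).
#' @export
#' @examples
#' species_alignment(
#'   seq_id  = c("a1", "a2", "b1", "b2"),
#'   species = c("A", "A", "B", "B"),
#'   residues = c("ACGT", "ACGT", "ACTT", "ACTT")
#' )
species_alignment <- function(seq_id, species, residues) {
  if (length(seq_id) != length(species) || length(seq_id) != length(residues)) {
    abort("seq_id, species and residues must have equal length",
          class = "lampdx_error_alignment_shape")
  }
  if (anyDuplicated(seq_id)) {
    abort("duplicated seq_id in alignment", class = "lampdx_error_labelling")
  }
  residues <- toupper(residues)
  widths <- nchar(residues)
  if (length(unique(widths)) > 1L) {
    abort(sprintf("ragged alignment: sequence lengths %s",
                  paste(sort(unique(widths)), collapse = ", ")),
          class = "lampdx_error_alignment_shape")
  }
  bad <- setdiff(unique(unlist(strsplit(residues, ""))),
                 c(names(IUPAC_SETS), "-", ".", "?"))
  if (length(bad)) {
    abort(sprintf("unknown residue code(s): %s", paste(bad, collapse = ", ")),
          class = "lampdx_error_residue")
  }
  if (any(table(species) < 1L)) {
    abort("empty species group", class = "lampdx_error_group")
  }
  out <- tibble(seq_id = unname(as.character(seq_id)),
                species = unname(as.character(species)),
                residues = unname(residues))
  structure(out,
            columns = if (nrow(out)) unname(widths[1]) else 0L,
            class = c("species_alignment", class(out)))
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> %d sequences x %d positions, %d groups\n",
              nrow(x), alignment_columns(x), length(unique(x$species))))
  NextMethod()
}

#' Alignment width (number of positions)
#' @param aln a `species_alignment`.
#' @return integer count of alignment columns.
#' @export
alignment_columns <- function(aln) attr(aln, "columns")

#' Read a species-labelled alignment from FASTA + groups table
#'
#' @param fasta_path path to an aligned multi-FASTA (equal-length records).
#' @param groups_path path to a TSV with header `seq_id<TAB>species`, or a
#'   data frame with those columns.
#' @return a [species_alignment()] tibble.
#' @export
read_species_alignment <- function(fasta_path, groups_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  groups <- if (is.data.frame(groups_path)) {
    as_tibble(groups_path)
  } else {
    readr::read_tsv(groups_path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  if (!all(c("seq_id", "species") %in% names(groups))) {
    abort("groups table needs columns seq_id and species",
          class = "lampdx_error_labelling")
  }
  missing <- setdiff(ids, groups$seq_id)
  if (length(missing)) {
    abort(sprintf("seq_id absent from groups table: %s",
                  paste(utils::head(missing, 5), collapse = ", ")),
          class = "lampdx_error_labelling")
  }
  sp <- setNames(groups$species, groups$seq_id)[ids]
  species_alignment(ids, unname(sp), as.character(seqs))
}

#' Write a species alignment back to FASTA + groups TSV
#'
#' @param aln a `species_alignment`.
#' @param fasta_path,groups_path output file paths.
#' @return invisibly, the input alignment.
#' @export
write_species_alignment <- function(aln, fasta_path, groups_path) {
  set <- Biostrings::DNAStringSet(setNames(aln$residues, aln$seq_id))
  Biostrings::writeXStringSet(set, fasta_path)
  readr::write_tsv(tibble(seq_id = aln$seq_id, species = aln$species),
                   groups_path, progress = FALSE)
  invisible(aln)
}

# residue matrix (sequences x positions) for fast per-site work
residue_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$residues, "", fixed = TRUE))
  rownames(m) <- aln$seq_id
  m
}
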