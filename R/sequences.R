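#' Protein sequence with a label
#'
#' A light container for a one-letter amino-acid sequence. Residues are
#' stored as an uppercase character vector with 1-based positions. The 20
#' standard letters plus X/B/Z/U are accepted; whether a residue is
#' scorable is checked against the active scoring matrix at alignment
#' time.
#'
#' @param residues a single string or a character vector of one-letter
#'   codes.
#' @param id sequence label.
#' @return A `residue_sequence` object.
#' @examples
#' residue_sequence("ACDE", id = "toy")
#' @export
residue_sequence <- function(residues, id = "seq") {
  if (length(residues) == 1 && nchar(residues[1]) > 1) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1) stop("sequence must be non-empty", call. = FALSE)
  structure(list(id = as.character(id), residues = residues),
            class = "residue_sequence")
}

#' @export
print.residue_sequence <- function(x, ...) {
  s <- paste(x$residues, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<residue_sequence> %s (%d aa): %s\n", x$id,
              length(x$residues), s))
  invisible(x)
}

#' @export
length.residue_sequence <- function(x) length(x$residues)

#' @export
as.character.residue_sequence <- function(x, ...) {
  paste(x$residues, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A list of [residue_sequence()] objects.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(k) {
    residue_sequence(as.character(set[[k]]),
                     id = sub("\\s.*$", "", names(set)[k]))
  })
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a `residue_sequence` or list of them.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "residue_sequence")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(vapply(seqs, as.character, character(1)))
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
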