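#' Pairwise alignment as an ordered list of columns
#'
#' The central object: an alignment of two [residue_sequence()]s stored as
#' parallel integer vectors `i` and `j`, one entry per column. A MATCH
#' column has both `i` and `j` set; a DELETE column (gap in sequence 2)
#' has `j = NA`; an INSERT column (gap in sequence 1) has `i = NA`.
#' Positions are 1-based and strictly increasing down each sequence. In
#' every mode except `"local"` each residue of both sequences appears in
#' exactly one column; local alignments cover one contiguous sub-range of
#' each sequence.
#'
#' @param seq1,seq2 [residue_sequence()] objects.
#' @param i,j integer vectors of residue positions, `NA` for gaps.
#' @param mode one of `"semiglobal"`, `"local"`, `"model_guided"`,
#'   `"trimmed"`, `"reference"`.
#' @return A `pairwise_alignment` object.
#' @export
pairwise_alignment <- function(seq1, seq2, i, j,
                               mode = c("semiglobal", "local", "model_guided",
                                        "trimmed", "reference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq1, "residue_sequence"),
            inherits(seq2, "residue_sequence"))
  i <- as.integer(i)
  j <- as.integer(j)
  if (length(i) != length(j)) stop("i and j must have equal length",
                                   call. = FALSE)
  if (any(is.na(i) & is.na(j))) {
    stop("a column cannot be a gap in both sequences", call. = FALSE)
  }
  ii <- i[!is.na(i)]
  jj <- j[!is.na(j)]
  if (is.unsorted(ii, strictly = TRUE) || is.unsorted(jj, strictly = TRUE)) {
    stop("residue positions must be strictly increasing along columns",
         call. = FALSE)
  }
  n <- length(seq1$residues)
  m <- length(seq2$residues)
  if (length(ii) && (min(ii) < 1 || max(ii) > n)) {
    stop("sequence 1 positions out of range", call. = FALSE)
  }
  if (length(jj) && (min(jj) < 1 || max(jj) > m)) {
    stop("sequence 2 positions out of range", call. = FALSE)
  }
  if (mode == "local") {
    if (length(ii) && !identical(ii, seq(min(ii), max(ii))) ||
        length(jj) && !identical(jj, seq(min(jj), max(jj)))) {
      stop("local alignments must cover contiguous residue ranges",
           call. = FALSE)
    }
  } else {
    if (!identical(ii, seq_len(n)) || !identical(jj, seq_len(m))) {
      stop("every residue of both sequences must appear exactly once in ",
           mode, " mode", call. = FALSE)
    }
  }
  structure(list(seq1 = seq1, seq2 = seq2, i = i, j = j, mode = mode),
            class = "pairwise_alignment")
}

#' @export
length.pairwise_alignment <- function(x) length(x$i)

#' Aligned residue pairs (edges) of an alignment
#'
#' @param aln a [pairwise_alignment()].
#' @return A two-column integer matrix of MATCH-column positions `(i, j)`.
#' @export
alignment_edges <- function(aln) {
  keep <- !is.na(aln$i) & !is.na(aln$j)
  cbind(i = aln$i[keep], j = aln$j[keep])
}

edge_keys <- function(edges) paste(edges[, 1], edges[, 2], sep = ":")

#' Gapped character strings of the two alignment rows
#'
#' @param aln a [pairwise_alignment()].
#' @return Character vector of length 2.
#' @export
aligned_strings <- function(aln) {
  r1 <- ifelse(is.na(aln$i), "-", aln$seq1$residues[aln$i])
  r2 <- ifelse(is.na(aln$j), "-", aln$seq2$residues[aln$j])
  c(paste(r1, collapse = ""), paste(r2, collapse = ""))
}

#' Build an alignment from two gapped strings
#'
#' Positions are recovered from the cumulative count of non-gap
#' characters, so the input rows must have equal length.
#'
#' @param row1,row2 gapped strings (gap character `-`).
#' @param id1,id2 sequence labels.
#' @param mode alignment mode tag, default `"reference"`.
#' @return A [pairwise_alignment()].
#' @export
alignment_from_strings <- function(row1, row2, id1 = "seq1", id2 = "seq2",
                                   mode = "reference") {
  c1 <- strsplit(toupper(row1), "")[[1]]
  c2 <- strsplit(toupper(row2), "")[[1]]
  if (length(c1) != length(c2)) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  g1 <- c1 == "-"
  g2 <- c2 == "-"
  i <- ifelse(g1, NA_integer_, cumsum(!g1))
  j <- ifelse(g2, NA_integer_, cumsum(!g2))
  pairwise_alignment(residue_sequence(c1[!g1], id = id1),
                     residue_sequence(c2[!g2], id = id2),
                     i, j, mode = mode)
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  s <- aligned_strings(x)
  cat(sprintf("<pairwise_alignment> %s vs %s, %d columns, %d edges [%s]\n",
              x$seq1$id, x$seq2$id, length(x$i), nrow(alignment_edges(x)),
              x$mode))
  n <- nchar(s[1])
  for (start in seq(1, n, by = width)) {
    end <- min(start + width - 1, n)
    cat(substr(s[1], start, end), "\n", substr(s[2], start, end), "\n",
        sep = "")
    if (end < n) cat("\n")
  }
  invisible(x)
}

same_sequence_pair <- function(a, b) {
  identical(a$seq1$residues, b$seq1$residues) &&
    identical(a$seq2$residues, b$seq2$residues)
}

#' Read a pairwise alignment from an aligned-FASTA file
#'
#' The first two records are used as the two alignment rows.
#'
#' @param path aligned-FASTA file.
#' @param mode mode tag for the resulting alignment.
#' @return A [pairwise_alignment()].
#' @export
read_alignment_fasta <- function(path, mode = "reference") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) stop("need two aligned records in ", path,
                            call. = FALSE)
  alignment_from_strings(as.character(set[[1]]), as.character(set[[2]]),
                         id1 = sub("\\s.*$", "", names(set)[1]),
                         id2 = sub("\\s.*$", "", names(set)[2]),
                         mode = mode)
}

#' Write one or more pairwise alignments as aligned FASTA
#'
#' Each alignment contributes two records; an optional score is carried in
#' the record headers (`score=`).
#'
#' @param alns a [pairwise_alignment()] or list of them.
#' @param path output file.
#' @param scores optional numeric vector of per-alignment scores.
#' @export
write_alignment_fasta <- function(alns, path, scores = NULL) {
  if (inherits(alns, "pairwise_alignment")) alns <- list(alns)
  rows <- character(0)
  nms <- character(0)
  for (k in seq_along(alns)) {
    s <- aligned_strings(alns[[k]])
    tag <- if (!is.null(scores)) sprintf(" score=%g", scores[k]) else ""
    pre <- if (length(alns) > 1) sprintf("aln%d|", k) else ""
    nms <- c(nms, paste0(pre, alns[[k]]$seq1$id, tag),
             paste0(pre, alns[[k]]$seq2$id, tag))
    rows <- c(rows, s)
  }
  set <- Biostrings::BStringSet(rows)
  names(set) <- nms
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Fraction of identical aligned residue pairs
#'
#' By default identities are divided by the total number of alignment
#' columns, gaps included; set `denominator = "matches"` to divide by the
#' number of MATCH columns only.
#'
#' @param aln a [pairwise_alignment()].
#' @param denominator `"columns"` (default) or `"matches"`.
#' @return A fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln, denominator = c("columns", "matches")) {
  denominator <- match.arg(denominator)
  if (length(aln$i) == 0) stop("alignment has no columns", call. = FALSE)
  e <- alignment_edges(aln)
  ident <- sum(aln$seq1$residues[e[, 1]] == aln$seq2$residues[e[, 2]])
  den <- if (denominator == "columns") length(aln$i) else nrow(e)
  if (den == 0) stop("alignment has no MATCH columns", call. = FALSE)
  ident / den
}

#' Convert an alignment score to bits per alignment column
#'
#' @param score alignment score in matrix-native units.
#' @param aln the scored [pairwise_alignment()].
#' @param scheme the [scoring_scheme()] whose units the score is in.
#' @return `score * bits_per_unit / ncol`.
#' @export
bits_per_position <- function(score, aln, scheme) {
  ncols <- length(aln$i)
  if (ncols == 0) stop("alignment has no columns", call. = FALSE)
  score * scheme$bits_per_unit / ncols
}

#' Score an existing alignment under a scoring scheme
#'
#' Sums substitution scores over MATCH columns and affine gap costs
#' (`gap_open + k * gap_extend` for a maximal run of k gap columns in one
#' sequence) over gap runs. In semiglobal mode terminal gap columns --
#' every gap column before the first MATCH or after the last MATCH --
#' cost nothing, so a fully staggered all-gap alignment scores 0; in
#' local mode all gaps are charged.
#'
#' @param aln a [pairwise_alignment()].
#' @param scheme a [scoring_scheme()].
#' @param mode `"semiglobal"` or `"local"`.
#' @return Numeric score in matrix-native units.
#' @export
score_existing_alignment <- function(aln, scheme,
                                     mode = c("semiglobal", "local")) {
  mode <- match.arg(mode)
  ncols <- length(aln$i)
  if (ncols == 0) return(0)
  S <- match_score_matrix(aln$seq1, aln$seq2, scheme)
  e <- alignment_edges(aln)
  total <- if (nrow(e)) sum(S[e]) else 0
  is_match <- !is.na(aln$i) & !is.na(aln$j)
  interior <- if (any(is_match)) {
    seq(min(which(is_match)), max(which(is_match)))
  } else integer(0)
  # maximal runs of gap columns, per gapped sequence
  gap_in_2 <- is.na(aln$j) # DELETE columns
  gap_in_1 <- is.na(aln$i) # INSERT columns
  runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cbind(start = starts[r$values], len = r$lengths[r$values])
  }
  for (mask in list(gap_in_2, gap_in_1)) {
    rr <- runs(mask)
    if (nrow(rr) == 0) next
    for (k in seq_len(nrow(rr))) {
      terminal <- !(rr[k, "start"] %in% interior)
      if (mode == "semiglobal" && terminal) next
      total <- total + scheme$gap_open + rr[k, "len"] * scheme$gap_extend
    }
  }
  unname(total)
}
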