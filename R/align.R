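path_to_alignment <- function(path, s1, s2, mode) {
  i <- path[1, ]
  j <- path[2, ]
  i[i == 0] <- NA_integer_
  j[j == 0] <- NA_integer_
  pairwise_alignment(s1, s2, i, j, mode = mode)
}

dp_result <- function(alignment, score, local_bounds = NULL) {
  structure(list(alignment = alignment, score = score,
                 local_bounds = local_bounds),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("<dp_result> score %g (%s)\n", x$score, x$alignment$mode))
  if (!is.null(x$local_bounds)) {
    b <- x$local_bounds
    cat(sprintf("  local bounds: seq1 %d-%d, seq2 %d-%d\n",
                b["i_start"], b["i_end"], b["j_start"], b["j_end"]))
  }
  print(x$alignment)
  invisible(x)
}

#' Optimal semi-global alignment (free end gaps)
#'
#' Needleman-Wunsch global alignment over both full sequences in which the
#' terminal gap runs cost nothing. Interior gaps are affine:
#' `gap_open + k * gap_extend` for a gap of length k. Traceback ties are
#' broken with the fixed priority MATCH > DELETE > INSERT, so results are
#' deterministic.
#'
#' @param s1,s2 [residue_sequence()] objects (or plain strings).
#' @param scheme a [scoring_scheme()].
#' @return A `dp_result` with fields `alignment` (a
#'   [pairwise_alignment()]) and `score` (matrix-native units).
#' @examples
#' scheme <- scoring_scheme("BLOSUM50", -10, -2)
#' align_semiglobal("ACDE", "ACDE", scheme)$score # 32
#' @export
align_semiglobal <- function(s1, s2, scheme) {
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  S <- match_score_matrix(s1, s2, scheme)
  res <- cpp_semiglobal(S, scheme$gap_open, scheme$gap_extend)
  aln <- path_to_alignment(res$path, s1, s2, "semiglobal")
  dp_result(aln, res$score)
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Maximum-scoring local alignment under the same affine gap model as
#' [align_semiglobal()]. The alignment starts and ends with a MATCH
#' column; if no residue pair scores positively the result is an empty
#' alignment with score 0.
#'
#' @inheritParams align_semiglobal
#' @return A `dp_result`; `local_bounds` holds the start/end residue
#'   coordinates `(i_start, j_start, i_end, j_end)`, or `NA`s when the
#'   alignment is empty.
#' @export
align_local <- function(s1, s2, scheme) {
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  S <- match_score_matrix(s1, s2, scheme)
  res <- cpp_local(S, scheme$gap_open, scheme$gap_extend)
  bounds <- setNames(as.integer(res$bounds),
                     c("i_start", "j_start", "i_end", "j_end"))
  if (ncol(res$path) == 0) {
    aln <- structure(list(seq1 = s1, seq2 = s2, i = integer(0),
                          j = integer(0), mode = "local"),
                     class = "pairwise_alignment")
  } else {
    aln <- path_to_alignment(res$path, s1, s2, "local")
  }
  dp_result(aln, res$score, local_bounds = bounds)
}

as_residue_sequence <- function(x, default_id) {
  if (inherits(x, "residue_sequence")) return(x)
  residue_sequence(x, id = default_id)
}
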