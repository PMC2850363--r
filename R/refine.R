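#' Trim specification for unreliable-edge removal
#'
#' @param criterion which per-edge score drives the trim:
#'   `"model_probability"` (default threshold 0.5), `"robustness_norm"`,
#'   `"frequency"`, `"local_region"`, or `"combined"` (local-region trim
#'   followed by a model-probability trim).
#' @param threshold edges scoring below this are gapped out.
#' @return A `trim_spec` object.
#' @export
trim_spec <- function(criterion = c("model_probability", "robustness_norm",
                                    "frequency", "local_region", "combined"),
                      threshold = 0.5) {
  criterion <- match.arg(criterion)
  if (criterion %in% c("model_probability", "robustness_norm", "frequency") &&
      (threshold < 0 || threshold > 1)) {
    stop("threshold must be in [0, 1] for criterion '", criterion, "'",
         call. = FALSE)
  }
  structure(list(criterion = criterion, threshold = threshold),
            class = "trim_spec")
}

# Reorder each maximal run of gap columns so DELETE columns precede
# INSERT columns (A/V trimmed to A-/-V, runs merged deterministically).
canonicalize_gaps <- function(i, j) {
  is_gap <- is.na(i) | is.na(j)
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    del <- idx[!is.na(i[idx])]
    ins <- idx[!is.na(j[idx])]
    i[idx] <- c(i[del], rep(NA_integer_, length(ins)))
    j[idx] <- c(rep(NA_integer_, length(del)), j[ins])
  }
  list(i = i, j = j)
}

gap_out_matches <- function(aln, drop, mode = "trimmed") {
  # each dropped MATCH column (i, j) becomes DELETE(i) then INSERT(j)
  new_i <- list()
  new_j <- list()
  for (k in seq_along(aln$i)) {
    if (drop[k]) {
      new_i[[length(new_i) + 1]] <- c(aln$i[k], NA_integer_)
      new_j[[length(new_j) + 1]] <- c(NA_integer_, aln$j[k])
    } else {
      new_i[[length(new_i) + 1]] <- aln$i[k]
      new_j[[length(new_j) + 1]] <- aln$j[k]
    }
  }
  cc <- canonicalize_gaps(unlist(new_i), unlist(new_j))
  pairwise_alignment(aln$seq1, aln$seq2, cc$i, cc$j, mode = mode)
}

#' Remove unreliable edges from an alignment
#'
#' Every MATCH column whose score falls below the threshold is replaced
#' by a DELETE column followed by an INSERT column, so both sequences
#' keep their full residue content and no new edges are introduced.
#' Adjacent replacements are merged into runs (all deletes, then all
#' inserts). The operation is idempotent for a fixed score map and
#' threshold.
#'
#' @param aln a [pairwise_alignment()].
#' @param scores per-edge scores: a data frame with columns `i`, `j` and
#'   a score column (`probability`, `score`, or the third column), or a
#'   numeric matrix indexed `[i, j]`. Every MATCH edge of `aln` must be
#'   covered.
#' @param spec a [trim_spec()]; only its `threshold` is used here.
#' @return The trimmed [pairwise_alignment()] (mode `"trimmed"`).
#' @export
trim_alignment <- function(aln, scores, spec = trim_spec()) {
  e <- alignment_edges(aln)
  if (nrow(e) == 0) return(aln)
  if (is.matrix(scores)) {
    vals <- scores[e]
  } else {
    df <- as.data.frame(scores)
    score_col <- intersect(c("probability", "score"), names(df))
    score_col <- if (length(score_col)) score_col[1] else names(df)[3]
    key <- paste(df$i, df$j, sep = ":")
    vals <- df[[score_col]][match(edge_keys(e), key)]
  }
  if (any(is.na(vals))) {
    missing <- edge_keys(e)[is.na(vals)]
    stop("no score for MATCH edge(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  }
  below <- vals < spec$threshold
  drop <- rep(FALSE, length(aln$i))
  drop[!is.na(aln$i) & !is.na(aln$j)] <- below
  if (!any(drop)) {
    aln$mode <- "trimmed"
    return(aln)
  }
  gap_out_matches(aln, drop)
}

#' Trim a semi-global alignment to the local alignment boundaries
#'
#' MATCH columns whose coordinates fall outside the local
#' (Smith-Waterman) alignment's start/end residue ranges are gapped out
#' with the same DELETE-then-INSERT replacement as [trim_alignment()];
#' interior columns are untouched. This removes the poorly determined
#' alignment ends while keeping full residue coverage.
#'
#' @param semiglobal a semi-global [pairwise_alignment()].
#' @param local the `dp_result` of [align_local()] on the same pair (or
#'   a named vector `i_start`, `j_start`, `i_end`, `j_end`).
#' @return The trimmed [pairwise_alignment()].
#' @export
trim_to_local_region <- function(semiglobal, local) {
  b <- if (inherits(local, "dp_result")) {
    if (!is.null(local$alignment$seq1$residues) &&
        !same_sequence_pair(local$alignment, semiglobal) &&
        length(local$alignment$i) > 0) {
      stop("local alignment is over a different sequence pair",
           call. = FALSE)
    }
    local$local_bounds
  } else local
  if (any(is.na(b))) {
    stop("local alignment is empty; no boundaries to trim to",
         call. = FALSE)
  }
  drop <- !is.na(semiglobal$i) & !is.na(semiglobal$j) &
    (semiglobal$i < b["i_start"] | semiglobal$i > b["i_end"] |
       semiglobal$j < b["j_start"] | semiglobal$j > b["j_end"])
  if (!any(drop)) {
    semiglobal$mode <- "trimmed"
    return(semiglobal)
  }
  gap_out_matches(semiglobal, drop)
}

#' Generate an alignment from model probabilities
#'
#' Runs the semi-global dynamic programming with the model-predicted
#' edge probability (or, optionally, the logit) as the score of the
#' MATCH move at every cell, in place of the substitution matrix, with
#' affine gap penalties (default -10/-2). Because the DP is free to pick
#' any path, the result can contain correct edges that the optimal
#' sequence alignment misses.
#'
#' @inheritParams align_semiglobal
#' @param coeffs a [logistic_coefficients()] object.
#' @param features an [edge_feature_table()] for the pair; edges missing
#'   from the table are scored with `f = 0`, `r = 0`, `m = 0`.
#' @param gap_open,gap_extend affine gap penalties on the probability
#'   scale.
#' @param score `"probability"` (default) or `"logit"`.
#' @return A `dp_result` whose score is the summed edge score minus gap
#'   costs (mode `"model_guided"`).
#' @export
model_guided_align <- function(s1, s2, coeffs, features,
                               gap_open = -10, gap_extend = -2,
                               score = c("probability", "logit")) {
  score <- match.arg(score)
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  n <- length(s1$residues)
  m <- length(s2$residues)
  pred <- predict_edge_probability(coeffs, features$frequency,
                                   features$robustness_norm,
                                   features$max_bpp_norm)
  base <- predict_edge_probability(coeffs, 0, 0, 0)[[score]]
  S <- matrix(base, nrow = n, ncol = m)
  S[cbind(features$i, features$j)] <- pred[[score]]
  if (!all(is.finite(S))) stop("non-finite edge score", call. = FALSE)
  res <- cpp_semiglobal(S, gap_open, gap_extend)
  aln <- path_to_alignment(res$path, s1, s2, "model_guided")
  dp_result(aln, res$score)
}
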