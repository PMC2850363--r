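#' Best alignment score through every edge (Zuker through-scores)
#'
#' For every cell (i, j) of the path graph, computes the score of the best
#' semi-global alignment constrained to contain the edge (i, j), by
#' stitching forward and backward affine dynamic-programming matrices at
#' the MATCH transition. The through-score matrix satisfies
#' `T(i, j) <= s_opt`, with equality attained by every edge of an optimal
#' alignment.
#'
#' @inheritParams align_semiglobal
#' @return An `edge_score_matrix`: list with `through` (n x m numeric
#'   matrix) and `s_opt` (optimal semi-global score).
#' @export
edge_best_scores <- function(s1, s2, scheme) {
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  S <- match_score_matrix(s1, s2, scheme)
  z <- cpp_zuker(S, scheme$gap_open, scheme$gap_extend)
  structure(list(through = z$through, s_opt = z$s_opt,
                 robustness = z$robustness, seq1 = s1, seq2 = s2,
                 scheme = scheme),
            class = "edge_score_matrix")
}

#' @export
print.edge_score_matrix <- function(x, ...) {
  cat(sprintf("<edge_score_matrix> %d x %d, s_opt = %g\n",
              nrow(x$through), ncol(x$through), x$s_opt))
  invisible(x)
}

#' Percent-of-optimal neighborhood specification
#'
#' @param fraction fraction of the optimal score, in (0, 1]; e.g. 0.75
#'   for the "75% of optimal" neighborhood.
#' @param scheme a [scoring_scheme()].
#' @return A `neighborhood_spec` object.
#' @export
neighborhood_spec <- function(fraction = 0.75,
                              scheme = scoring_scheme("BLOSUM50", -10, -2)) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(fraction = fraction, scheme = scheme),
            class = "neighborhood_spec")
}

#' Sample the near-optimal alignment neighborhood (Zuker sampling)
#'
#' For every edge whose through-score is at least `fraction * s_opt`, one
#' alignment containing that edge is produced by deterministic
#' bidirectional traceback; duplicates are removed. The pool therefore
#' covers every near-optimal edge (the Zuker guarantee) and always
#' contains an optimal alignment, but is only a sample of all
#' near-optimal alignments.
#'
#' Percent-of-optimal thresholds are meaningless when the optimal score is
#' not positive, so such pairs are refused.
#'
#' @inheritParams align_semiglobal
#' @param spec a [neighborhood_spec()].
#' @return A `neighborhood_pool`: list with `alignments` (list of
#'   [pairwise_alignment()]), `scores`, `s_opt`, `threshold` and `spec`.
#' @export
sample_neighborhood <- function(s1, s2, spec = neighborhood_spec()) {
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  scheme <- spec$scheme
  S <- match_score_matrix(s1, s2, scheme)
  z <- cpp_zuker(S, scheme$gap_open, scheme$gap_extend)
  if (z$s_opt <= 0) {
    stop("optimal score is not positive (s_opt = ", z$s_opt,
         "); a percent-of-optimal neighborhood is undefined", call. = FALSE)
  }
  threshold <- spec$fraction * z$s_opt
  pool <- cpp_pool(S, scheme$gap_open, scheme$gap_extend, threshold)
  alignments <- lapply(pool$paths, path_to_alignment, s1 = s1, s2 = s2,
                       mode = "semiglobal")
  structure(list(alignments = alignments, scores = as.numeric(pool$scores),
                 s_opt = pool$s_opt, threshold = threshold, spec = spec,
                 seq1 = s1, seq2 = s2),
            class = "neighborhood_pool")
}

#' @export
print.neighborhood_pool <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_pool> %d alignments at >= %.0f%% of optimal (s_opt %g)\n",
    length(x$alignments), 100 * x$spec$fraction, x$s_opt))
  invisible(x)
}

#' @export
length.neighborhood_pool <- function(x) length(x$alignments)

# union of edges over pool members, with per-edge member counts
pool_edge_counts <- function(pool) {
  all_edges <- do.call(rbind, lapply(pool$alignments, alignment_edges))
  keys <- edge_keys(all_edges)
  counts <- table(keys)
  first <- !duplicated(keys)
  data.frame(i = all_edges[first, 1], j = all_edges[first, 2],
             count = as.integer(counts[keys[first]]))
}

#' Alignment envelope of a neighborhood pool
#'
#' For each residue of either sequence, the minimum and maximum partner
#' index over all MATCH columns of the pool members; residues never
#' matched get `NA` bounds. The envelope brackets the region of the path
#' graph that the pool explores.
#'
#' @param pool a `neighborhood_pool` from [sample_neighborhood()].
#' @return An `alignment_envelope`: list of two data frames (`seq1`,
#'   `seq2`) with columns `residue`, `min_partner`, `max_partner`.
#' @export
alignment_envelope <- function(pool) {
  if (!inherits(pool, "neighborhood_pool") || length(pool$alignments) == 0) {
    stop("need a non-empty neighborhood pool", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(pool$alignments, alignment_edges))
  env_for <- function(pos, partner, len) {
    mn <- tapply(partner, pos, min)
    mx <- tapply(partner, pos, max)
    out <- data.frame(residue = seq_len(len), min_partner = NA_integer_,
                      max_partner = NA_integer_)
    idx <- as.integer(names(mn))
    out$min_partner[idx] <- as.integer(mn)
    out$max_partner[idx] <- as.integer(mx)
    out
  }
  structure(list(
    seq1 = env_for(edges[, 1], edges[, 2], length(pool$seq1$residues)),
    seq2 = env_for(edges[, 2], edges[, 1], length(pool$seq2$residues))
  ), class = "alignment_envelope")
}

#' Write a neighborhood pool as multi-record aligned FASTA
#'
#' @param pool a `neighborhood_pool`.
#' @param path output file; each member contributes two records with the
#'   member score in the header.
#' @export
write_pool_fasta <- function(pool, path) {
  write_alignment_fasta(pool$alignments, path, scores = pool$scores)
}

#' Write an alignment envelope as TSV
#'
#' One row per residue of each sequence: `sequence`, `residue`,
#' `min_partner`, `max_partner`.
#'
#' @param envelope an `alignment_envelope`.
#' @param path output file.
#' @export
write_envelope_tsv <- function(envelope, path) {
  df <- rbind(cbind(sequence = "seq1", envelope$seq1),
              cbind(sequence = "seq2", envelope$seq2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
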