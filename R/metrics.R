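#' Shift score parameters
#'
#' @param epsilon the mismatch floor; the score ranges over
#'   `[-epsilon, 1]`. Default 0.2, the published value.
#' @return A `shift_score_params` object.
#' @export
shift_score_params <- function(epsilon = 0.2) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0) {
    stop("epsilon must be a single number >= 0", call. = FALSE)
  }
  structure(list(epsilon = epsilon), class = "shift_score_params")
}

#' Shift score between two alignments of the same sequence pair
#'
#' The Cline shift score rewards small positional displacements of
#' aligned partners instead of demanding exact column identity. Every
#' residue aligned in one alignment contributes one term per alignment
#' it is aligned in: `(1 + eps) / (1 + |shift|) - eps` when the residue
#' is aligned in both (where the shift is the displacement of its
#' partner between the two alignments), and `-eps` when it is aligned in
#' only one. The sum is divided by the total number of aligned-residue
#' instances in both alignments, giving a symmetric score in
#' `[-eps, 1]`: 1 exactly for identical edge sets, `-eps` when the
#' aligned-residue sets are disjoint.
#'
#' @param a,b [pairwise_alignment()]s over the same sequence pair.
#' @param params a [shift_score_params()].
#' @return A number in `[-epsilon, 1]`.
#' @examples
#' aln <- alignment_from_strings("ACDE", "ACDE")
#' shift_score(aln, aln) # 1
#' @export
shift_score <- function(a, b, params = shift_score_params()) {
  if (!same_sequence_pair(a, b)) {
    stop("alignments are over different sequence pairs", call. = FALSE)
  }
  eps <- params$epsilon
  n <- length(a$seq1$residues)
  m <- length(a$seq2$residues)
  partner_maps <- function(aln) {
    e <- alignment_edges(aln)
    p1 <- rep(NA_integer_, n) # seq1 position -> seq2 partner
    p2 <- rep(NA_integer_, m) # seq2 position -> seq1 partner
    if (nrow(e)) {
      p1[e[, 1]] <- e[, 2]
      p2[e[, 2]] <- e[, 1]
    }
    list(p1 = p1, p2 = p2)
  }
  pa <- partner_maps(a)
  pb <- partner_maps(b)
  side <- function(pma, pmb) {
    aligned_a <- !is.na(pma)
    both <- aligned_a & !is.na(pmb)
    only_a <- aligned_a & is.na(pmb)
    sum((1 + eps) / (1 + abs(pma[both] - pmb[both])) - eps) -
      eps * sum(only_a)
  }
  num <- side(pa$p1, pb$p1) + side(pa$p2, pb$p2) + # residues aligned in a
    side(pb$p1, pa$p1) + side(pb$p2, pa$p2)        # residues aligned in b
  den <- 2 * nrow(alignment_edges(a)) + 2 * nrow(alignment_edges(b))
  if (den == 0) stop("both alignments have no MATCH columns", call. = FALSE)
  num / den
}

#' Per-edge confusion counts of a candidate alignment
#'
#' Candidate MATCH edges are labelled with [label_edges()] against the
#' references ("k of n" rule): true positives are candidate edges present
#' in at least `k` references, false positives the rest. False negatives
#' are reference-positive edges absent from the candidate.
#'
#' @param candidate a [pairwise_alignment()].
#' @param references list of reference alignments over the same pair.
#' @param k minimum number of references for an edge to count as
#'   positive (default 2).
#' @return An `edge_confusion`: list with `true_positives`,
#'   `false_positives`, `false_negatives`, `tp_fraction`
#'   (TP / (TP + FP), `NaN` when the candidate has no edges).
#' @export
edge_confusion <- function(candidate, references, k = 2) {
  for (r in references) {
    if (!same_sequence_pair(candidate, r)) {
      stop("candidate and references are over different sequence pairs",
           call. = FALSE)
    }
  }
  ce <- alignment_edges(candidate)
  # positive edge set: edges present in >= k references
  all_ref <- do.call(rbind, lapply(references, alignment_edges))
  rk <- edge_keys(all_ref)
  counts <- table(rk)
  pos_keys <- names(counts)[counts >= k]
  if (nrow(ce)) {
    lab <- label_edges(ce, references, k = k)
    tp <- sum(lab$y == 1)
    fp <- sum(lab$y == 0)
    fn <- sum(!(pos_keys %in% edge_keys(ce)))
  } else {
    tp <- 0L
    fp <- 0L
    fn <- length(pos_keys)
  }
  structure(list(true_positives = as.integer(tp),
                 false_positives = as.integer(fp),
                 false_negatives = as.integer(fn),
                 tp_fraction = tp / (tp + fp)),
            class = "edge_confusion")
}

#' @export
print.edge_confusion <- function(x, ...) {
  cat(sprintf("<edge_confusion> TP %d, FP %d, FN %d (TP fraction %.3f)\n",
              x$true_positives, x$false_positives, x$false_negatives,
              x$tp_fraction))
  invisible(x)
}

#' Better/worse summary over per-pair metric deltas
#'
#' Given a metric measured before and after an intervention on each
#' pair, counts the pairs that strictly improved and strictly worsened
#' (ties count in neither) and reports the mean and standard deviation
#' of the positive and negative deltas separately.
#'
#' @param per_pair_deltas data frame (or two-column matrix) with columns
#'   `before` and `after`.
#' @return Data frame with one row: `better`, `worse`, `better_mean`,
#'   `better_sd`, `worse_mean`, `worse_sd`.
#' @export
pair_summary <- function(per_pair_deltas) {
  df <- as.data.frame(per_pair_deltas)
  if (nrow(df) == 0) stop("no pairs to summarize", call. = FALSE)
  if (!all(c("before", "after") %in% names(df))) {
    names(df)[1:2] <- c("before", "after")
  }
  delta <- df$after - df$before
  up <- delta[delta > 0]
  down <- delta[delta < 0]
  data.frame(
    better = length(up), worse = length(down),
    better_mean = if (length(up)) mean(up) else 0,
    better_sd = if (length(up) > 1) sd(up) else 0,
    worse_mean = if (length(down)) mean(down) else 0,
    worse_sd = if (length(down) > 1) sd(down) else 0)
}
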