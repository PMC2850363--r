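# shared fixtures, built in code

bl50 <- scoring_scheme("BLOSUM50", gap_open = -10, gap_extend = -2)
bl62 <- scoring_scheme("BLOSUM62", gap_open = -11, gap_extend = -1)

# two alignments of one 4+4 pair whose aligned-residue sets are disjoint
disjoint_alignment_pair <- function() {
  s1 <- residue_sequence("ACDE", id = "s1")
  s2 <- residue_sequence("FGHI", id = "s2")
  a <- pairwise_alignment(s1, s2,
                          i = c(1, 2, 3, 4, NA, NA),
                          j = c(1, 2, NA, NA, 3, 4), mode = "reference")
  b <- pairwise_alignment(s1, s2,
                          i = c(1, 2, NA, NA, 3, 4),
                          j = c(NA, NA, 1, 2, 3, 4), mode = "reference")
  list(a = a, b = b)
}

# lazily built benchmark shared by the heavier tests (built once per run)
.bench_cache <- new.env(parent = emptyenv())
benchmark_small <- function() {
  if (is.null(.bench_cache$set)) {
    .bench_cache$set <- generate_benchmark_set(
      n_pairs = 20, ancestor_length = 100, seed = 20100322)
  }
  .bench_cache$set
}

# per-pair evaluation bundle used by model/refine benchmark tests
.pair_eval_cache <- new.env(parent = emptyenv())
evaluate_benchmark_pair <- function(pair, id, scheme = bl50) {
  if (!is.null(.pair_eval_cache[[id]])) return(.pair_eval_cache[[id]])
  features <- edge_feature_table(pair$seq1, pair$seq2, scheme)
  opt <- align_semiglobal(pair$seq1, pair$seq2, scheme)
  loc <- align_local(pair$seq1, pair$seq2, scheme)
  labels <- label_edges(features[, c("i", "j")], pair$references, k = 2)
  res <- list(features = features, opt = opt, loc = loc, labels = labels)
  .pair_eval_cache[[id]] <- res
  res
}
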