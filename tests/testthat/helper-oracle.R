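# Independent exhaustive-enumeration oracle for small alignment problems.
#
# An alignment of an (n, m) pair is a string over {M, D, I} with n
# M+D symbols and m M+I symbols. All such strings are enumerated once
# per shape and cached; each carries its MATCH-column edge list and the
# affine gap cost of its gap runs (which depends only on the shape).
# Scores are then just sums over a substitution matrix, so the oracle
# shares no code with the package's dynamic programming.

.shape_cache <- new.env(parent = emptyenv())

# all alignments of an (n, m) pair: list of list(sym, edges) where
# edges is a 2-column matrix of matched (i, j) positions
enumerate_shapes <- function(n, m) {
  key <- paste(n, m, sep = "x")
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  out <- vector("list", 0)
  recurse <- function(i, j, sym) {
    if (i == n && j == m) {
      s <- sym
      takes1 <- s != "I"
      takes2 <- s != "D"
      ii <- cumsum(takes1)
      jj <- cumsum(takes2)
      keep <- s == "M"
      # gap "cost" cached per unit penalty: (runs, gapped columns), for
      # free-end and all-charged conventions
      runs_free <- oracle_gap_runs(s, free_ends = TRUE)
      runs_all <- oracle_gap_runs(s, free_ends = FALSE)
      out[[length(out) + 1]] <<- list(
        sym = s, edges = cbind(ii[keep], jj[keep]),
        runs_free = runs_free, runs_all = runs_all)
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, c(sym, "M"))
    if (i < n) recurse(i + 1, j, c(sym, "D"))
    if (j < m) recurse(i, j + 1, c(sym, "I"))
    invisible()
  }
  recurse(0, 0, character(0))
  .shape_cache[[key]] <- out
  out
}

# number of charged gap runs and charged gap columns of a symbol vector
oracle_gap_runs <- function(sym, free_ends = TRUE) {
  n_runs <- 0
  n_cols <- 0
  mpos <- which(sym == "M")
  lo <- if (length(mpos)) min(mpos) else Inf
  hi <- if (length(mpos)) max(mpos) else -Inf
  for (g in c("D", "I")) {
    r <- rle(sym == g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      if (free_ends && (ends[k] < lo || starts[k] > hi)) next
      n_runs <- n_runs + 1
      n_cols <- n_cols + r$lengths[k]
    }
  }
  c(n_runs, n_cols)
}

oracle_scores <- function(S, go, ge, free_ends = TRUE) {
  shapes <- enumerate_shapes(nrow(S), ncol(S))
  vapply(shapes, function(sh) {
    edge_sum <- if (nrow(sh$edges)) sum(S[sh$edges]) else 0
    runs <- if (free_ends) sh$runs_free else sh$runs_all
    edge_sum + runs[1] * go + runs[2] * ge
  }, numeric(1))
}

# best semi-global score by brute force
oracle_semiglobal <- function(S, go, ge) {
  max(oracle_scores(S, go, ge, free_ends = TRUE))
}

# through-scores T(i,j), avoid-scores and robustness by brute force
oracle_edge_analysis <- function(S, go, ge) {
  n <- nrow(S)
  m <- ncol(S)
  shapes <- enumerate_shapes(n, m)
  scores <- oracle_scores(S, go, ge, free_ends = TRUE)
  through <- matrix(-Inf, n, m)
  avoid <- matrix(-Inf, n, m)
  for (k in seq_along(shapes)) {
    e <- shapes[[k]]$edges
    s <- scores[k]
    inA <- matrix(FALSE, n, m)
    if (nrow(e)) inA[e] <- TRUE
    through[inA] <- pmax(through[inA], s)
    avoid[!inA] <- pmax(avoid[!inA], s)
  }
  list(s_opt = max(scores), through = through, avoid = avoid,
       robustness = through - avoid)
}

# best local alignment score by brute force: all sub-rectangles, all
# alignments of each, every gap charged
oracle_local <- function(S, go, ge) {
  n <- nrow(S)
  m <- ncol(S)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      sub <- S[i1:i2, j1:j2, drop = FALSE]
      best <- max(best, max(oracle_scores(sub, go, ge, free_ends = FALSE)))
    }
  }
  best
}

random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                    "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
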