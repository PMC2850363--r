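#' Edge robustness: through-score minus best avoiding score
#'
#' The robustness of an edge is the best semi-global score of an
#' alignment containing the edge minus the best score over all alignments
#' that do not contain it. It is positive exactly when the edge occurs in
#' every optimal alignment, and is computed exactly: every alignment
#' either matches residue i of sequence 1 to some column or deletes it,
#' so the avoiding score is the maximum of the other through-scores in
#' row i and the best score among alignments that delete residue i.
#'
#' @inheritParams align_semiglobal
#' @param edges optional two-column matrix/data frame of edges `(i, j)`;
#'   default all n x m edges.
#' @return Data frame with columns `i`, `j`, `robustness_raw`
#'   (matrix-native score units).
#' @export
robustness <- function(s1, s2, scheme, edges = NULL) {
  esm <- edge_best_scores(s1, s2, scheme)
  R <- esm$robustness
  if (is.null(edges)) {
    edges <- cbind(i = rep(seq_len(nrow(R)), ncol(R)),
                   j = rep(seq_len(ncol(R)), each = nrow(R)))
  } else {
    edges <- as.matrix(edges[, 1:2])
    if (any(edges[, 1] < 1 | edges[, 1] > nrow(R) |
            edges[, 2] < 1 | edges[, 2] > ncol(R))) {
      stop("edge positions outside sequence bounds", call. = FALSE)
    }
  }
  data.frame(i = as.integer(edges[, 1]), j = as.integer(edges[, 2]),
             robustness_raw = R[edges])
}

#' Edge frequency within a neighborhood pool
#'
#' @param pool a `neighborhood_pool` from [sample_neighborhood()].
#' @return Data frame `i`, `j`, `frequency` (member count / pool size)
#'   for every edge occurring in at least one pool member.
#' @export
edge_frequency <- function(pool) {
  if (!inherits(pool, "neighborhood_pool") || length(pool$alignments) == 0) {
    stop("need a non-empty neighborhood pool", call. = FALSE)
  }
  counts <- pool_edge_counts(pool)
  data.frame(i = counts$i, j = counts$j,
             frequency = counts$count / length(pool$alignments))
}

#' Maximum bits-per-position over pool members containing an edge
#'
#' For each edge seen in the pool, the highest bits-per-position score
#' (member score converted to bits, divided by member columns) among the
#' members that contain it. Edges absent from the pool are absent from
#' the result rather than zero.
#'
#' @param pool a `neighborhood_pool`.
#' @param scheme the [scoring_scheme()] the pool was built with (defaults
#'   to the pool's own scheme).
#' @return Data frame `i`, `j`, `max_bpp_raw`.
#' @export
edge_max_bpp <- function(pool, scheme = pool$spec$scheme) {
  if (!inherits(pool, "neighborhood_pool") || length(pool$alignments) == 0) {
    stop("need a non-empty neighborhood pool", call. = FALSE)
  }
  bpp <- vapply(seq_along(pool$alignments), function(k) {
    bits_per_position(pool$scores[k], pool$alignments[[k]], scheme)
  }, numeric(1))
  per_member <- lapply(seq_along(pool$alignments), function(k) {
    e <- alignment_edges(pool$alignments[[k]])
    data.frame(i = e[, 1], j = e[, 2], bpp = bpp[k])
  })
  all <- do.call(rbind, per_member)
  keys <- paste(all$i, all$j, sep = ":")
  mx <- tapply(all$bpp, keys, max)
  first <- !duplicated(keys)
  data.frame(i = all$i[first], j = all$j[first],
             max_bpp_raw = as.numeric(mx[keys[first]]))
}

#' Min-max normalize per-edge features over the pool's edge set
#'
#' Robustness and maximum bits-per-position are rescaled to `[0, 1]`
#' using the minimum and maximum raw values over the edges of the
#' suboptimal pool (rows with `in_pool = TRUE`); values for edges outside
#' the pool are clamped into `[0, 1]`. A constant feature maps to 0.5 by
#' convention. Frequency is already a fraction and passes through
#' unchanged. `max_bpp_norm` is `NA` for edges never seen in the pool;
#' the model layer imputes 0 for them.
#'
#' @param table an edge feature table (see [edge_feature_table()]).
#' @return The table with `robustness_norm` and `max_bpp_norm` columns
#'   filled in.
#' @export
normalize_features <- function(table) {
  if (nrow(table) == 0) stop("empty feature table", call. = FALSE)
  in_pool <- if ("in_pool" %in% names(table)) table$in_pool
             else table$frequency > 0
  minmax <- function(raw) {
    ref <- raw[in_pool & !is.na(raw)]
    if (length(ref) == 0) ref <- raw[!is.na(raw)]
    lo <- min(ref)
    hi <- max(ref)
    if (hi - lo < .Machine$double.eps^0.5) {
      out <- rep(0.5, length(raw))
      out[is.na(raw)] <- NA_real_
      return(out)
    }
    pmin(1, pmax(0, (raw - lo) / (hi - lo)))
  }
  table$robustness_norm <- minmax(table$robustness_raw)
  table$max_bpp_norm <- minmax(table$max_bpp_raw)
  table
}

#' Per-edge feature table: robustness, frequency, max bits-per-position
#'
#' Assembles the three predictors of the edge-reliability model for one
#' sequence pair: exact robustness for every edge of the n x m path
#' graph, and pool-derived frequency and maximum bits-per-position for
#' edges sampled in the percent-of-optimal neighborhood. Features are
#' min-max normalized per pair over the pool's edge set
#' ([normalize_features()]). `in_local_region` flags edges inside the
#' local (Smith-Waterman) alignment boundaries.
#'
#' @inheritParams align_semiglobal
#' @param fraction percent-of-optimal threshold for the pool
#'   (default 0.75).
#' @param pool optionally, a precomputed `neighborhood_pool`.
#' @param all_edges if `TRUE` (default) the table covers all n x m
#'   edges; otherwise only edges seen in the pool.
#' @return Data frame with columns `i`, `j`, `res1`, `res2`,
#'   `robustness_raw`, `robustness_norm`, `frequency`, `max_bpp_raw`,
#'   `max_bpp_norm`, `in_pool`, `in_local_region`.
#' @export
edge_feature_table <- function(s1, s2, scheme = scoring_scheme("BLOSUM50",
                                                               -10, -2),
                               fraction = 0.75, pool = NULL,
                               all_edges = TRUE) {
  s1 <- as_residue_sequence(s1, "seq1")
  s2 <- as_residue_sequence(s2, "seq2")
  if (is.null(pool)) {
    pool <- sample_neighborhood(s1, s2, neighborhood_spec(fraction, scheme))
  }
  rob <- robustness(s1, s2, scheme)
  freq <- edge_frequency(pool)
  mbpp <- edge_max_bpp(pool, scheme)
  key_all <- paste(rob$i, rob$j, sep = ":")
  key_freq <- paste(freq$i, freq$j, sep = ":")
  key_bpp <- paste(mbpp$i, mbpp$j, sep = ":")
  tab <- rob
  tab$frequency <- freq$frequency[match(key_all, key_freq)]
  tab$frequency[is.na(tab$frequency)] <- 0
  tab$max_bpp_raw <- mbpp$max_bpp_raw[match(key_all, key_bpp)]
  tab$in_pool <- tab$frequency > 0
  if (!all_edges) tab <- tab[tab$in_pool, , drop = FALSE]
  loc <- align_local(s1, s2, scheme)
  b <- loc$local_bounds
  tab$in_local_region <- if (any(is.na(b))) rep(FALSE, nrow(tab)) else {
    tab$i >= b["i_start"] & tab$i <= b["i_end"] &
      tab$j >= b["j_start"] & tab$j <= b["j_end"]
  }
  tab$res1 <- s1$residues[tab$i]
  tab$res2 <- s2$residues[tab$j]
  tab <- normalize_features(tab)
  rownames(tab) <- NULL
  tab[, c("i", "j", "res1", "res2", "robustness_raw", "robustness_norm",
          "frequency", "max_bpp_raw", "max_bpp_norm", "in_pool",
          "in_local_region")]
}

#' Write / read an edge feature table as TSV
#'
#' @param table an edge feature table.
#' @param path file path.
#' @export
write_feature_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
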