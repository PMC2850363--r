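#' Amino-acid scoring scheme with affine gap penalties
#'
#' Bundles a substitution matrix with affine gap penalties and the scale
#' factor that converts matrix-native score units to bits. The built-in
#' matrices are the NCBI BLOSUM50 and BLOSUM62 tables (as distributed with
#' Biostrings); BLOSUM50 is in 1/3-bit units and BLOSUM62 in 1/2-bit
#' units. A gap of length k costs `gap_open + k * gap_extend` (the
#' SSEARCH/FASTA convention), so the default -10/-2 scheme charges -12 for
#' a length-1 gap.
#'
#' @param matrix `"BLOSUM50"`, `"BLOSUM62"`, or a path to an NCBI-format
#'   matrix text file (see [read_score_matrix()]).
#' @param gap_open gap opening penalty, an integer <= 0.
#' @param gap_extend per-residue gap extension penalty, an integer <= 0.
#' @param bits_per_unit bits per matrix-native score unit. Filled in
#'   automatically for the built-in matrices (1/3 for BLOSUM50, 1/2 for
#'   BLOSUM62); defaults to 1/2 for matrices loaded from file.
#' @return A `scoring_scheme` object.
#' @examples
#' scheme <- scoring_scheme("BLOSUM50", gap_open = -10, gap_extend = -2)
#' scheme$scores["A", "A"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM50", gap_open = -10,
                           gap_extend = -2, bits_per_unit = NULL) {
  builtin <- c(BLOSUM50 = 1 / 3, BLOSUM62 = 1 / 2)
  if (is.character(matrix) && length(matrix) == 1 &&
      matrix %in% names(builtin)) {
    scores <- get_builtin_matrix(matrix)
    name <- matrix
    if (is.null(bits_per_unit)) bits_per_unit <- builtin[[matrix]]
  } else if (is.character(matrix) && length(matrix) == 1) {
    if (!file.exists(matrix)) {
      stop("unknown scoring matrix '", matrix,
           "': use BLOSUM50, BLOSUM62, or a path to an NCBI-format file",
           call. = FALSE)
    }
    scores <- read_score_matrix(matrix)
    name <- basename(matrix)
    if (is.null(bits_per_unit)) bits_per_unit <- 1 / 2
  } else if (is.matrix(matrix)) {
    scores <- matrix
    name <- "custom"
    if (is.null(bits_per_unit)) bits_per_unit <- 1 / 2
  } else {
    stop("'matrix' must be a matrix name, file path, or numeric matrix",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(scores, t(scores), check.attributes = FALSE))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be <= 0 (a gap of length k costs ",
         "gap_open + k * gap_extend)", call. = FALSE)
  }
  structure(
    list(matrix_name = name, scores = scores,
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
         bits_per_unit = bits_per_unit),
    class = "scoring_scheme"
  )
}

get_builtin_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  storage.mode(m) <- "numeric"
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by the NCBI toolkits (optional
#' `#` comment lines, a header row of residue letters, then one labelled
#' score row per residue).
#'
#' @param path file path.
#' @return A symmetric numeric matrix with residue-letter dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a matrix file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals[header, header, drop = FALSE]
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap open %g / extend %g, %s bits/unit\n",
              x$matrix_name, x$gap_open, x$gap_extend,
              format(x$bits_per_unit, digits = 4)))
  invisible(x)
}

# residues the package tolerates even when the matrix lacks them
TOLERATED_RESIDUES <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        "X", "B", "Z", "U")

# Per-pair match score lookup; residues absent from the matrix but in the
# tolerated set score 0 against everything, anything else is an error.
residue_scores <- function(seq, scheme) {
  res <- seq$residues
  known <- rownames(scheme$scores)
  bad <- which(!(res %in% known) & !(res %in% TOLERATED_RESIDUES))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d of sequence '%s'",
                 res[bad[1]], bad[1], seq$id), call. = FALSE)
  }
  res
}

# n x m matrix of match scores for a sequence pair under a scheme
match_score_matrix <- function(s1, s2, scheme) {
  r1 <- residue_scores(s1, scheme)
  r2 <- residue_scores(s2, scheme)
  known <- rownames(scheme$scores)
  k1 <- r1 %in% known
  k2 <- r2 %in% known
  S <- matrix(0, nrow = length(r1), ncol = length(r2))
  if (any(k1) && any(k2)) {
    S[k1, k2] <- scheme$scores[r1[k1], r2[k2], drop = FALSE]
  }
  S
}
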