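test_that("semiglobal alignment reproduces hand-computed scores", {
  r <- align_semiglobal("ACDE", "ACDE", bl50)
  expect_equal(r$score, 32) # 5 + 13 + 8 + 6 on the BLOSUM50 diagonal
  expect_equal(alignment_edges(r$alignment),
               cbind(i = 1:4, j = 1:4))

  r1 <- align_semiglobal("A", "A", bl50)
  expect_equal(r1$score, 5)
  expect_equal(length(r1$alignment), 1L)
})

test_that("semiglobal score equals exhaustive enumeration on small pairs", {
  set.seed(42)
  reduced <- c("A", "C", "D", "E")
  for (k in 1:25) {
    n <- sample(1:6, 1)
    m <- sample(1:6, 1)
    s1 <- random_protein(n, reduced)
    s2 <- random_protein(m, reduced)
    S <- bl50$scores[strsplit(s1, "")[[1]], strsplit(s2, "")[[1]],
                     drop = FALSE]
    expect_equal(align_semiglobal(s1, s2, bl50)$score,
                 oracle_semiglobal(S, -10, -2),
                 info = paste(s1, s2))
  }
})

test_that("optimal score is symmetric and monotone under extension", {
  set.seed(7)
  for (k in 1:10) {
    s1 <- random_protein(sample(3:8, 1))
    s2 <- random_protein(sample(3:8, 1))
    sc <- align_semiglobal(s1, s2, bl50)$score
    expect_equal(align_semiglobal(s2, s1, bl50)$score, sc)
    # appending an identical residue to both never decreases the score
    ext <- align_semiglobal(paste0(s1, "W"), paste0(s2, "W"), bl50)$score
    expect_gte(ext, sc)
  }
})

test_that("DP score round-trips through score_existing_alignment exactly", {
  set.seed(11)
  for (k in 1:10) {
    s1 <- random_protein(sample(4:12, 1))
    s2 <- random_protein(sample(4:12, 1))
    r <- align_semiglobal(s1, s2, bl50)
    expect_identical(score_existing_alignment(r$alignment, bl50), r$score)
  }
})

test_that("local alignment finds embedded exact match and honors bounds", {
  r <- align_local("ACDE", "QACDEQ", bl50)
  expect_equal(r$score, 32)
  expect_equal(unname(r$local_bounds), c(1L, 2L, 4L, 5L))
  expect_equal(aligned_strings(r$alignment), c("ACDE", "ACDE"))

  # no positive substitution score anywhere -> empty alignment, score 0
  sub <- matrix(-1, 3, 3)
  neg <- scoring_scheme(structure(sub, dimnames = list(c("A", "C", "D"),
                                                       c("A", "C", "D"))),
                        gap_open = -10, gap_extend = -2)
  r0 <- align_local("ACD", "DCA", neg)
  expect_equal(r0$score, 0)
  expect_equal(length(r0$alignment), 0L)
  expect_true(all(is.na(r0$local_bounds)))
})

test_that("local score equals brute force over all sub-alignments", {
  set.seed(13)
  for (k in 1:6) {
    s1 <- random_protein(4)
    s2 <- random_protein(5)
    S <- bl50$scores[strsplit(s1, "")[[1]], strsplit(s2, "")[[1]],
                     drop = FALSE]
    expect_equal(align_local(s1, s2, bl50)$score,
                 oracle_local(S, -10, -2), info = paste(s1, s2))
  }
})

test_that("existing-alignment scoring charges interior gaps, frees ends", {
  # fully staggered: both gap runs terminal, so worth 0
  stag <- alignment_from_strings("AC--", "--GT")
  expect_equal(score_existing_alignment(stag, bl50), 0)

  # hand-built: ACDEF / A-DEF has one interior length-1 gap
  aln <- alignment_from_strings("ACDEF", "A-DEF")
  manual <- bl50$scores["A", "A"] + (-10 + 1 * -2) +
    bl50$scores["D", "D"] + bl50$scores["E", "E"] + bl50$scores["F", "F"]
  expect_equal(score_existing_alignment(aln, bl50), manual)
  # terminal gaps are charged in local mode but free in semiglobal
  aln2 <- alignment_from_strings("ACDE-", "ACDEF")
  expect_equal(score_existing_alignment(aln2, bl50, mode = "local"),
               score_existing_alignment(aln2, bl50) + (-10 - 2))
})

test_that("malformed column orders are rejected", {
  s1 <- residue_sequence("ACD")
  s2 <- residue_sequence("ACD")
  expect_error(pairwise_alignment(s1, s2, i = c(2, 1, 3), j = c(1, 2, 3)),
               "strictly increasing")
  expect_error(pairwise_alignment(s1, s2, i = c(1, 2), j = c(1, 2)),
               "exactly once")
  expect_error(pairwise_alignment(s1, s2, i = c(1, NA, 2, 3),
                                  j = c(1, NA, 2, 3)),
               "gap in both")
})

test_that("percent identity supports both denominators", {
  ident <- alignment_from_strings("ACDE", "ACDE")
  expect_equal(percent_identity(ident), 1.0)
  near <- alignment_from_strings("ACDE", "ACDD")
  expect_equal(percent_identity(near), 0.75)
  gapped <- alignment_from_strings("ACD-E", "ACDDE")
  expect_equal(percent_identity(gapped), 4 / 5)
  expect_equal(percent_identity(gapped, denominator = "matches"), 1.0)
})

test_that("bits-per-position converts matrix-native units", {
  aln <- alignment_from_strings("ACDEFACDEF", "ACDEFACDEF")
  expect_equal(bits_per_position(30, aln, bl50), 1.0) # 30 third-bits / 10
  expect_equal(bits_per_position(0, aln, bl50), 0.0)
  expect_equal(bits_per_position(20, aln, bl62), 1.0) # 20 half-bits / 10
})

test_that("wildcard residues score zero, unknown residues error", {
  # U is tolerated but absent from BLOSUM50: contributes 0
  r <- align_semiglobal("AUC", "AUC", bl50)
  expect_equal(r$score, bl50$scores["A", "A"] + 0 + bl50$scores["C", "C"])
  expect_error(align_semiglobal("AJC", "AAC", bl50), "J.*position 2")
})

test_that("scoring scheme validates inputs", {
  expect_error(scoring_scheme("BLOSUM99"), "unknown scoring matrix")
  expect_error(scoring_scheme("BLOSUM50", gap_open = 10), "<= 0")
  asym <- matrix(c(1, 2, 3, 4), 2, 2,
                 dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(scoring_scheme(asym), "symmetric")
})

test_that("NCBI-format matrix files round-trip through the parser", {
  path <- tempfile(fileext = ".mat")
  writeLines(c("# toy matrix", "   A  C  D",
               "A  4 -1 -2", "C -1  9 -3", "D -2 -3  6"), path)
  m <- read_score_matrix(path)
  expect_equal(m["C", "C"], 9)
  expect_equal(m["A", "D"], m["D", "A"])
  scheme <- scoring_scheme(path, gap_open = -5, gap_extend = -1)
  expect_equal(align_semiglobal("ACD", "ACD", scheme)$score, 19)
})

test_that("local scores agree with an independent Smith-Waterman", {
  set.seed(77)
  for (k in 1:6) {
    s1 <- random_protein(15)
    s2 <- random_protein(18)
    mine <- align_local(s1, s2, bl50)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s1), Biostrings::AAString(s2), type = "local",
      substitutionMatrix = bl50$scores, gapOpening = 10, gapExtension = 2)
    expect_equal(mine, Biostrings::score(ref), info = paste(s1, s2))
  }
})
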