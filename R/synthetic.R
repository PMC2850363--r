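# Robinson & Robinson background amino-acid frequencies
BACKGROUND_FREQS <- local({
  f <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
         Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
         L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
         S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)
  f / sum(f)
})

#' Specification for a synthetic homologous sequence pair
#'
#' Describes how to simulate a pair of homologous protein sequences with
#' a known true alignment: an ancestor drawn from background amino-acid
#' frequencies, two descendants derived by independent per-site
#' substitution (with the substitution rate calibrated so the expected
#' identity over matched sites equals `target_identity`) and
#' geometric-length indels, plus a set of jittered copies of the true
#' alignment standing in for structure-based reference alignments.
#'
#' @param ancestor_length ancestor length in residues (>= 10).
#' @param target_identity expected fraction of identical residues over
#'   MATCH columns of the true alignment.
#' @param indel_rate per-site probability that an indel starts at a site
#'   in one lineage.
#' @param indel_length geometric success parameter for indel lengths
#'   (mean length `1/indel_length`).
#' @param n_references number of perturbed reference alignments
#'   (default 4, mirroring the four structure aligners behind the
#'   published 2-of-4 labeling rule).
#' @param reference_jitter maximum displacement, in columns, applied to
#'   each gap run when perturbing the true alignment into a reference.
#' @param seed RNG seed; generation is deterministic per seed.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(ancestor_length = 120, target_identity = 0.3,
                         indel_rate = 0.015, indel_length = 0.5,
                         n_references = 4, reference_jitter = 2,
                         seed = 1) {
  if (ancestor_length < 10) stop("ancestor_length must be >= 10",
                                 call. = FALSE)
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]", call. = FALSE)
  }
  if (indel_rate < 0 || indel_rate > 1 || indel_length <= 0 ||
      indel_length > 1) {
    stop("indel_rate must be in [0, 1] and indel_length in (0, 1]",
         call. = FALSE)
  }
  if (n_references < 1 || reference_jitter < 0) {
    stop("need n_references >= 1 and reference_jitter >= 0", call. = FALSE)
  }
  structure(list(ancestor_length = as.integer(ancestor_length),
                 target_identity = target_identity,
                 indel_rate = indel_rate, indel_length = indel_length,
                 n_references = as.integer(n_references),
                 reference_jitter = as.integer(reference_jitter),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Expected identity at a matched site when each lineage independently
# substitutes with probability p (replacement drawn from the background
# excluding the current residue).
expected_site_identity <- function(p, freqs = BACKGROUND_FREQS) {
  sum(vapply(seq_along(freqs), function(a) {
    d <- p * freqs / (1 - freqs[a])
    d[a] <- 1 - p
    freqs[a] * sum(d^2)
  }, numeric(1)))
}

calibrate_substitution_rate <- function(target) {
  floor_id <- expected_site_identity(1)
  if (target <= floor_id) {
    stop(sprintf(
      "target_identity %.3f is below the background coincidence floor %.3f",
      target, floor_id), call. = FALSE)
  }
  if (target >= 1) return(0)
  uniroot(function(p) expected_site_identity(p) - target,
          c(0, 1), tol = 1e-10)$root
}

sample_residues <- function(n) {
  sample(names(BACKGROUND_FREQS), n, replace = TRUE,
         prob = BACKGROUND_FREQS)
}

mutate_lineage <- function(ancestor, p) {
  n <- length(ancestor)
  out <- ancestor
  hit <- runif(n) < p
  for (k in which(hit)) {
    freqs <- BACKGROUND_FREQS
    freqs[ancestor[k]] <- 0
    out[k] <- sample(names(freqs), 1, prob = freqs / sum(freqs))
  }
  out
}

# presence vector over ancestor sites + inserted residues after each
# site (index a + 1 holds insertions after site a; index 1 = before
# site 1)
apply_indels <- function(residues, indel_rate, indel_length) {
  n <- length(residues)
  present <- rep(TRUE, n)
  inserts <- vector("list", n + 1)
  for (a in seq_len(n)) {
    if (runif(1) < indel_rate) {
      len <- rgeom(1, indel_length) + 1
      if (runif(1) < 0.5) {
        present[a:min(n, a + len - 1)] <- FALSE
      } else {
        inserts[[a + 1]] <- sample_residues(len)
      }
    }
  }
  list(present = present, inserts = inserts)
}

#' Generate a synthetic homologous pair with a known true alignment
#'
#' See [fixture_spec()] for the generative model. The true alignment is
#' recorded from the mutation history: ancestor sites surviving in both
#' descendants become MATCH columns, sites surviving in one become
#' DELETE/INSERT columns, and lineage-specific insertions become gap
#' columns in the other sequence. Output is deterministic per seed.
#'
#' @param spec a [fixture_spec()].
#' @return A `fixture_pair`: list with `seq1`, `seq2`
#'   ([residue_sequence()]s), `true_alignment`, `references` (list of
#'   perturbed copies), `realized_identity` (identical / MATCH columns
#'   of the true alignment) and `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    p <- calibrate_substitution_rate(spec$target_identity)
    anc <- sample_residues(spec$ancestor_length)
    d1 <- mutate_lineage(anc, p)
    d2 <- mutate_lineage(anc, p)
    ev1 <- apply_indels(d1, spec$indel_rate, spec$indel_length)
    ev2 <- apply_indels(d2, spec$indel_rate, spec$indel_length)
    if (!any(ev1$present) || !any(ev2$present)) {
      stop("indel process deleted an entire descendant; ",
           "use a lower indel_rate or longer ancestor", call. = FALSE)
    }
    # assemble columns over the ancestor coordinate
    sym <- character(0)   # M / D / I per column
    r1 <- character(0)    # residues of descendant 1, in order
    r2 <- character(0)
    emit_inserts <- function(a) {
      ins1 <- ev1$inserts[[a + 1]]
      ins2 <- ev2$inserts[[a + 1]]
      if (length(ins1)) {
        sym <<- c(sym, rep("D", length(ins1)))
        r1 <<- c(r1, ins1)
      }
      if (length(ins2)) {
        sym <<- c(sym, rep("I", length(ins2)))
        r2 <<- c(r2, ins2)
      }
    }
    emit_inserts(0)
    for (a in seq_len(spec$ancestor_length)) {
      in1 <- ev1$present[a]
      in2 <- ev2$present[a]
      if (in1 && in2) {
        sym <- c(sym, "M")
        r1 <- c(r1, d1[a])
        r2 <- c(r2, d2[a])
      } else if (in1) {
        sym <- c(sym, "D")
        r1 <- c(r1, d1[a])
      } else if (in2) {
        sym <- c(sym, "I")
        r2 <- c(r2, d2[a])
      }
      emit_inserts(a)
    }
    seq1 <- residue_sequence(r1, id = sprintf("synth%d_a", spec$seed))
    seq2 <- residue_sequence(r2, id = sprintf("synth%d_b", spec$seed))
    truth <- alignment_from_symbols(sym, seq1, seq2)
    refs <- lapply(seq_len(spec$n_references), function(r) {
      ref_seed <- (spec$seed + 999331 * r) %% .Machine$integer.max
      perturb_reference(truth, spec$reference_jitter, seed = ref_seed)
    })
    e <- alignment_edges(truth)
    realized <- if (nrow(e)) {
      mean(seq1$residues[e[, 1]] == seq2$residues[e[, 2]])
    } else NA_real_
    structure(list(seq1 = seq1, seq2 = seq2, true_alignment = truth,
                   references = refs, realized_identity = realized,
                   spec = spec),
              class = "fixture_pair")
  })
}

# build a pairwise alignment from a column symbol vector (M/D/I)
alignment_from_symbols <- function(sym, seq1, seq2, mode = "reference") {
  takes1 <- sym != "I"
  takes2 <- sym != "D"
  i <- ifelse(takes1, cumsum(takes1), NA_integer_)
  j <- ifelse(takes2, cumsum(takes2), NA_integer_)
  pairwise_alignment(seq1, seq2, i, j, mode = mode)
}

#' @export
print.fixture_pair <- function(x, ...) {
  cat(sprintf(
    "<fixture_pair> %s (%d aa) vs %s (%d aa), identity %.3f, %d references\n",
    x$seq1$id, length(x$seq1$residues), x$seq2$id, length(x$seq2$residues),
    x$realized_identity, length(x$references)))
  invisible(x)
}

#' Perturb a reference alignment by relocating gap runs
#'
#' Emulates the disagreement among structure-based alignments: each
#' maximal run of gap columns is displaced by a uniform random offset of
#' at most `jitter` columns, which re-pairs the residues around it while
#' keeping the alignment valid (residue content and column counts are
#' unchanged). `jitter = 0` returns the input unchanged.
#'
#' @param true_alignment a [pairwise_alignment()].
#' @param jitter maximum displacement in columns (>= 0).
#' @param seed RNG seed.
#' @return A perturbed [pairwise_alignment()] of the same pair.
#' @export
perturb_reference <- function(true_alignment, jitter, seed = NULL) {
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  if (jitter == 0) return(true_alignment)
  with_seed(seed, {
    sym <- ifelse(is.na(true_alignment$i), "I",
                  ifelse(is.na(true_alignment$j), "D", "M"))
    r <- rle(sym)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    run_id <- rep(seq_along(r$lengths), r$lengths)
    v_sym <- sym
    v_run <- run_id
    for (k in which(r$values != "M")) {
      idx <- which(v_run == k)
      delta <- sample(seq(-jitter, jitter), 1)
      if (delta == 0) next
      block_sym <- v_sym[idx]
      block_run <- v_run[idx]
      v_sym <- v_sym[-idx]
      v_run <- v_run[-idx]
      at <- min(max(min(idx) + delta, 1), length(v_sym) + 1)
      v_sym <- append(v_sym, block_sym, after = at - 1)
      v_run <- append(v_run, block_run, after = at - 1)
    }
    alignment_from_symbols(v_sym, true_alignment$seq1,
                           true_alignment$seq2, mode = "reference")
  })
}

#' Generate a tiered synthetic benchmark set
#'
#' Produces `n_pairs` fixture pairs per similarity tier. The default
#' tiers target the mean identities of the high (48%), medium (26.9%)
#' and low (22.6%) sequence-similarity groups of the CATH benchmark the
#' edge-reliability model was developed on. Optionally writes sequences
#' (FASTA), true and reference alignments (aligned FASTA) and a manifest
#' TSV to a directory.
#'
#' @param n_pairs pairs per tier.
#' @param tiers named numeric vector of target identities.
#' @param dir optional output directory.
#' @param seed base seed; pair seeds are derived deterministically.
#' @param ... further arguments passed to [fixture_spec()]
#'   (`ancestor_length`, `indel_rate`, ...).
#' @return List with `pairs` (named list of `fixture_pair`s) and
#'   `manifest` (data frame).
#' @export
generate_benchmark_set <- function(n_pairs = 20,
                                   tiers = c(high = 0.48, medium = 0.269,
                                             low = 0.226),
                                   dir = NULL, seed = 1, ...) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  pairs <- list()
  rows <- list()
  idx <- 0L
  for (t in seq_along(tiers)) {
    for (k in seq_len(n_pairs)) {
      idx <- idx + 1L
      pair_seed <- as.integer((seed + 7919 * idx) %% .Machine$integer.max)
      spec <- fixture_spec(target_identity = tiers[[t]], seed = pair_seed,
                           ...)
      pair <- generate_pair(spec)
      id <- sprintf("%s_%02d", names(tiers)[t], k)
      pairs[[id]] <- pair
      files <- c(fasta = NA_character_, true = NA_character_)
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        fa <- file.path(dir, paste0("pair_", id, ".fasta"))
        write_fasta(list(pair$seq1, pair$seq2), fa)
        tr <- file.path(dir, paste0("pair_", id, "_true.afa"))
        write_alignment_fasta(pair$true_alignment, tr)
        for (r in seq_along(pair$references)) {
          write_alignment_fasta(
            pair$references[[r]],
            file.path(dir, sprintf("pair_%s_ref%d.afa", id, r)))
        }
        files <- c(fasta = fa, true = tr)
      }
      rows[[idx]] <- data.frame(
        pair_id = id, tier = names(tiers)[t], target_identity = tiers[[t]],
        realized_identity = pair$realized_identity, seed = pair_seed,
        fasta = files[["fasta"]], true_alignment = files[["true"]],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}
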