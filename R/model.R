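#' Coefficients of the logistic edge-reliability model
#'
#' The model predicts the probability that an alignment edge appears in a
#' structure-based reference alignment from three normalized features:
#' the edge's frequency in the near-optimal pool (f), its robustness (r),
#' and the maximum bits-per-position of any pool member containing it
#' (m): `logit(p) = intercept + a_f * f + a_r * r + a_m * m`.
#'
#' @param intercept,frequency,robustness,max_bpp model coefficients.
#' @param provenance `"paper_default"` for the published fit, `"refit"`
#'   for coefficients estimated by [fit_model()].
#' @return A `logistic_coefficients` object.
#' @seealso [default_coefficients()] for the published values.
#' @export
logistic_coefficients <- function(intercept, frequency, robustness, max_bpp,
                                  provenance = c("refit", "paper_default")) {
  provenance <- match.arg(provenance)
  vals <- c(intercept = intercept, frequency = frequency,
            robustness = robustness, max_bpp = max_bpp)
  if (!all(is.finite(vals))) {
    stop("all coefficients must be finite", call. = FALSE)
  }
  structure(as.list(vals), provenance = provenance,
            class = "logistic_coefficients")
}

#' Published default coefficients of the edge-reliability model
#'
#' Intercept -6.1032, frequency 5.7816, robustness 4.7489, maximum
#' bits-per-position -1.6225; fitted to 5000 edges sampled from the local
#' region of 75%-of-optimal alignment pools across three scoring schemes
#' (BLOSUM50 -10/-2, BLOSUM50 -12/-2, BLOSUM62 -11/-1), with an edge
#' labelled positive when present in at least 2 of 4 structure-based
#' reference alignments.
#'
#' @return A `logistic_coefficients` object tagged `"paper_default"`.
#' @export
default_coefficients <- function() {
  logistic_coefficients(-6.1032, 5.7816, 4.7489, -1.6225,
                        provenance = "paper_default")
}

#' @export
print.logistic_coefficients <- function(x, ...) {
  cat(sprintf(
    "<logistic_coefficients> [%s] intercept %.4f, f %.4f, r %.4f, m %.4f\n",
    attr(x, "provenance"), x$intercept, x$frequency, x$robustness,
    x$max_bpp))
  invisible(x)
}

#' Predict the probability that an edge is structurally correct
#'
#' Evaluates the logistic model: `logit = a0 + a_f f + a_r r + a_m m`,
#' `p = exp(logit) / (1 + exp(logit))`. Inputs are vectorized. `NA`
#' values of `m` (edges never seen in the pool) are imputed as 0.
#' Features outside `[0, 1]` trigger a warning but are used as given.
#'
#' @param coeffs a [logistic_coefficients()] object.
#' @param f,r,m normalized frequency, robustness, and maximum
#'   bits-per-position.
#' @return Data frame with columns `logit` and `probability`.
#' @examples
#' predict_edge_probability(default_coefficients(), 1, 1, 0)
#' @export
predict_edge_probability <- function(coeffs, f, r, m) {
  m <- ifelse(is.na(m), 0, m)
  if (!all(is.finite(f)) || !all(is.finite(r)) || !all(is.finite(m))) {
    stop("features must be finite", call. = FALSE)
  }
  if (any(c(f, r, m) < -1e-9) || any(c(f, r, m) > 1 + 1e-9)) {
    warning("features outside [0, 1]; the model was fit on normalized inputs")
  }
  logit <- coeffs$intercept + coeffs$frequency * f +
    coeffs$robustness * r + coeffs$max_bpp * m
  data.frame(logit = logit, probability = stats::plogis(logit))
}

#' Label edges by occurrence in reference alignments
#'
#' An edge is labelled 1 when it occurs as a MATCH column in at least `k`
#' of the reference alignments (the "k of n" rule; the published model
#' uses 2 of 4).
#'
#' @param edges two-column matrix/data frame of edges `(i, j)`.
#' @param references list of [pairwise_alignment()]s over the same
#'   sequence pair.
#' @param k minimum number of references containing the edge.
#' @return Data frame `i`, `j`, `count`, `y`.
#' @export
label_edges <- function(edges, references, k = 2) {
  if (length(references) < 1) stop("need at least one reference",
                                   call. = FALSE)
  if (k < 1 || k > length(references)) {
    stop("k must be between 1 and the number of references", call. = FALSE)
  }
  ref1 <- references[[1]]
  for (r in references) {
    if (!same_sequence_pair(r, ref1)) {
      stop("references are not alignments of the same sequence pair",
           call. = FALSE)
    }
  }
  edges <- as.matrix(as.data.frame(edges)[, 1:2])
  keys <- paste(edges[, 1], edges[, 2], sep = ":")
  counts <- integer(length(keys))
  for (r in references) {
    rk <- edge_keys(alignment_edges(r))
    counts <- counts + (keys %in% rk)
  }
  data.frame(i = as.integer(edges[, 1]), j = as.integer(edges[, 2]),
             count = counts, y = as.integer(counts >= k))
}

#' Fit the logistic edge-reliability model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`, logit link, deviance tolerance 1e-8, at most
#' 100 iterations) of edge labels on any subset of the three predictors.
#'
#' @param observations data frame with columns `f`, `r`, `m` (normalized
#'   features; `NA` `m` is imputed as 0) and `y` (0/1 response). An
#'   optional `pair` column identifies the sequence pair for grouped
#'   train/test splits.
#' @param predictors subset of `c("f", "r", "m")` to include.
#' @return An `edge_fit`: coefficient table (estimate, standard error,
#'   Wald z, p-value), null and residual deviance, AIC, a
#'   [logistic_coefficients()] object (absent predictors get coefficient
#'   0), and a `separation` flag set when fitted probabilities hit 0/1.
#' @export
fit_model <- function(observations, predictors = c("f", "r", "m")) {
  if (length(predictors) > 0) {
    predictors <- match.arg(predictors, c("f", "r", "m"), several.ok = TRUE)
  }
  obs <- as.data.frame(observations)
  need <- c(predictors, "y")
  if (!all(need %in% names(obs))) {
    stop("observations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("m" %in% names(obs)) obs$m[is.na(obs$m)] <- 0
  if (length(unique(obs$y)) < 2) {
    stop("response has a single class; cannot fit", call. = FALSE)
  }
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = obs, family = binomial("logit"),
        control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  ct <- summary(fit)$coefficients
  colnames(ct) <- c("estimate", "std_error", "z", "p_value")
  get_coef <- function(nm) if (nm %in% rownames(ct)) ct[nm, "estimate"] else 0
  coeffs <- logistic_coefficients(
    intercept = get_coef("(Intercept)"), frequency = get_coef("f"),
    robustness = get_coef("r"), max_bpp = get_coef("m"),
    provenance = "refit")
  structure(list(coefficients = ct, model = coeffs,
                 null_deviance = fit$null.deviance,
                 residual_deviance = fit$deviance,
                 aic = fit$aic, converged = fit$converged,
                 separation = separation, glm = fit,
                 predictors = predictors),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge_fit> y ~ %s\n", paste(x$predictors, collapse = " + ")))
  print(round(x$coefficients, 4))
  cat(sprintf("null deviance %.2f, residual deviance %.2f, AIC %.2f\n",
              x$null_deviance, x$residual_deviance, x$aic))
  if (x$separation) cat("warning: separation detected\n")
  invisible(x)
}

#' ROC curve and AUC for an edge scoring
#'
#' Sweeps a threshold over the unique score values and reports the
#' true/false positive rates; the AUC is computed by the rank
#' (Mann-Whitney) formula, which rank-averages ties and equals the
#' trapezoid-rule area under the sweep.
#'
#' @param scores numeric vector of edge scores (higher = more likely
#'   positive).
#' @param labels 0/1 vector of the same length.
#' @return A `roc_curve`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
evaluate_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg,
                numeric(1))
  points <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  ranks <- rank(scores) # ties rank-averaged
  auc <- (sum(ranks[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f over %d thresholds\n", x$auc,
              nrow(x$points) - 1))
  invisible(x)
}

#' Single-predictor screening diagnostic
#'
#' Fits each predictor alone and reports its Wald p-value together with
#' the conventional p < 0.25 screening flag (a deliberately permissive
#' threshold that keeps variables which may matter only jointly). This is
#' a reported diagnostic; final model choice is by AIC comparison
#' ([aic_comparison()]).
#'
#' @inheritParams fit_model
#' @return Data frame `predictor`, `estimate`, `p_value`, `keep`.
#' @export
screen_predictors <- function(observations) {
  rows <- lapply(c("f", "r", "m"), function(v) {
    fit <- fit_model(observations, predictors = v)
    ct <- fit$coefficients
    data.frame(predictor = v, estimate = ct[v, "estimate"],
               p_value = ct[v, "p_value"], keep = ct[v, "p_value"] < 0.25)
  })
  do.call(rbind, rows)
}

#' Residual deviance and AIC across nested predictor subsets
#'
#' Fits the full model, frequency + robustness, frequency alone and
#' robustness alone, and tabulates residual deviance and AIC for
#' parsimony comparison.
#'
#' @inheritParams fit_model
#' @return Data frame `model`, `residual_deviance`, `aic`.
#' @export
aic_comparison <- function(observations) {
  subsets <- list(full = c("f", "r", "m"), freq_robust = c("f", "r"),
                  frequency = "f", robustness = "r")
  rows <- lapply(names(subsets), function(nm) {
    fit <- fit_model(observations, predictors = subsets[[nm]])
    data.frame(model = nm, residual_deviance = fit$residual_deviance,
               aic = fit$aic)
  })
  do.call(rbind, rows)
}

#' Split observations into training and test sets by sequence pair
#'
#' Edges from one sequence pair are never split across training and test
#' sets.
#'
#' @param observations data frame with a `pair` column.
#' @param test_fraction fraction of pairs assigned to the test set.
#' @param seed RNG seed for the pair assignment.
#' @return List with `train` and `test` data frames.
#' @export
partition_by_pair <- function(observations, test_fraction = 0.5,
                              seed = NULL) {
  obs <- as.data.frame(observations)
  if (!"pair" %in% names(obs)) stop("observations need a 'pair' column",
                                    call. = FALSE)
  pairs <- unique(obs$pair)
  n_test <- max(1, round(length(pairs) * test_fraction))
  test_pairs <- with_seed(seed, sample(pairs, n_test))
  list(train = obs[!(obs$pair %in% test_pairs), , drop = FALSE],
       test = obs[obs$pair %in% test_pairs, , drop = FALSE])
}

#' Write / read model coefficients as JSON
#'
#' @param coeffs a [logistic_coefficients()] object.
#' @param path file path.
#' @export
write_coefficients <- function(coeffs, path) {
  jsonlite::write_json(
    list(intercept = coeffs$intercept, frequency = coeffs$frequency,
         robustness = coeffs$robustness, max_bpp = coeffs$max_bpp,
         provenance = attr(coeffs, "provenance")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic_coefficients(x$intercept, x$frequency, x$robustness, x$max_bpp,
                        provenance = x$provenance)
}
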