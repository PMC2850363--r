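test_that("published coefficients reproduce hand-computed probabilities", {
  co <- default_coefficients()
  # independent arithmetic, written out from the model equation
  p0 <- predict_edge_probability(co, 0, 0, 0)
  expect_equal(p0$logit, -6.1032)
  expect_equal(p0$probability, 1 / (1 + exp(6.1032)), tolerance = 1e-12)
  expect_equal(p0$probability, 0.00223, tolerance = 1e-3)

  p1 <- predict_edge_probability(co, 1, 1, 0)
  expect_equal(p1$logit, -6.1032 + 5.7816 + 4.7489)
  expect_equal(p1$probability, exp(4.4273) / (1 + exp(4.4273)),
               tolerance = 1e-12)
  expect_equal(p1$probability, 0.9882, tolerance = 1e-4)
})

test_that("logit and probability stay consistent to 1e-12", {
  co <- default_coefficients()
  grid <- expand.grid(f = c(0, 0.25, 0.5, 0.75, 1),
                      r = c(0, 0.5, 1), m = c(0, 0.5, 1))
  pred <- predict_edge_probability(co, grid$f, grid$r, grid$m)
  expect_equal(pred$probability / (1 - pred$probability),
               exp(pred$logit), tolerance = 1e-12)
  # strictly increasing in frequency (positive coefficient)
  pf <- predict_edge_probability(co, seq(0, 1, 0.1), 0.5, 0.5)$probability
  expect_true(all(diff(pf) > 0))
})

test_that("prediction rejects and flags bad feature values", {
  co <- default_coefficients()
  expect_error(predict_edge_probability(co, Inf, 0, 0), "finite")
  expect_warning(predict_edge_probability(co, 2, 0, 0), "outside")
  # NA max-bpp (edge never pooled) is imputed as zero
  expect_equal(predict_edge_probability(co, 0.5, 0.5, NA)$probability,
               predict_edge_probability(co, 0.5, 0.5, 0)$probability)
  expect_error(logistic_coefficients(NA, 1, 1, 1), "finite")
})

test_that("edges are labelled by the k-of-n reference rule", {
  pair <- generate_pair(fixture_spec(ancestor_length = 60,
                                     target_identity = 0.5, seed = 5))
  refs <- pair$references
  edges <- alignment_edges(pair$true_alignment)
  lab1 <- label_edges(edges, refs, k = 1)
  labn <- label_edges(edges, refs, k = length(refs))
  # hand-tallied counts agree
  tally <- rowSums(vapply(refs, function(r) {
    edge_keys(edges) %in% edge_keys(alignment_edges(r))
  }, logical(nrow(edges))))
  expect_equal(lab1$count, unname(tally))
  expect_equal(lab1$y, as.integer(tally >= 1))
  expect_equal(labn$y, as.integer(tally == length(refs)))
  # an edge found in exactly one reference is positive at k = 1 only
  once <- which(tally == 1)
  if (length(once)) {
    expect_equal(lab1$y[once[1]], 1L)
    expect_equal(labn$y[once[1]], 0L)
  }
  # references over a different pair are rejected
  other <- generate_pair(fixture_spec(ancestor_length = 60,
                                      target_identity = 0.5, seed = 6))
  expect_error(label_edges(edges, list(refs[[1]],
                                       other$true_alignment)),
               "same sequence pair")
  expect_error(label_edges(edges, refs, k = 9), "between 1")
})

test_that("refitting recovers known coefficients within 3 SE", {
  co <- default_coefficients()
  set.seed(909)
  n <- 20000
  obs <- data.frame(f = runif(n), r = runif(n), m = runif(n))
  eta <- co$intercept + co$frequency * obs$f + co$robustness * obs$r +
    co$max_bpp * obs$m
  obs$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_model(obs)
  ct <- fit$coefficients
  truth <- c(co$intercept, co$frequency, co$robustness, co$max_bpp)
  expect_true(all(abs(ct[, "estimate"] - truth) <= 3 * ct[, "std_error"]))
  expect_true(fit$converged)
  # AIC bookkeeping: residual deviance + 2 * parameters
  expect_equal(fit$aic, fit$residual_deviance + 2 * 4)
})

test_that("intercept-only fit on balanced responses is near zero", {
  obs <- data.frame(y = rep(c(0, 1), each = 500))
  fit <- fit_model(obs, predictors = character(0))
  expect_lt(abs(fit$coefficients["(Intercept)", "estimate"]), 1e-8)
})

test_that("nested models never decrease residual deviance", {
  set.seed(910)
  n <- 4000
  obs <- data.frame(f = runif(n), r = runif(n), m = runif(n))
  obs$y <- rbinom(n, 1, plogis(-2 + 3 * obs$f + 1 * obs$r))
  tab <- aic_comparison(obs)
  dev <- setNames(tab$residual_deviance, tab$model)
  expect_lte(dev[["full"]], dev[["freq_robust"]])
  expect_lte(dev[["freq_robust"]], dev[["frequency"]])
  expect_lte(dev[["full"]], dev[["robustness"]])
})

test_that("degenerate fits are refused or flagged", {
  expect_error(fit_model(data.frame(f = runif(10), r = 0, m = 0,
                                    y = rep(1, 10))),
               "single class")
  # perfectly separable data: flagged, coefficients still finite
  obs <- data.frame(f = c(runif(50, 0, 0.4), runif(50, 0.6, 1)),
                    r = 0.5, m = 0.5, y = rep(c(0, 1), each = 50))
  fit <- fit_model(obs, predictors = "f")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients[, "estimate"])))
})

test_that("single-predictor screening reports the 0.25 rule", {
  set.seed(911)
  n <- 3000
  obs <- data.frame(f = runif(n), r = runif(n), m = runif(n))
  obs$y <- rbinom(n, 1, plogis(-2 + 4 * obs$f))
  sc <- screen_predictors(obs)
  expect_equal(sc$predictor, c("f", "r", "m"))
  expect_true(sc$keep[sc$predictor == "f"])
  expect_equal(sc$keep, sc$p_value < 0.25)
})

test_that("ROC analysis matches its closed-form cases and pROC", {
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0)
  roc <- evaluate_roc(scores, labels)
  expect_equal(roc$auc, 1.0)
  # complement symmetry
  roc_neg <- evaluate_roc(-scores, labels)
  expect_equal(roc$auc + roc_neg$auc, 1.0)
  # label-independent scores give AUC ~ 0.5
  set.seed(912)
  s <- runif(4000)
  y <- rbinom(4000, 1, 0.4)
  expect_equal(evaluate_roc(s, y)$auc, 0.5, tolerance = 0.05)
  # agrees with an independent implementation, ties included
  s2 <- round(runif(500), 1)
  y2 <- rbinom(500, 1, plogis(3 * s2 - 1.5))
  got <- evaluate_roc(s2, y2)$auc
  want <- as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(evaluate_roc(s2, rep(1, 500)), "positive and one negative")
})

test_that("train/test partitions never split a sequence pair", {
  obs <- data.frame(f = runif(100), r = runif(100), m = runif(100),
                    y = rbinom(100, 1, 0.5),
                    pair = rep(paste0("p", 1:10), each = 10))
  sp <- partition_by_pair(obs, test_fraction = 0.3, seed = 1)
  expect_length(intersect(unique(sp$train$pair), unique(sp$test$pair)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100)
  # same seed, same split
  sp2 <- partition_by_pair(obs, test_fraction = 0.3, seed = 1)
  expect_identical(sp, sp2)
})

test_that("coefficients round-trip through JSON", {
  co <- default_coefficients()
  path <- tempfile(fileext = ".json")
  write_coefficients(co, path)
  back <- read_coefficients(path)
  expect_equal(back$intercept, co$intercept)
  expect_equal(back$max_bpp, co$max_bpp)
  expect_equal(attr(back, "provenance"), "paper_default")
})
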