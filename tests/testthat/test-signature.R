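test_that("compute_metrics matches hand-computed confusion quantities", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$youden, 1)

  # 3 of 4 pairs concordant
  m2 <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(m2$auc, 0.75)

  # youden identity holds for every evaluation
  withr::with_seed(5, {
    for (r in 1:10) {
      y <- rbinom(40, 1, 0.5); if (length(unique(y)) < 2) next
      s <- runif(40)
      mm <- compute_metrics(y, s)
      expect_equal(mm$youden, mm$sensitivity + mm$specificity - 1)
    }
  })

  # undefined PPV reported as NA, not zero
  m3 <- compute_metrics(c(1, 0), c(0.1, 0.2))
  expect_true(is.na(m3$ppv))
  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)), "one class")
})

test_that("AUC equals brute-force pair concordance with tie credit", {
  withr::with_seed(9, {
    for (r in 1:30) {
      n <- sample(10:40, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(runif(n), 1)              # induces ties
      pos <- s[y == 1]; neg <- s[y == 0]
      conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(compute_metrics(y, s)$auc, mean(conc), tolerance = 1e-12)
    }
  })
})

test_that("model comparison averages rounds and crowns the best family", {
  # perfectly separable cohort: every family reaches mean AUC 1
  ch <- generate_cohort(30, 30, 12, n_deg = 8, effect = 6, noise_sd = 0.5,
                        seed = 81)
  mz <- zscore_genes(ch$matrix)
  cmp <- compare_models(mz, ch$labels, rounds = 5, base_seed = 19)
  expect_equal(cmp$auc, rep(1, nrow(cmp)))
  expect_true(attr(cmp, "winner") %in% model_families())

  # permuted labels: no family can beat chance by much
  withr::with_seed(20, y_perm <- sample(ch$labels))
  cmp0 <- compare_models(mz, y_perm, rounds = 5, base_seed = 21)
  expect_true(all(cmp0$auc > 0.3 & cmp0$auc < 0.7))
})

test_that("fit_final exposes calibrated linear weights with correct signs", {
  ch <- generate_cohort(40, 40, 10, n_deg = 6, effect = 3, noise_sd = 1,
                        seed = 91)
  mz <- zscore_genes(ch$matrix)
  planted <- ch$truth$deg_genes
  model <- fit_final(mz, ch$labels, "linear_svm", seed = 23)
  expect_s3_class(model, "signature_model")
  expect_equal(sign(model$weights[names(planted)]), sign(planted),
               ignore_attr = TRUE)
  expect_gt(model$calibrator$b, 0)            # calibrator is monotone

  # identical seed => identical serialized model
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_signature_model(model, p1)
  write_signature_model(fit_final(mz, ch$labels, "linear_svm", seed = 23), p2)
  expect_identical(readLines(p1), readLines(p2))

  # round trip through JSON preserves predictions
  m2 <- read_signature_model(p1)
  expect_equal(predict_cohort(m2, mz)$probability,
               predict_cohort(model, mz)$probability, tolerance = 1e-12)

  expect_error(fit_final(mz, ch$labels, "random_forest", seed = 1),
               "no linear weights")
})

test_that("predict_cohort is monotone in each gene with its weight sign", {
  ch <- generate_cohort(40, 40, 8, n_deg = 4, effect = 3, noise_sd = 1,
                        seed = 101)
  mz <- zscore_genes(ch$matrix)
  model <- fit_final(mz, ch$labels, "linear_svm", seed = 29)
  g_pos <- names(which.max(model$weights))
  g_neg <- names(which.min(model$weights))

  base <- unclass(mz)
  bump <- function(g, delta) {
    x <- base; x[g, ] <- x[g, ] + delta
    pr <- predict_cohort(model, expression_matrix(x, "raw_log"))
    pr$probability
  }
  p0 <- predict_cohort(model, mz)$probability
  expect_true(all(bump(g_pos, 0.5) > p0))
  expect_true(all(bump(g_neg, 0.5) < p0))

  # all-zero sample scores at calibrator(intercept)
  x0 <- base; x0[] <- 0
  pr0 <- predict_cohort(model, expression_matrix(x0, "raw_log"))
  expect_equal(pr0$probability,
               rep(plogis(model$calibrator$a +
                          model$calibrator$b * model$intercept), ncol(mz)),
               tolerance = 1e-12)

  # missing signature gene is an error naming the gene
  m_small <- expression_matrix(base[-match(g_pos, rownames(base)), ,
                                    drop = FALSE], "raw_log")
  expect_error(predict_cohort(model, m_small), g_pos)
})
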