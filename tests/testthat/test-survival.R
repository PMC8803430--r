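test_that("Kaplan-Meier matches hand product-limit computation", {
  # all events at 1, 2, 3 with n = 3: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # no events: S stays at 1
  km0 <- km_estimate(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))

  # censoring removes subjects from later risk sets (vs exhaustive oracle)
  withr::with_seed(3, {
    for (r in 1:10) {
      n <- sample(5:10, 1)
      time <- sample(1:8, n, replace = TRUE)
      event <- rbinom(n, 1, 0.7)
      if (sum(event) == 0) next
      km <- km_estimate(time, event)
      orc <- km_oracle(time, event)
      expect_equal(km$surv[km$n_event > 0], orc$surv, tolerance = 1e-12)
    }
  })
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank equals the hypergeometric-variance oracle", {
  withr::with_seed(7, {
    for (r in 1:10) {
      n <- sample(6:10, 1)
      time <- sample(1:6, n, replace = TRUE)
      event <- rbinom(n, 1, 0.8)
      group <- rep(c("a", "b"), length.out = n)
      if (sum(event) == 0 || length(unique(group)) < 2) next
      got <- logrank_test(time, event, group)
      orc <- logrank_oracle(time, event, group)
      expect_equal(got$chi2, orc$chi2, tolerance = 1e-10)
      expect_equal(got$p, orc$p, tolerance = 1e-10)
    }
  })

  # duplicated identical groups: no difference to detect
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # strongly separated synthetic groups at beta = 1.5
  sc <- setNames(rep(c(0, 1), each = 50), sprintf("S%03d", 1:100))
  tb <- generate_survival(sc, beta = 1.5, base_hazard = 0.05,
                          censor_rate = 0.1, seed = 11)
  lr <- logrank_test(tb$time, tb$event, sc > 0.5)
  expect_lt(lr$p, 0.01)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
})

test_that("Cox fit recovers hazard ratios and is scale-consistent", {
  withr::with_seed(13, {
    n <- 300
    x <- rnorm(n)
    tb <- generate_survival(setNames(x, paste0("S", 1:n)), beta = 0.7,
                            base_hazard = 0.05, censor_rate = 0.2, seed = 17)
    tb$x <- x
    fit <- cox_fit(tb, "x")
    se <- (log(fit$ci_high) - log(fit$ci_low)) / (2 * qnorm(0.975))
    expect_lt(abs(fit$coef - 0.7), 3 * se)
    expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)

    # univariate on a single covariate equals the joint model with only it
    expect_equal(cox_fit(tb, "x", univariate = TRUE), fit, tolerance = 1e-12)

    # duplicating the dataset leaves the HR unchanged
    tb2 <- rbind(tb, tb)
    expect_equal(cox_fit(tb2, "x")$hr, fit$hr, tolerance = 1e-8)

    tb_small <- tb[1:10, ]
    tb_small$event <- c(1, 1, 1, rep(0, 7))
    expect_warning(cox_fit(tb_small, "x"), "fewer than 5 events")
  })
})

test_that("time-dependent ROC reduces to the binary AUC without censoring", {
  withr::with_seed(19, {
    n <- 120
    score <- rnorm(n)
    tb <- generate_survival(setNames(score, paste0("S", 1:n)), beta = 1,
                            base_hazard = 0.05, censor_rate = 0, seed = 23)
    td <- time_dependent_roc(score, tb$time, tb$event, horizons = c(6, 12, 24))
    for (i in seq_len(nrow(td))) {
      h <- td$horizon[i]
      y <- as.integer(tb$time <= h)
      if (length(unique(y)) < 2) next
      expect_equal(td$auc[i], compute_metrics(y, score)$auc, tolerance = 1e-12)
    }

    # perfectly ranking score: AUC 1 at every horizon
    o <- order(tb$time)
    perfect <- numeric(n); perfect[o] <- seq(n, 1)
    td1 <- time_dependent_roc(perfect, tb$time, tb$event, horizons = c(6, 12))
    expect_equal(td1$auc, rep(1, 2))

    # score independent of survival: AUC near 0.5
    td0 <- time_dependent_roc(rnorm(n), tb$time, tb$event, horizons = 12)
    expect_equal(td0$auc, 0.5, tolerance = 0.15)

    # horizon beyond follow-up is reported as missing
    tdx <- time_dependent_roc(score, tb$time, tb$event,
                              horizons = max(tb$time) + 1)
    expect_true(is.na(tdx$auc))
  })
})
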