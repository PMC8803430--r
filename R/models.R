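#' The five model families used for signature construction
#'
#' @return Character vector of family names in their fixed reference order
#'   (also the tie-break order for model comparison).
#' @export
model_families <- function() {
  c("lasso_logistic", "linear_svm", "ann", "random_forest", "xgboost_tree")
}

# ---- shared helpers --------------------------------------------------------

# rank/Mann-Whitney AUC with 0.5 credit for ties; y in {0,1}
auc_rank <- function(y, score) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop_ts("AUC undefined: one class absent")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified k-fold assignment, deterministic given the RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified train/test split
#'
#' Splits samples into train/test at the given test fraction, stratified by
#' class so neither side can end up one-class (the non-stratified failure
#' mode at small n).
#'
#' @param y binary labels (0/1).
#' @param test_frac test fraction (default 0.2); test size is
#'   `round(test_frac * n)`.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_frac = 0.2) {
  n <- length(y)
  n_test <- round(test_frac * n)
  i1 <- sample(which(y == 1)); i0 <- sample(which(y == 0))
  # per-class test counts proportional to class size, at least 1 each
  t1 <- max(1L, min(length(i1) - 1L, round(n_test * length(i1) / n)))
  t0 <- max(1L, min(length(i0) - 1L, n_test - t1))
  test <- c(i1[seq_len(t1)], i0[seq_len(t0)])
  list(train = sort(setdiff(seq_len(n), test)), test = sort(test))
}

# ---- family fitting --------------------------------------------------------

# Fixed hyperparameter search spaces (version-controlled defaults; the
# coarse seeded search over the tree families stands in for Bayesian
# optimisation at desk scale).
family_search_space <- function(family, p) {
  switch(family,
    lasso_logistic = lapply(10^seq(-3, -0.5, length.out = 6),
                            function(l) list(lambda = l)),
    linear_svm = lapply(c(0.01, 0.1, 1), function(C) list(C = C)),
    ann = list(list(hidden = 4L, decay = 0.01), list(hidden = 4L, decay = 0.1)),
    random_forest = list(
      list(mtry = max(1L, floor(sqrt(p))), min_node = 3L),
      list(mtry = max(1L, floor(sqrt(p))), min_node = 10L),
      list(mtry = max(1L, floor(p / 5)), min_node = 5L)),
    xgboost_tree = list(
      list(depth = 2L, eta = 0.3), list(depth = 3L, eta = 0.1),
      list(depth = 3L, eta = 0.3)),
    stop_ts("unknown family: ", family))
}

#' Fit one model family with train-only hyperparameter tuning
#'
#' Hyperparameters are chosen by 5-fold stratified cross-validated AUC on
#' the supplied (training) data over the family's fixed search space, then
#' the model is refit on all supplied samples. Every random draw (folds,
#' initialisation, bootstraps) derives from `seed`, so identical inputs and
#' seed give identical fits.
#'
#' @param family one of [model_families()].
#' @param x numeric matrix, samples x genes.
#' @param y binary labels (1 = nonresponse).
#' @param seed integer seed.
#' @param tune logical; `FALSE` fits the first point of the search space.
#' @return An object of class `tacesig_model`.
#' @export
fit_model <- function(family, x, y, seed, tune = TRUE) {
  family <- match.arg(family, model_families())
  y <- as_label01(y, nrow(x))
  if (length(unique(y)) < 2L) stop_ts("training data must contain both classes")
  space <- family_search_space(family, ncol(x))
  with_seed_(seed, {
    params <- space[[1L]]
    if (tune && length(space) > 1L) {
      fold <- stratified_folds(y, 5L)
      cv_auc <- vapply(space, function(par) {
        preds <- numeric(length(y))
        for (k in 1:5) {
          tr <- fold != k
          if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
          fit <- fit_family_raw(family, x[tr, , drop = FALSE], y[tr], par)
          preds[!tr] <- raw_score(fit, x[!tr, , drop = FALSE])
        }
        auc_rank(y, preds)
      }, numeric(1))
      params <- space[[which.max(cv_auc)]]
    }
    fit <- fit_family_raw(family, x, y, params)
    structure(list(family = family, fit = fit, params = params,
                   genes = colnames(x), seed = seed),
              class = "tacesig_model")
  })
}

#' @export
print.tacesig_model <- function(x, ...) {
  cat("tacesig_model:", x$family, "on", length(x$genes), "genes\n")
  invisible(x)
}

fit_family_raw <- function(family, x, y, par) {
  switch(family,
    lasso_logistic = fit_lasso(x, y, par),
    linear_svm = fit_linear_svm(x, y, par),
    ann = fit_ann(x, y, par),
    random_forest = fit_rf(x, y, par),
    xgboost_tree = fit_gbt(x, y, par))
}

raw_score <- function(fit, x) fit$score_fun(fit, x)

#' Continuous nonresponse score of a fitted model
#'
#' Probabilities for the probabilistic families, the margin for the linear
#' SVM; higher always means more nonresponse-like.
#'
#' @param model `tacesig_model`.
#' @param x samples x genes matrix over the model's genes.
#' @return Numeric vector, one score per row of `x`.
#' @export
model_score <- function(model, x) {
  if (!all(model$genes %in% colnames(x)))
    stop_ts("missing genes in new data: ",
            paste(setdiff(model$genes, colnames(x)), collapse = ", "))
  raw_score(model$fit, x[, model$genes, drop = FALSE])
}

# lasso logistic via glmnet at a tuned fixed lambda
fit_lasso <- function(x, y, par) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = c(par$lambda * 4, par$lambda),
                        standardize = FALSE)
  list(kind = "lasso", glmnet = fit, lambda = par$lambda,
       score_fun = function(f, x)
         as.numeric(predict(f$glmnet, x, s = f$lambda, type = "response")),
       coef_fun = function(f) {
         cf <- as.numeric(coef(f$glmnet, s = f$lambda))
         setNames(cf[-1L], rownames(coef(f$glmnet, s = f$lambda))[-1L])
       })
}

# linear SVM: L2-regularised squared hinge, deterministic L-BFGS-B
fit_linear_svm <- function(x, y, par) {
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(x); p <- ncol(x); C <- par$C
  obj <- function(th) {
    w <- th[1:p]; b <- th[p + 1L]
    m <- 1 - ys * (drop(x %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[1:p]; b <- th[p + 1L]
    m <- 1 - ys * (drop(x %*% w) + b)
    act <- pmax(m, 0)
    gw <- w - 2 * C * drop(crossprod(x, ys * act))
    gb <- -2 * C * sum(ys * act)
    c(gw, gb)
  }
  opt <- optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 300))
  w <- setNames(opt$par[1:p], colnames(x)); b <- opt$par[p + 1L]
  list(kind = "svm", w = w, b = b, C = C,
       score_fun = function(f, x) drop(x %*% f$w) + f$b,
       coef_fun = function(f) f$w)
}

# single-hidden-layer network (tanh / sigmoid), analytic backprop,
# seeded initialisation, L2 weight decay
fit_ann <- function(x, y, par) {
  n <- nrow(x); p <- ncol(x); h <- par$hidden; decay <- par$decay
  np <- p * h + h + h + 1L
  unpack <- function(th) list(
    W1 = matrix(th[seq_len(p * h)], p, h),
    b1 = th[p * h + seq_len(h)],
    w2 = th[p * h + h + seq_len(h)],
    b2 = th[np])
  fwd <- function(pa, x) {
    z <- tanh(sweep(x %*% pa$W1, 2, pa$b1, "+"))
    list(z = z, s = drop(z %*% pa$w2) + pa$b2)
  }
  obj <- function(th) {
    pa <- unpack(th)
    s <- fwd(pa, x)$s
    # numerically safe mean cross-entropy: log(1+e^s) - y*s
    mean((pmax(s, 0) + log1p(exp(-abs(s)))) - y * s) +
      decay * (sum(pa$W1^2) + sum(pa$w2^2))
  }
  grad <- function(th) {
    pa <- unpack(th)
    f <- fwd(pa, x)
    d2 <- (plogis(f$s) - y) / n            # dL/ds
    gw2 <- drop(crossprod(f$z, d2)) + 2 * decay * pa$w2
    gb2 <- sum(d2)
    dz <- outer(d2, pa$w2) * (1 - f$z^2)   # n x h
    gW1 <- crossprod(x, dz) + 2 * decay * pa$W1
    gb1 <- colSums(dz)
    c(as.numeric(gW1), gb1, gw2, gb2)
  }
  th0 <- rnorm(np, 0, 0.1)
  opt <- optim(th0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  pa <- unpack(opt$par)
  list(kind = "ann", pa = pa, genes = colnames(x),
       score_fun = function(f, x) {
       z <- tanh(sweep(x %*% f$pa$W1, 2, f$pa$b1, "+"))
       plogis(drop(z %*% f$pa$w2) + f$pa$b2)
       })
}

# random forest of probability trees (bagged Rcpp regression trees on the
# 0/1 label); importance = summed SSE-reduction gain
fit_rf <- function(x, y, par, ntree = 120L) {
  n <- nrow(x)
  trees <- vector("list", ntree)
  imp <- numeric(ncol(x))
  for (t in seq_len(ntree)) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    tr <- cpp_build_tree(x, y, rows, par$mtry, 4L, par$min_node)
    imp <- imp + tr$importance
    trees[[t]] <- tr
  }
  list(kind = "rf", trees = trees, importance = setNames(imp, colnames(x)),
       score_fun = function(f, x) {
         s <- numeric(nrow(x))
         for (tr in f$trees) s <- s + cpp_predict_tree(tr, x)
         s / length(f$trees)
       })
}

# gradient-boosted trees, first-order logistic boosting with shrinkage and
# row subsampling; importance = summed split gain
fit_gbt <- function(x, y, par, nrounds = 80L, subsample = 0.8) {
  n <- nrow(x)
  p0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
  f0 <- qlogis(p0)
  Fx <- rep(f0, n)
  trees <- vector("list", nrounds)
  imp <- numeric(ncol(x))
  for (t in seq_len(nrounds)) {
    r <- y - plogis(Fx)
    rows <- sample.int(n, max(2L, floor(subsample * n))) - 1L
    tr <- cpp_build_tree(x, r, rows, ncol(x), par$depth, 5L)
    imp <- imp + tr$importance
    trees[[t]] <- tr
    Fx <- Fx + par$eta * cpp_predict_tree(tr, x)
  }
  list(kind = "gbt", trees = trees, f0 = f0, eta = par$eta,
       importance = setNames(imp, colnames(x)),
       score_fun = function(f, x) {
         s <- rep(f$f0, nrow(x))
         for (tr in f$trees) s <- s + f$eta * cpp_predict_tree(tr, x)
         plogis(s)
       })
}

# ---- importance extraction -------------------------------------------------

#' Per-gene importance of a fitted model
#'
#' Linear families return absolute coefficients; the tree families their
#' native split-gain importance; the neural network the mean permutation
#' importance (cross-entropy loss increase over seeded column shuffles) on
#' the held-out test split — the stand-in for per-feature attribution
#' values. Loss, not AUC, is permuted so redundant informative genes keep
#' nonzero attribution even when ranking is already perfect.
#'
#' @param model `tacesig_model`.
#' @param x_test,y_test held-out split (required for `ann`).
#' @param n_perm permutation repeats for the `ann` attribution (default 3).
#' @return Named nonnegative numeric vector over the model's genes.
#' @export
model_importance <- function(model, x_test = NULL, y_test = NULL, n_perm = 3L) {
  fit <- model$fit
  imp <- switch(fit$kind,
    lasso = abs(fit$coef_fun(fit)),
    svm = abs(fit$coef_fun(fit)),
    rf = fit$importance,
    gbt = fit$importance,
    ann = {
      if (is.null(x_test) || is.null(y_test))
        stop_ts("ann importance needs the held-out test split")
      y_test <- as_label01(y_test, nrow(x_test))
      x_test <- x_test[, model$genes, drop = FALSE]
      logloss <- function(p) {
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -mean(y_test * log(p) + (1 - y_test) * log(1 - p))
      }
      base_loss <- logloss(raw_score(fit, x_test))
      rises <- matrix(0, n_perm, ncol(x_test))
      for (r in seq_len(n_perm)) {
        for (j in seq_len(ncol(x_test))) {
          xp <- x_test
          xp[, j] <- xp[sample.int(nrow(xp)), j]
          rises[r, j] <- logloss(raw_score(fit, xp)) - base_loss
        }
      }
      setNames(pmax(colMeans(rises), 0), colnames(x_test))
    })
  imp <- imp[model$genes]
  names(imp) <- model$genes
  if (all(imp == 0)) stop_ts("degenerate fit: all-zero importance vector")
  imp
}

#' Deterministic importance ranks
#'
#' Rank 1 = most important; ties broken by gene id (stable, deterministic).
#'
#' @param importance named nonnegative vector.
#' @return Named integer vector of ranks, a permutation of `1..G`.
#' @export
importance_ranks <- function(importance) {
  ord <- order(-importance, names(importance))
  setNames(order(ord), names(importance))[names(importance)]
}
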