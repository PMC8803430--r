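#' Classification metrics at a probability threshold
#'
#' AUC uses the rank (Mann-Whitney) formulation with 0.5 credit for tied
#' scores; the remaining metrics derive from one confusion matrix at the
#' threshold (positive class = nonresponse, call positive when
#' `score > threshold`). PPV/NPV with an empty predicted class are
#' reported as `NA`, never 0.
#'
#' @param y_true binary labels (1 = nonresponse); both classes required.
#' @param score numeric scores in `[0, 1]`.
#' @param threshold call threshold (default 0.5).
#' @return One-row data.frame: `auc`, `f1`, `accuracy`, `youden`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
compute_metrics <- function(y_true, score, threshold = 0.5) {
  y_true <- as_label01(y_true, length(score))
  if (length(unique(y_true)) < 2L) stop_ts("AUC undefined: one class absent")
  auc <- auc_rank(y_true, score)
  call <- as.integer(score > threshold)
  tp <- sum(call == 1 & y_true == 1); fn <- sum(call == 0 & y_true == 1)
  tn <- sum(call == 0 & y_true == 0); fp <- sum(call == 1 & y_true == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && (ppv + sens) > 0) 2 * ppv * sens / (ppv + sens)
        else NA_real_
  data.frame(auc = auc, f1 = f1, accuracy = (tp + tn) / length(y_true),
             youden = sens + spec - 1, sensitivity = sens,
             specificity = spec, ppv = ppv, npv = npv)
}

#' Compare model families by averaged metrics over seeded rounds
#'
#' For each family: `rounds` stratified 80/20 splits (seeded from
#' `base_seed`), train-only tuning, metrics on the held-out 20%; metrics
#' are averaged per metric across rounds (undefined PPV/NPV/F1 values are
#' excluded from their average with a logged count). The winner is the
#' family with the highest mean AUC; ties break by the fixed order of
#' [model_families()].
#'
#' @param m expression matrix restricted to the signature genes.
#' @param labels binary labels.
#' @param families character vector of families (default all five).
#' @param rounds evaluation rounds (default 10).
#' @param base_seed integer seed.
#' @return data.frame of mean metrics per family (ordered as given) with
#'   attributes `winner` and `n_undefined` (count of NA metric values
#'   excluded from averaging).
#' @export
compare_models <- function(m, labels, families = model_families(),
                           rounds = 10L, base_seed) {
  if (missing(base_seed)) stop_ts("base_seed is mandatory")
  labels <- as_label01(labels, ncol(m))
  rows <- list()
  n_undef <- 0L
  for (fam in families) {
    res <- run_iterations(m, labels, fam, rounds = rounds,
                          base_seed = derive_seed(base_seed, fam),
                          compute_importance = FALSE)
    mets <- do.call(rbind, lapply(res, `[[`, "metrics"))
    n_undef <- n_undef + sum(is.na(mets))
    rows[[fam]] <- cbind(data.frame(family = fam),
                         as.data.frame(t(colMeans(mets, na.rm = TRUE))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_undef > 0)
    message(n_undef, " undefined metric value(s) excluded from round averages")
  win <- out$family[which.max(out$auc)]
  attr(out, "winner") <- win
  attr(out, "n_undefined") <- n_undef
  out
}

# Platt-style sigmoid calibration of a margin: p = plogis(a + b * d),
# fitted on smoothed targets (t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2)) to
# stay finite under perfect separation. b >= 0 enforces monotonicity.
fit_platt <- function(d, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(th) {
    s <- th[1] + exp(th[2]) * d
    sum((pmax(s, 0) + log1p(exp(-abs(s)))) - t * s)
  }
  opt <- optim(c(0, 0), nll, method = "BFGS", control = list(maxit = 200))
  list(a = opt$par[1], b = exp(opt$par[2]))
}

apply_calibrator <- function(cal, d) plogis(cal$a + cal$b * d)

#' Fit the final linear signature on the full development cohort
#'
#' Tunes and fits the chosen linear family on all samples, exposes the
#' per-gene weights (sign convention: positive pushes toward nonresponse)
#' and intercept, and fits a monotone Platt sigmoid calibrator mapping the
#' margin to a probability so external cohorts can be called at 0.5.
#'
#' @param m expression matrix restricted to the signature genes
#'   (z-scored, as the model expects).
#' @param labels binary labels (1 = nonresponse).
#' @param family `"linear_svm"` (default) or `"lasso_logistic"`; the tree
#'   and network families carry no linear weights and are rejected here —
#'   use [model_importance()] on a [fit_model()] fit instead.
#' @param seed integer seed.
#' @param threshold call threshold (default 0.5).
#' @return Object of class `signature_model`: `genes`, `weights`,
#'   `intercept`, `calibrator` (`a`, `b`), `family`, `seed`, `threshold`.
#' @export
fit_final <- function(m, labels, family = "linear_svm", seed,
                      threshold = 0.5) {
  if (missing(seed)) stop_ts("seed is mandatory")
  if (!family %in% c("linear_svm", "lasso_logistic"))
    stop_ts("family '", family, "' has no linear weights; ",
            "fit it with fit_model() and export model_importance() instead")
  labels <- as_label01(labels, ncol(m))
  x <- t(unclass(m))
  model <- fit_model(family, x, labels, seed = seed)
  w <- model$fit$coef_fun(model$fit)
  b <- if (family == "linear_svm") model$fit$b
       else as.numeric(coef(model$fit$glmnet, s = model$fit$lambda))[1L]
  d <- drop(x %*% w) + b
  cal <- with_seed_(seed, fit_platt(d, labels))
  structure(list(genes = colnames(x), weights = w, intercept = b,
                 calibrator = cal, family = family, seed = seed,
                 threshold = threshold, params = model$params),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model (%s): %d genes, threshold %.2f\n",
              x$family, length(x$genes), x$threshold))
  print(round(x$weights, 4))
  invisible(x)
}

#' Score an external cohort with a fitted signature
#'
#' `probability = calibrator(intercept + sum(w_g x_g))`; a sample is
#' called nonresponse when its probability exceeds the threshold. All
#' signature genes must be present — missing genes are an error, never
#' silently imputed.
#'
#' @param model `signature_model`.
#' @param m_external expression matrix of the cohort to score (z-scored
#'   on its own samples, matching the development preprocessing).
#' @return data.frame: `sample`, `score` (margin), `probability`, `call`
#'   (`"response"`/`"nonresponse"`).
#' @export
predict_cohort <- function(model, m_external) {
  missing_genes <- setdiff(model$genes, rownames(m_external))
  if (length(missing_genes))
    stop_ts("signature genes absent from cohort: ",
            paste(missing_genes, collapse = ", "))
  x <- t(unclass(m_external)[model$genes, , drop = FALSE])
  d <- drop(x %*% model$weights[model$genes]) + model$intercept
  p <- apply_calibrator(model$calibrator, d)
  data.frame(sample = colnames(m_external), score = d, probability = p,
             call = ifelse(p > model$threshold, "nonresponse", "response"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize / restore a signature model as JSON
#'
#' @param model `signature_model`.
#' @param path output path.
#' @return `path` invisibly; `read_signature_model()` returns the model.
#' @export
write_signature_model <- function(model, path) {
  obj <- list(family = model$family, genes = model$genes,
              weights = as.list(model$weights),
              intercept = model$intercept,
              calibrator = model$calibrator, threshold = model$threshold,
              seed = model$seed, params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = obj$genes,
                 weights = unlist(obj$weights),
                 intercept = obj$intercept,
                 calibrator = obj$calibrator, family = obj$family,
                 seed = obj$seed, threshold = obj$threshold,
                 params = obj$params),
            class = "signature_model")
}
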