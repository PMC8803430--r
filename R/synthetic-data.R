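#' Generate a two-group expression cohort with planted ground truth
#'
#' Emulates the statistical structure the downstream analysis assumes: iid
#' Gaussian log2-intensity background, a set of planted differentially
#' expressed genes shifted by +/- `effect` in nonresponders (half up, half
#' down), and a designated informative subset that drives the response
#' label. Labels are fixed at the requested group sizes and informative
#' genes receive the class-conditional shift, so by Bayes' rule the label
#' is exactly a logistic function of the informative genes with weights
#' `sign * effect / noise_sd^2` — learnable, with overlap controlled by
#' `effect / noise_sd`. Optionally a block of stemness-driver genes is
#' shifted upward in nonresponders to plant a stemness gradient.
#'
#' @param n_resp,n_nonresp responders (label 0) and nonresponders (label 1).
#' @param n_genes total genes.
#' @param n_deg planted differentially expressed genes (`<= n_genes`).
#' @param effect absolute planted shift in log2 units (the planted log2
#'   fold change is `+effect` for up genes, `-effect` for down genes).
#' @param n_informative informative genes (`<= n_deg`), the first
#'   `n_informative` planted genes.
#' @param noise_sd iid Gaussian noise sd (log2 units).
#' @param seed mandatory integer seed; identical seed gives an identical
#'   cohort.
#' @param n_stemness optional count of extra stemness-driver genes.
#' @param stemness_shift mean upward offset of the drivers in nonresponders.
#' @return List with `matrix` (an [expression_matrix()], `raw_log`),
#'   `labels` (named 0/1 vector, 1 = nonresponder), and `truth` (planted
#'   log2 fold changes, informative weights, stemness drivers/weights,
#'   and the generator parameters).
#' @export
generate_cohort <- function(n_resp, n_nonresp, n_genes, n_deg = 0L,
                            effect = 1, n_informative = n_deg,
                            noise_sd = 1, seed,
                            n_stemness = 0L, stemness_shift = 0) {
  if (missing(seed)) stop_ts("seed is mandatory")
  if (n_resp <= 0 || n_nonresp <= 0 || n_genes <= 0)
    stop_ts("cohort dimensions must be positive")
  if (n_deg > n_genes) stop_ts("n_deg exceeds n_genes")
  if (n_informative > n_deg) stop_ts("n_informative exceeds n_deg")
  if (n_deg > 0 && effect <= 0) stop_ts("planted |log2FC| must be > 0")
  if (n_stemness + n_genes < n_stemness) stop_ts("bad n_stemness")
  n <- n_resp + n_nonresp
  with_seed_(seed, {
    samples <- sprintf("S%03d", seq_len(n))
    labels <- setNames(sample(rep(c(0, 1), c(n_resp, n_nonresp))), samples)
    g_total <- n_genes + n_stemness
    genes <- sprintf("G%04d", seq_len(g_total))
    baseline <- runif(g_total, 4, 10)
    vals <- baseline + matrix(rnorm(g_total * n, 0, noise_sd), g_total, n)
    dimnames(vals) <- list(genes, samples)
    deg_genes <- character(0); deg_lfc <- numeric(0)
    if (n_deg > 0) {
      deg_genes <- genes[seq_len(n_deg)]
      n_up <- ceiling(n_deg / 2)
      deg_lfc <- setNames(rep(c(effect, -effect), c(n_up, n_deg - n_up)), deg_genes)
      vals[deg_genes, ] <- vals[deg_genes, ] +
        outer(deg_lfc, labels)          # shift applied to nonresponders only
    }
    informative <- head(deg_genes, n_informative)
    info_w <- if (n_informative > 0)
      setNames(deg_lfc[informative] / noise_sd^2, informative) else numeric(0)
    stem_genes <- character(0); stem_w <- numeric(0)
    if (n_stemness > 0) {
      stem_genes <- genes[n_genes + seq_len(n_stemness)]
      stem_w <- setNames(runif(n_stemness, 0.5, 1.5), stem_genes)
      vals[stem_genes, ] <- vals[stem_genes, ] +
        outer(stem_w * stemness_shift, labels)
    }
    truth <- list(
      deg_genes = deg_lfc, informative_genes = info_w,
      stemness_genes = stem_w, stemness_shift = stemness_shift,
      params = list(n_resp = n_resp, n_nonresp = n_nonresp,
                    n_genes = n_genes, n_deg = n_deg, effect = effect,
                    n_informative = n_informative, noise_sd = noise_sd,
                    n_stemness = n_stemness, seed = seed)
    )
    list(matrix = expression_matrix(vals, "raw_log"),
         labels = labels, truth = truth)
  })
}

#' Generate survival times whose hazard depends on a score
#'
#' Event times are exponential with rate `base_hazard * exp(beta * score)`;
#' censoring is independent uniform on `(0, c_max)` with `c_max` solved
#' numerically so the expected censored fraction is approximately
#' `censor_rate`.
#'
#' @param scores named numeric vector, one score per sample.
#' @param beta log hazard ratio per unit score.
#' @param base_hazard baseline exponential rate (> 0), per month.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `time` (months), `event`
#'   (1 = event observed, 0 = censored).
#' @export
generate_survival <- function(scores, beta, base_hazard = 0.05,
                              censor_rate = 0, seed) {
  if (missing(seed)) stop_ts("seed is mandatory")
  if (base_hazard <= 0) stop_ts("base_hazard must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop_ts("censor_rate must be in [0, 1)")
  if (is.null(names(scores))) names(scores) <- sprintf("S%03d", seq_along(scores))
  with_seed_(seed, {
    rate <- base_hazard * exp(beta * scores)
    t_ev <- rexp(length(scores), rate)
    time <- t_ev; event <- rep(1L, length(scores))
    if (censor_rate > 0) {
      # E[censored] for C ~ U(0, cmax): mean over samples of min(T, cmax)/cmax
      f <- function(cmax) mean(pmin(t_ev, cmax) / cmax) - censor_rate
      lo <- min(t_ev) * 1e-3; hi <- max(t_ev) * 1e3
      cmax <- tryCatch(uniroot(f, c(lo, hi))$root, error = function(e) max(t_ev))
      cens <- runif(length(scores), 0, cmax)
      event <- as.integer(t_ev <= cens)
      time <- pmin(t_ev, cens)
    }
    data.frame(sample = names(scores), time = time, event = event,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Generate bulk mixtures of known cell-type proportions
#'
#' `bulk = sig %*% t(props)` plus iid Gaussian noise, truncated at zero —
#' the linear mixing model that deconvolution assumes, on the linear
#' (non-log) intensity scale.
#'
#' @param sig signature matrix (marker genes x cell types), nonnegative.
#' @param props matrix of proportions (samples x cell types), rows on the
#'   simplex.
#' @param noise_sd Gaussian noise sd on the linear scale.
#' @param seed integer seed.
#' @return Numeric matrix, genes x samples, linear scale.
#' @export
generate_mixtures <- function(sig, props, noise_sd = 0, seed) {
  if (missing(seed)) stop_ts("seed is mandatory")
  props <- as.matrix(props)
  if (ncol(props) != ncol(sig)) stop_ts("props columns must match signature cell types")
  if (any(props < 0) || any(abs(rowSums(props) - 1) > 1e-9))
    stop_ts("each props row must lie on the simplex")
  with_seed_(seed, {
    bulk <- sig %*% t(props)
    if (noise_sd > 0)
      bulk <- bulk + matrix(rnorm(length(bulk), 0, noise_sd), nrow(bulk))
    bulk[bulk < 0] <- 0
    colnames(bulk) <- rownames(props) %||% sprintf("S%03d", seq_len(ncol(bulk)))
    rownames(bulk) <- rownames(sig)
    bulk
  })
}
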