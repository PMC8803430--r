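#' Per-sample gene-set enrichment scores (rank-based single-sample scoring)
#'
#' For each sample, genes are ranked by expression (highest expression =
#' rank N, average ranks for ties). Walking down the descending-expression
#' order, in-set genes advance a running statistic by their rank weight
#' `rank^tau` (normalised by the total in-set rank weight) and out-of-set
#' genes retreat by `1/(N - k)`. The score is the sum of the running
#' deviation over all positions divided by N — the integrated weighted
#' Kolmogorov-Smirnov random walk used by single-sample GSEA — minus the
#' statistic's analytic expectation under uniformly random gene sets
#' (`mean(W)/W_N - (N+1)/2N`, with `W` the cumulative positional rank
#' weights), so scores of random sets are centred at zero rather than
#' carrying the rank-weighting offset. Being purely rank-based, scores are
#' invariant to any strictly monotone transform of a sample's expression
#' values.
#'
#' @param m expression matrix.
#' @param sets named list of gene-symbol vectors (see [read_gmt()]).
#' @param tau rank-weighting exponent (default 0.25).
#' @param min_size minimum mapped genes per set (default 5); smaller sets
#'   are dropped with a warning.
#' @return Numeric matrix, sets x samples.
#' @export
sample_enrichment <- function(m, sets, tau = 0.25, min_size = 5L) {
  x <- unclass(m)
  n <- nrow(x)
  mapped <- lapply(sets, function(g) which(rownames(x) %in% g))
  sizes <- lengths(mapped)
  drop <- sizes < min_size
  if (any(drop)) {
    warning(sum(drop), " gene set(s) below min_size dropped: ",
            paste(head(names(sets)[drop], 5L), collapse = ", "))
    mapped <- mapped[!drop]
  }
  if (length(mapped) == 0L) stop_ts("no gene set has >= min_size genes in the matrix")
  scores <- matrix(NA_real_, length(mapped), ncol(x),
                   dimnames = list(names(mapped), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j])                      # highest expression -> rank n
    ord <- order(x[, j], decreasing = TRUE)
    w <- r^tau
    # null expectation of the integrated walk for a random set
    W <- cumsum(w[ord])
    null_mean <- mean(W) / W[n] - (n + 1) / (2 * n)
    inset <- logical(n)
    for (i in seq_along(mapped)) {
      inset[] <- FALSE; inset[mapped[[i]]] <- TRUE
      io <- inset[ord]
      k <- sum(io)
      step_in <- numeric(n); step_in[io] <- w[ord][io]
      cdf_in <- cumsum(step_in) / sum(step_in)
      cdf_out <- cumsum(!io) / (n - k)
      scores[i, j] <- sum(cdf_in - cdf_out) / n - null_mean
    }
  }
  scores
}

#' Contrast per-sample set scores between response groups
#'
#' Welch t-test per gene set, sign convention nonresponder minus
#' responder, with BH adjustment across sets.
#'
#' @param scores sets x samples matrix from [sample_enrichment()].
#' @param labels binary labels (1 = nonresponder); both groups >= 2.
#' @return data.frame: `set`, `mean_diff`, `t`, `p`, `q`, ordered by `q`.
#' @export
contrast_sets <- function(scores, labels) {
  labels <- as_label01(labels, ncol(scores))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (length(i1) < 2L || length(i0) < 2L) stop_ts("each group needs >= 2 samples")
  res <- t(apply(scores, 1, function(s) {
    if (sd(s[i1]) == 0 && sd(s[i0]) == 0) {
      # degenerate: identical constant rows give t = 0, p = 1
      return(c(mean(s[i1]) - mean(s[i0]),
               if (mean(s[i1]) == mean(s[i0])) 0 else Inf,
               if (mean(s[i1]) == mean(s[i0])) 1 else 0))
    }
    tt <- t.test(s[i1], s[i0], var.equal = FALSE)
    c(mean(s[i1]) - mean(s[i0]), unname(tt$statistic), tt$p.value)
  }))
  out <- data.frame(set = rownames(scores), mean_diff = res[, 1],
                    t = res[, 2], p = res[, 3], q = bh_adjust(res[, 3]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, out$p, out$set), , drop = FALSE]
}
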