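#' Moderated two-group t-statistics with empirical-Bayes variance shrinkage
#'
#' For each gene, the pooled two-group variance \eqn{s^2_g} (df
#' \eqn{d_g = n_1 + n_2 - 2}) is shrunk toward a common prior
#' \eqn{s_0^2} with prior df \eqn{d_0}, both estimated by moment matching
#' on \eqn{\log s^2_g} (mean/trigamma equations of the scaled inverse
#' chi-square model). The moderated statistic is
#' \deqn{\tilde t_g = \frac{\Delta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},
#'   \quad \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g},}
#' with two-sided p-values from a t distribution on \eqn{d_0 + d_g} df.
#' The fold-change sign convention is nonresponder minus responder, so
#' positive log2FC means upregulated in nonresponders.
#'
#' @param m expression matrix (log2 intensities or z-scores; use a
#'   consistent scale — the default pipeline passes raw log2 data).
#' @param labels binary per-sample labels (1 = nonresponder), or
#'   `"response"`/`"nonresponse"` strings; both groups need >= 2 samples.
#' @param d0_override `NULL` (estimate d0), `0` (ordinary pooled t), or
#'   `Inf` (fully shrunk t using s0 only); used to exercise the two
#'   closed-form limits.
#' @return data.frame, one row per gene: `gene`, `log2FC`, `s2_g`,
#'   `t_mod`, `df_total`, `p`, `q` (BH), `direction` (`up`/`down` in
#'   nonresponders), plus attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(m, labels, d0_override = NULL) {
  labels <- as_label01(labels, ncol(m))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < 2L || n0 < 2L) stop_ts("each group needs >= 2 samples")
  x <- unclass(m)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m0 <- rowMeans(x[, i0, drop = FALSE])
  lfc <- m1 - m0
  v1 <- apply(x[, i1, drop = FALSE], 1, var)
  v0 <- apply(x[, i0, drop = FALSE], 1, var)
  dg <- n1 + n0 - 2
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / dg
  hp <- if (is.null(d0_override)) estimate_var_prior(s2, dg)
        else list(d0 = d0_override, s0_2 = exp(mean(log(pmax(s2, 1e-300)))))
  d0 <- hp$d0; s0_2 <- hp$s0_2
  if (is.infinite(d0)) {
    s_tilde2 <- rep(s0_2, length(s2)); df_total <- Inf
  } else {
    s_tilde2 <- (d0 * s0_2 + dg * s2) / (d0 + dg); df_total <- d0 + dg
  }
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n0))
  t_mod <- lfc / se
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod))
       else 2 * pt(-abs(t_mod), df = df_total)
  out <- data.frame(
    gene = rownames(m), log2FC = lfc, s2_g = s2, t_mod = t_mod,
    df_total = df_total, p = p, q = bh_adjust(p),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# Moment-matching estimate of the variance prior (d0, s0^2) from the
# log sample variances: under the hierarchical model,
#   E[log s2_g] = log s0^2 + digamma(dg/2) - log(dg/2) - digamma(d0/2) + log(d0/2)
#   Var[log s2_g] = trigamma(dg/2) + trigamma(d0/2)
# so d0 solves trigamma(d0/2) = var(log s2) - trigamma(dg/2) (Newton on
# the trigamma inverse) and s0^2 follows from the mean equation.
estimate_var_prior <- function(s2, dg) {
  ok <- s2 > 0
  if (sum(ok) < 2L) stop_ts("too few positive gene variances to estimate the prior")
  z <- log(s2[ok])
  e_target <- var(z) - trigamma(dg / 2)
  if (e_target <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
  } else {
    d0 <- 2 * inv_trigamma(e_target)
    s0_2 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Newton inversion of trigamma on (0, Inf); x > 0.
inv_trigamma <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_ts("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
  q
}

#' Filter differential-expression records to a DEG table
#'
#' Keeps genes with `|log2FC| > lfc_min` and `q < q_max`, both strict
#' inequalities, and reports the up/down bookkeeping.
#'
#' @param records data.frame from [moderated_t()].
#' @param lfc_min absolute log2 fold-change threshold (default 1.0).
#' @param q_max BH-adjusted p threshold (default 0.05).
#' @return The filtered data.frame, ordered by increasing `q`, with
#'   attribute `counts` = `c(total, up, down)`.
#' @export
filter_degs <- function(records, lfc_min = 1.0, q_max = 0.05) {
  keep <- abs(records$log2FC) > lfc_min & records$q < q_max
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$q, out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- c(total = nrow(out),
                           up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}
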