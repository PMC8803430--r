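#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimises `||A x - b||^2` subject to `x >= 0`. Used by [deconvolve()];
#' exported because the primitive is handy on its own and no installed
#' package provides it.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol nonnegativity/optimality tolerance.
#' @return List with `x` (coefficients) and `resid_norm`.
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      if (!any(passive)) { s <- numeric(n); break }
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, resid_norm = sqrt(sum((b - A %*% x)^2)))
}

#' Deconvolve bulk expression into cell-type fractions
#'
#' Non-negative least squares of each bulk sample on the marker-gene
#' signature matrix, with coefficients normalised to the simplex. Mixing
#' is linear in intensity, so `raw_log` matrices are de-logged (`2^x`)
#' first and z-scored matrices are rejected.
#'
#' @param bulk expression matrix (or plain linear-scale matrix) of bulk
#'   samples.
#' @param sig signature matrix, marker genes x cell types (linear scale).
#' @param min_shared minimum fraction of signature genes that must be
#'   present in the bulk matrix (default 0.5).
#' @return Matrix samples x cell types of fractions on the simplex, with
#'   attribute `degenerate` naming samples whose NNLS coefficients were
#'   all zero (their fractions are NA).
#' @export
deconvolve <- function(bulk, sig, min_shared = 0.5) {
  if (inherits(bulk, "expression_matrix")) {
    if (scale_tag(bulk) == "zscore")
      stop_ts("z-scored matrices cannot be deconvolved; mixing is linear in intensity")
    bulk <- 2^unclass(bulk)
  }
  shared <- intersect(rownames(sig), rownames(bulk))
  if (length(shared) < min_shared * nrow(sig))
    stop_ts("only ", length(shared), "/", nrow(sig),
            " signature genes present in bulk (need >= ",
            ceiling(min_shared * nrow(sig)), ")")
  A <- sig[shared, , drop = FALSE]
  fr <- matrix(NA_real_, ncol(bulk), ncol(sig),
               dimnames = list(colnames(bulk), colnames(sig)))
  degenerate <- character(0)
  for (j in seq_len(ncol(bulk))) {
    x <- nnls_fit(A, bulk[shared, j])$x
    if (sum(x) <= 0) {
      degenerate <- c(degenerate, colnames(bulk)[j])
    } else {
      fr[j, ] <- x / sum(x)
    }
  }
  if (length(degenerate))
    warning("all-zero deconvolution coefficients for: ",
            paste(degenerate, collapse = ", "))
  attr(fr, "degenerate") <- degenerate
  fr
}

#' Contrast cell-type fractions between response groups
#'
#' Independent (Welch) t-test per cell type with BH adjustment; sign
#' convention nonresponder minus responder.
#'
#' @param fracs samples x cell types matrix from [deconvolve()].
#' @param labels binary labels (1 = nonresponder), one per sample row.
#' @return data.frame: `cell_type`, `mean_resp`, `mean_nonresp`, `t`,
#'   `p`, `q`.
#' @export
compare_fractions <- function(fracs, labels) {
  labels <- as_label01(labels, nrow(fracs))
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (length(i1) < 2L || length(i0) < 2L) stop_ts("each group needs >= 2 samples")
  res <- apply(fracs, 2, function(f) {
    if (sd(f[i1]) == 0 && sd(f[i0]) == 0)
      return(c(mean(f[i0]), mean(f[i1]),
               if (mean(f[i1]) == mean(f[i0])) 0 else Inf,
               if (mean(f[i1]) == mean(f[i0])) 1 else 0))
    tt <- t.test(f[i1], f[i0], var.equal = FALSE)
    c(mean(f[i0]), mean(f[i1]), unname(tt$statistic), tt$p.value)
  })
  out <- data.frame(cell_type = colnames(fracs), mean_resp = res[1, ],
                    mean_nonresp = res[2, ], t = res[3, ], p = res[4, ],
                    q = bh_adjust(res[4, ]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$q, out$p, out$cell_type), , drop = FALSE]
}

#' mRNA stemness index
#'
#' Per sample, the Spearman correlation between the sample's expression
#' over the genes shared with the stemness weight vector and the weights
#' themselves; the correlations are then min-max standardised to `[0, 1]`
#' within the scored cohort. Being rank-based, the raw correlation is
#' invariant to any strictly monotone transform of a sample's expression.
#'
#' @param m expression matrix (>= 2 samples).
#' @param weights named numeric weight vector (gene -> weight), e.g. from
#'   [read_weight_vector()]. A small synthetic toy vector ships at
#'   `system.file("extdata", "stemness_weights_synthetic.tsv", package =
#'   "tacesig")` for examples; real use consumes externally trained
#'   stemness weights.
#' @return data.frame: `sample`, `rho` (Spearman), `mRNAsi` in `[0, 1]`.
#' @export
stemness_index <- function(m, weights) {
  if (ncol(m) < 2L) stop_ts("min-max standardisation needs >= 2 samples")
  shared <- intersect(rownames(m), names(weights))
  if (length(shared) < 10L)
    stop_ts("fewer than 10 weighted genes present in the matrix")
  if (length(shared) < 0.5 * length(weights))
    warning("only ", length(shared), "/", length(weights),
            " weighted genes present in the matrix")
  w <- weights[shared]
  x <- unclass(m)[shared, , drop = FALSE]
  rho <- apply(x, 2, function(col) cor(col, w, method = "spearman"))
  rng <- range(rho)
  if (diff(rng) == 0) {
    warning("all samples have identical stemness correlation; mRNAsi set to 0")
    si <- rep(0, length(rho))
  } else {
    si <- (rho - rng[1]) / diff(rng)
  }
  data.frame(sample = colnames(m), rho = rho, mRNAsi = si,
             stringsAsFactors = FALSE, row.names = NULL)
}
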