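test_that("NNLS matches unconstrained least squares on interior problems", {
  withr::with_seed(3, {
    for (r in 1:10) {
      A <- matrix(runif(40 * 3, 1, 5), 40, 3)
      x_true <- runif(3, 0.5, 2)             # strictly positive solution
      b <- drop(A %*% x_true)
      got <- nnls_fit(A, b)$x
      ref <- drop(solve(crossprod(A), crossprod(A, b)))
      expect_equal(got, ref, tolerance = 1e-8)
      expect_equal(got, x_true, tolerance = 1e-8)
    }
    # active constraints: negative LS solution is clipped, not returned
    A2 <- cbind(c(1, 0), c(1, 1e-3))
    b2 <- c(1, -0.5)
    expect_true(all(nnls_fit(A2, b2)$x >= 0))
  })
})

test_that("deconvolution recovers known mixtures on the simplex", {
  sig <- toy_signature()
  props <- rbind(S1 = c(1, 0, 0, 0),
                 S2 = c(0.2, 0.3, 0.5, 0),
                 S3 = c(0.25, 0.25, 0.25, 0.25))
  bulk <- generate_mixtures(sig, props, noise_sd = 0, seed = 7)
  fr <- deconvolve(bulk, sig)
  expect_equal(unname(fr["S1", ]), c(1, 0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(fr["S2", ]), unname(props["S2", ]), tolerance = 1e-6)
  # fractions live on the simplex
  expect_true(all(abs(rowSums(fr) - 1) < 1e-9))
  expect_true(all(fr >= 0))

  # permuting cell-type columns permutes the output identically
  perm <- c(3, 1, 4, 2)
  fr2 <- deconvolve(bulk, sig[, perm])
  expect_equal(fr2, fr[, perm], tolerance = 1e-9, ignore_attr = TRUE)

  # z-scored input is rejected; too few shared genes is an error
  mz <- zscore_genes(expression_matrix(
    matrix(rnorm(nrow(sig) * 4, 8), nrow(sig), 4,
           dimnames = list(rownames(sig), paste0("S", 1:4))), "raw_log"))
  expect_error(deconvolve(mz, sig), "linear in intensity")
  bulk_small <- bulk[1:10, , drop = FALSE]
  expect_error(deconvolve(bulk_small, sig), "signature genes present")
})

test_that("log-scale expression matrices are de-logged before deconvolution", {
  sig <- toy_signature()
  props <- rbind(S1 = c(0.6, 0.4, 0, 0))
  bulk_lin <- generate_mixtures(sig, props, noise_sd = 0, seed = 9)
  m_log <- expression_matrix(log2(bulk_lin + 1e-9), "raw_log")
  fr <- deconvolve(m_log, sig)
  expect_equal(unname(fr["S1", ]), unname(props["S1", ]), tolerance = 1e-4)
})

test_that("fraction contrasts find planted shifts and flip with labels", {
  withr::with_seed(11, {
    n <- 40
    labels <- rep(c(0, 1), each = n / 2)
    fr <- matrix(abs(rnorm(n * 4, 0.25, 0.03)), n, 4,
                 dimnames = list(sprintf("S%02d", 1:n), paste0("CT", 1:4)))
    fr[labels == 1, 2] <- fr[labels == 1, 2] + 0.15   # planted shift in CT2
    fr <- fr / rowSums(fr)
  })
  ct <- compare_fractions(fr, labels)
  expect_lt(ct$q[ct$cell_type == "CT2"], 0.05)
  expect_gt(ct$mean_nonresp[ct$cell_type == "CT2"],
            ct$mean_resp[ct$cell_type == "CT2"])
  ct_sw <- compare_fractions(fr, 1 - labels)
  i <- match(ct$cell_type, ct_sw$cell_type)
  expect_equal(ct_sw$mean_nonresp[i], ct$mean_resp)
  # identical groups: no cell type near significance
  fr_dup <- rbind(fr[1:10, ], fr[1:10, ])
  ct0 <- compare_fractions(fr_dup, rep(c(0, 1), each = 10))
  expect_true(all(ct0$p > 0.99))
})

test_that("stemness index is a rank statistic min-max scaled per cohort", {
  withr::with_seed(13, {
    genes <- sprintf("G%03d", 1:60)
    w <- setNames(runif(60, -1, 1), genes)
    base <- matrix(rnorm(60 * 3, 7), 60, 3,
                   dimnames = list(genes, c("CONC", "ANTI", "MID")))
    # CONC follows the weights' ranks exactly, ANTI reverses them
    base[, "CONC"] <- rank(w) / 10 + 5
    base[, "ANTI"] <- -rank(w) / 10 + 5
    m <- expression_matrix(base, "raw_log")
  })
  st <- stemness_index(m, w)
  expect_equal(st$rho[st$sample == "CONC"], 1)
  expect_equal(st$rho[st$sample == "ANTI"], -1)
  expect_equal(st$mRNAsi[st$sample == "CONC"], 1)
  expect_equal(st$mRNAsi[st$sample == "ANTI"], 0)

  # invariant to monotone transforms and to weight-file gene order
  x2 <- unclass(m); x2[, "MID"] <- exp(x2[, "MID"] / 2)
  st2 <- stemness_index(expression_matrix(x2, "raw_log"), w)
  expect_equal(st2$rho, st$rho, tolerance = 1e-12)
  withr::with_seed(14, st3 <- stemness_index(m, w[sample(names(w))]))
  expect_equal(st3$rho, st$rho, tolerance = 1e-12)

  expect_error(stemness_index(m[, 1, drop = FALSE], w), ">= 2 samples")
  expect_error(stemness_index(m, w[1:5]), "fewer than 10")
})

test_that("a planted stemness gradient separates nonresponders", {
  ch <- generate_cohort(40, 35, 150, n_deg = 0, noise_sd = 1, seed = 17,
                        n_stemness = 50, stemness_shift = 1)
  w <- ch$truth$stemness_genes
  st <- stemness_index(ch$matrix, w)
  si <- setNames(st$mRNAsi, st$sample)
  expect_gt(mean(si[names(which(ch$labels == 1))]),
            mean(si[names(which(ch$labels == 0))]))
})
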