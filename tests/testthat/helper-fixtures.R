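# shared fixture builders; everything is generated in code at test time

tiny_matrix <- function(values = c(1.5, -2.25, 0.5, 3.125, 7, 42),
                        genes = c("G1", "G2", "G3"),
                        samples = c("S1", "S2")) {
  expression_matrix(matrix(values, nrow = length(genes),
                           dimnames = list(genes, samples)), "raw_log")
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a rank permutation of 1..G over gene names with prescribed ranks for a
# few genes (used to exercise the occurrence ledger arithmetic)
make_rank_perm <- function(genes, fixed) {
  G <- length(genes)
  ranks <- setNames(seq_len(G), genes)
  for (g in names(fixed)) {
    holder <- names(ranks)[ranks == fixed[[g]]]
    ranks[holder] <- ranks[g]
    ranks[g] <- as.integer(fixed[[g]])
  }
  stopifnot(identical(sort(unname(ranks)), seq_len(G)))
  ranks
}

fake_iterations <- function(rank_list) {
  lapply(rank_list, function(r) list(rank = r))
}

# small cell-type signature matrix for deconvolution tests
toy_signature <- function(n_genes = 60L, n_types = 4L, seed = 2024L) {
  withr::with_seed(seed, {
    sig <- matrix(rexp(n_genes * n_types, rate = 0.2), n_genes, n_types,
                  dimnames = list(sprintf("M%03d", seq_len(n_genes)),
                                  paste0("CT", seq_len(n_types))))
    # give each type some distinctive markers so columns are independent
    for (k in seq_len(n_types)) {
      idx <- ((k - 1) * floor(n_genes / n_types)) + seq_len(floor(n_genes / n_types))
      sig[idx, k] <- sig[idx, k] + 25
    }
    sig
  })
}

# exhaustive product-limit / log-rank oracles for small instances
km_oracle <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = times, surv = out)
}

logrank_oracle <- function(time, event, group) {
  g <- as.integer(as.factor(group)) - 1L
  times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o1 - e1)^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}
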