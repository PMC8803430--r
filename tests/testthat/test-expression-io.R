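test_that("read_matrix round-trips writer output and reports bad cells", {
  m <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path)
  expect_identical(unclass(m2), unclass(m))
  # round trip is bit-stable on the decimal representation
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m2, path2)
  expect_identical(readLines(path2), readLines(path))

  dup <- write_tsv_lines(c("id\tS1\tS2", "G1\t1\t2", "G1\t3\t4"))
  expect_error(read_matrix(dup), "duplicate row id")
  dup_s <- write_tsv_lines(c("id\tS1\tS1", "G1\t1\t2"))
  expect_error(read_matrix(dup_s), "duplicate sample id")

  # first non-numeric cell is named by row and column
  bad <- write_tsv_lines(c("id\tS1\tS2", "G1\t1.0\t2.0", "G2\tNA\t4"))
  expect_error(read_matrix(bad), "row 'G2', column 'S1'")
})

test_that("collapse_probes keeps the max-average probe per gene", {
  # P2 has the larger average and must win for gene G
  m <- expression_matrix(matrix(c(1, 2, 2, 3), 2, byrow = TRUE,
                                dimnames = list(c("P1", "P2"), c("S1", "S2"))),
                         "raw_log")
  pm <- data.frame(probe_id = c("P1", "P2"), gene_symbol = c("G", "G"))
  out <- collapse_probes(m, pm)
  expect_identical(rownames(out), "G")
  expect_equal(unname(unclass(out)[1, ]), c(2, 3))

  # single probe per gene: values unchanged, row relabelled
  pm1 <- data.frame(probe_id = c("P1", "P2"), gene_symbol = c("A", "B"))
  out1 <- collapse_probes(m, pm1)
  expect_equal(unname(unclass(out1)["A", ]), c(1, 2))
  expect_equal(unname(unclass(out1)["B", ]), c(2, 3))

  # ambiguous and blank-annotated probes are dropped
  pm2 <- data.frame(probe_id = c("P1", "P2"),
                    gene_symbol = c("A /// B", ""))
  expect_error(collapse_probes(m, pm2), "no mappable probes")
})

test_that("collapse_probes equals the brute-force per-gene argmax", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n_probe <- 5L
      probes <- sprintf("P%02d", 1:n_probe)
      vals <- matrix(rnorm(n_probe * 4), n_probe,
                     dimnames = list(probes, paste0("S", 1:4)))
      m <- expression_matrix(vals, "raw_log")
      gene <- sample(c("GA", "GB"), n_probe, replace = TRUE)
      pm <- data.frame(probe_id = probes, gene_symbol = gene)
      out <- collapse_probes(m, pm)
      # oracle: exhaustive argmax of probe means within each gene
      for (g in unique(gene)) {
        members <- probes[gene == g]
        means <- rowMeans(vals[members, , drop = FALSE])
        winner <- members[which.max(means)]
        expect_equal(unname(unclass(out)[g, ]), unname(vals[winner, ]))
      }
      expect_equal(nrow(out), length(unique(gene)))
    }
  })
})

test_that("collapse_probes row count equals genes with >=1 unambiguous probe", {
  withr::with_seed(19, {
    for (rep in 1:8) {
      probes <- sprintf("P%02d", 1:12)
      vals <- matrix(rnorm(12 * 3), 12, dimnames = list(probes, paste0("S", 1:3)))
      sym <- sample(c("G1", "G2", "G3", "A /// B", ""), 12, replace = TRUE)
      pm <- data.frame(probe_id = probes, gene_symbol = sym)
      genes_ok <- unique(sym[!(sym == "" | grepl("///", sym))])
      if (length(genes_ok) == 0) {
        expect_error(collapse_probes(expression_matrix(vals, "raw_log"), pm))
      } else {
        out <- collapse_probes(expression_matrix(vals, "raw_log"), pm)
        expect_equal(nrow(out), length(genes_ok))
      }
    }
  })
})

test_that("zscore_genes standardises rows with the n-1 denominator", {
  m <- expression_matrix(matrix(c(1, 2, 3), 1, dimnames = list("G1", paste0("S", 1:3))),
                         "raw_log")
  z <- zscore_genes(m)
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))   # sample sd = 1

  # constant gene dropped with warning
  v2 <- matrix(c(1, 2, 3, 5, 5, 5), 2, byrow = TRUE,
               dimnames = list(c("G1", "G2"), paste0("S", 1:3)))
  m2 <- expression_matrix(v2, "raw_log")
  expect_warning(z2 <- zscore_genes(m2), "constant gene")
  expect_identical(rownames(z2), "G1")

  # every retained row has mean 0, sd 1; z-scoring is idempotent
  withr::with_seed(5, {
    m3 <- expression_matrix(matrix(rnorm(50 * 6, sd = 3), 50,
                                   dimnames = list(sprintf("G%02d", 1:50),
                                                   paste0("S", 1:6))), "raw_log")
  })
  z3 <- zscore_genes(m3)
  expect_true(all(abs(rowMeans(z3)) < 1e-9))
  expect_true(all(abs(apply(z3, 1, sd) - 1) < 1e-9))
  z3b <- zscore_genes(expression_matrix(unclass(z3), "raw_log"))
  expect_equal(unclass(z3b), unclass(z3), tolerance = 1e-9)

  expect_error(zscore_genes(tiny_matrix()[, 1, drop = FALSE]), ">=2 samples")
})

test_that("read_gmt parses, de-duplicates and validates", {
  p <- write_tsv_lines("S1\tdesc\tA\tB\tB")
  sets <- read_gmt(p)
  expect_identical(sets$S1, c("A", "B"))

  expect_error(read_gmt(write_tsv_lines(character(0))), "empty GMT")
  expect_error(read_gmt(write_tsv_lines(c("S1\td\tA", "S1\td\tB"))),
               "duplicate gene-set name")
  expect_error(read_gmt(write_tsv_lines("S1\tdesc")), "fewer than 3")

  # 50-set hallmark-style fixture
  lines <- vapply(1:50, function(i)
    paste(c(sprintf("HM_%02d", i), "na", sprintf("g%d_%d", i, 1:8)),
          collapse = "\t"), character(1))
  sets50 <- read_gmt(write_tsv_lines(lines))
  expect_length(sets50, 50L)
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("S1", "S2"))) * 1.0
  expect_s3_class(expression_matrix(v, "raw_log"), "expression_matrix")
  v_na <- v; v_na[1, 1] <- NA
  expect_error(expression_matrix(v_na, "raw_log"), "non-finite")
  v_dup <- v; rownames(v_dup) <- c("A", "A")
  expect_error(expression_matrix(v_dup, "raw_log"), "duplicate gene")
  expect_error(expression_matrix(v, "zscore"), "not standardised")
})
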