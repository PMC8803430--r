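#' Construct an expression matrix
#'
#' The backbone container of the pipeline: a numeric genes x samples matrix
#' of log2 intensities (or per-gene z-scores) with unique row and column
#' names and a scale tag recording which of the two it holds.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene or probe ids) and colnames (sample ids).
#' @param scale_tag `"raw_log"` (log2 intensities) or `"zscore"`.
#' @return The validated matrix with class `"expression_matrix"` and a
#'   `scale_tag` attribute.
#' @export
expression_matrix <- function(values, scale_tag = c("raw_log", "zscore")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ts("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ts("values must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(rownames(values)))
    stop_ts("duplicate gene ids: ",
            paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_ts("duplicate sample ids: ",
            paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop_ts("values contain non-finite entries")
  if (scale_tag == "zscore" && ncol(values) > 1) {
    mu <- rowMeans(values)
    s <- apply(values, 1, sd)
    if (any(abs(mu) > 1e-9) || any(abs(s - 1) > 1e-9))
      stop_ts("scale_tag = 'zscore' but rows are not standardised (mean 0, sd 1)")
  }
  structure(values, scale_tag = scale_tag, class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "scale_tag")))
  print(head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

scale_tag <- function(m) attr(m, "scale_tag") %||% "raw_log"

#' Read a tab-delimited expression matrix
#'
#' Expects row ids in the first column, sample ids in the header, and
#' numeric cells elsewhere. Non-numeric cells are reported by row and
#' column id; duplicate row or sample ids are rejected.
#'
#' @param path file path.
#' @return An [expression_matrix()] with `scale_tag = "raw_log"`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_ts("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_ts("matrix file needs an id column plus >=1 sample column: ", path)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(ids))
    stop_ts("duplicate row id in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop_ts("duplicate sample id in ", path, ": ",
            paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop_ts("non-numeric cell in ", path, " at row '", ids[bad[1L]],
              "', column '", samples[j], "': '", col[bad[1L]], "'")
    vals[, j] <- num
  }
  expression_matrix(vals, "raw_log")
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_matrix()]; the round trip reproduces the decimal
#' representation exactly (values are written with full precision).
#'
#' @param m expression matrix.
#' @param path output path.
#' @param id_name header for the id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "gene_id") {
  df <- data.frame(id = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column probe-to-gene map
#'
#' Probes mapping to several genes must appear as a single row with the
#' symbols joined by `"///"` or `";"` (the usual array-annotation dialects);
#' such rows, and rows with a blank symbol, are kept and later discarded by
#' [collapse_probes()].
#'
#' @param path tab-delimited file with columns probe id, gene symbol.
#' @return data.frame with columns `probe_id`, `gene_symbol`, `status`
#'   (`mapped`, `ambiguous` or `unmapped`).
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop_ts("probe map needs two columns: probe id, gene symbol")
  pm <- data.frame(probe_id = df[[1L]], gene_symbol = df[[2L]],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$probe_id))
    stop_ts("duplicate probe ids in map: ",
            paste(unique(pm$probe_id[duplicated(pm$probe_id)]), collapse = ", "))
  sym <- trimws(pm$gene_symbol)
  pm$status <- ifelse(sym == "" | is.na(sym) | sym == "---", "unmapped",
                      ifelse(grepl("///|;", sym), "ambiguous", "mapped"))
  pm
}

#' Collapse probe-level rows to gene level
#'
#' Probes with ambiguous (multi-gene) or blank annotation are dropped.
#' When several probes map to one gene, the probe with the maximum average
#' expression across all samples is kept; ties are broken toward the
#' lexicographically smallest probe id for determinism.
#'
#' @param m probe-level expression matrix.
#' @param probe_map data.frame from [read_probe_map()] (columns `probe_id`,
#'   `gene_symbol`, optional `status`).
#' @return Gene-level [expression_matrix()]; rownames are gene symbols.
#' @export
collapse_probes <- function(m, probe_map) {
  if (is.null(probe_map$status)) {
    sym <- trimws(probe_map$gene_symbol)
    probe_map$status <- ifelse(sym == "" | is.na(sym), "unmapped",
                               ifelse(grepl("///|;", sym), "ambiguous", "mapped"))
  }
  keep <- probe_map[probe_map$status == "mapped", , drop = FALSE]
  keep <- keep[keep$probe_id %in% rownames(m), , drop = FALSE]
  if (nrow(keep) == 0L) stop_ts("no mappable probes present in the matrix")
  avg <- rowMeans(m)[keep$probe_id]
  # deterministic winner per gene: max average, tie -> smallest probe id
  ord <- order(keep$gene_symbol, -avg, keep$probe_id)
  keep <- keep[ord, , drop = FALSE]
  win <- keep[!duplicated(keep$gene_symbol), , drop = FALSE]
  out <- unclass(m)[win$probe_id, , drop = FALSE]
  rownames(out) <- win$gene_symbol
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, scale_tag(m))
}

#' Z-score each gene across samples
#'
#' Standardises every gene row to mean 0, sd 1 (sample sd, denominator
#' n - 1) across the samples of the cohort passed in. Genes with zero
#' variance are dropped with a warning, so downstream models never see
#' NaN.
#'
#' @param m expression matrix with at least two samples.
#' @return [expression_matrix()] with `scale_tag = "zscore"`.
#' @export
zscore_genes <- function(m) {
  if (ncol(m) < 2L) stop_ts("z-scoring needs >=2 samples")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped before z-scoring: ",
            paste(head(rownames(m)[const], 5L), collapse = ", "),
            if (sum(const) > 5L) ", ..." else "")
    m <- m[!const, , drop = FALSE]
    mu <- mu[!const]; s <- s[!const]
  }
  if (nrow(m) == 0L) stop_ts("no non-constant genes left to z-score")
  z <- (unclass(m) - mu) / s
  expression_matrix(z, "zscore")
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description (discarded), then member genes,
#' tab-separated. Duplicate genes within a set are de-duplicated;
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ts("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_ts("GMT line ", bad[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop_ts("duplicate gene-set name: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  if (any(lengths(sets) == 0L))
    stop_ts("empty gene set: ", paste(nm[lengths(sets) == 0L], collapse = ", "))
  sets
}

#' Read a marker-gene signature matrix for deconvolution
#'
#' @param path tab-delimited file, marker genes in rows, cell types in
#'   columns, nonnegative expression values.
#' @return Numeric matrix (genes x cell types).
#' @export
read_signature_matrix <- function(path) {
  m <- read_matrix(path)
  sig <- unclass(m)
  attr(sig, "scale_tag") <- NULL
  class(sig) <- setdiff(class(sig), "expression_matrix")
  if (any(sig < 0)) stop_ts("signature matrix must be nonnegative")
  if (any(colSums(sig) == 0)) stop_ts("signature matrix has an all-zero cell type column")
  sig
}

#' Read a gene-weight vector (e.g. stemness weights)
#'
#' @param path two-column tab-delimited file: gene, weight.
#' @return Named numeric vector.
#' @export
read_weight_vector <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_ts("weight file needs two columns: gene, weight")
  w <- suppressWarnings(as.numeric(df[[2L]]))
  if (any(is.na(w))) stop_ts("non-numeric weight for gene ", df[[1L]][which(is.na(w))[1L]])
  if (anyDuplicated(df[[1L]])) stop_ts("duplicate gene in weight file")
  setNames(w, df[[1L]])
}
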