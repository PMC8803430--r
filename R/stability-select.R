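#' Repeated-split importance iterations for one model family
#'
#' The core resampling loop of the signature discovery procedure: in each
#' of `R` iterations the cohort is split (stratified) into an 80% training
#' and 20% testing cohort, hyperparameters are tuned on the training part
#' only, the model is fitted, per-gene importance and deterministic ranks
#' are recorded, and test-set metrics are tracked. Iteration `i` is seeded
#' with `base_seed + i`, so a run is fully reproducible.
#'
#' @param m expression matrix restricted to the candidate (DEG) genes.
#' @param labels binary labels (1 = nonresponse).
#' @param family one of [model_families()].
#' @param rounds number of iterations R (default 10).
#' @param test_frac held-out fraction (default 0.2).
#' @param base_seed integer seed.
#' @param tune tune hyperparameters per iteration (default TRUE).
#' @param compute_importance record per-gene importance and ranks (TRUE for
#'   stability selection; [compare_models()] sets FALSE as it only needs
#'   the test metrics).
#' @return List of iteration records: `iteration`, `seed`, `train`, `test`
#'   (sample ids), `importance`, `rank` (named vectors over all genes),
#'   `metrics` (a [compute_metrics()] row on the test split).
#' @export
run_iterations <- function(m, labels, family, rounds = 10L, test_frac = 0.2,
                           base_seed, tune = TRUE, compute_importance = TRUE) {
  if (missing(base_seed)) stop_ts("base_seed is mandatory")
  labels <- as_label01(labels, ncol(m))
  x <- t(unclass(m))                       # samples x genes
  results <- vector("list", rounds)
  for (i in seq_len(rounds)) {
    seed_i <- base_seed + i
    sp <- with_seed_(seed_i, stratified_split(labels, test_frac))
    model <- fit_model(family, x[sp$train, , drop = FALSE], labels[sp$train],
                       seed = seed_i, tune = tune)
    imp <- if (compute_importance)
      with_seed_(seed_i,
        model_importance(model, x[sp$test, , drop = FALSE], labels[sp$test]))
    score <- model_score(model, x[sp$test, , drop = FALSE])
    metrics <- compute_metrics(labels[sp$test], normalize_score(score))
    results[[i]] <- list(
      iteration = i, seed = seed_i, family = family,
      train = colnames(m)[sp$train], test = colnames(m)[sp$test],
      importance = imp,
      rank = if (compute_importance) importance_ranks(imp),
      metrics = metrics)
  }
  results
}

# map an arbitrary monotone score onto [0,1] for thresholded metrics; the
# probabilistic families are already there, SVM margins get a logistic squash
normalize_score <- function(score) {
  if (all(score >= 0 & score <= 1)) score else plogis(score)
}

#' Accumulate the occurrence ledger over iterations
#'
#' A gene scores one occurrence in an iteration when its importance rank is
#' within the top fraction of the gene universe (`rank <=
#' floor(top_frac * G)`; 74 when G = 373 at the default 0.2). The ranking
#' sum adds the gene's full-universe ranks over exactly those flagged
#' iterations (mode `"flagged"`, the default) or over all iterations
#' (mode `"all"`), and the average rank is `ranking_sum / occurrence`
#' reported to one decimal.
#'
#' @param results list from [run_iterations()] (one family), or a
#'   concatenation over families sharing one gene universe.
#' @param top_frac top fraction flagged per iteration (default 0.2).
#' @param mode ranking-sum accounting: `"flagged"` or `"all"`.
#' @return data.frame: `gene`, `occurrence`, `ranking_sum`, `average_rank`
#'   (NA when never flagged), ordered by (occurrence desc, average_rank
#'   asc, gene), with attribute `n_flagged_per_iteration`.
#' @export
accumulate_occurrence <- function(results, top_frac = 0.2,
                                  mode = c("flagged", "all")) {
  mode <- match.arg(mode)
  genes <- names(results[[1L]]$rank)
  for (r in results)
    if (!identical(sort(names(r$rank)), sort(genes)))
      stop_ts("iterations disagree on the gene universe")
  G <- length(genes)
  cutoff <- floor(top_frac * G)
  occurrence <- setNames(integer(G), genes)
  ranking_sum <- setNames(numeric(G), genes)
  for (r in results) {
    rk <- r$rank[genes]
    flagged <- rk <= cutoff
    occurrence <- occurrence + flagged
    ranking_sum <- ranking_sum + if (mode == "flagged") rk * flagged else rk
  }
  avg <- ifelse(occurrence > 0, round(ranking_sum / occurrence, 1), NA_real_)
  out <- data.frame(gene = genes, occurrence = as.integer(occurrence),
                    ranking_sum = ranking_sum, average_rank = avg,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$occurrence, out$average_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_flagged_per_iteration") <- cutoff
  attr(out, "rounds") <- length(results)
  out
}

#' Select stable genes from the occurrence ledger
#'
#' Keeps genes flagged in at least `min_occurrence` of the iterations that
#' are also present in the external validation cohort's gene universe
#' (`allowed`), ordered by (occurrence desc, average rank asc, gene id).
#'
#' @param table data.frame from [accumulate_occurrence()].
#' @param min_occurrence minimum occurrence (default 8).
#' @param allowed character vector of permitted genes (e.g. the external
#'   cohort's genes); `NULL` allows all.
#' @return Ordered character vector of selected genes.
#' @export
select_genes <- function(table, min_occurrence = 8L, allowed = NULL) {
  if (!is.null(allowed) && length(allowed) == 0L)
    stop_ts("empty 'allowed' gene universe")
  keep <- table$occurrence >= min_occurrence
  n_stable <- sum(keep)
  if (!is.null(allowed)) keep <- keep & table$gene %in% allowed
  sel <- table[keep, , drop = FALSE]
  if (nrow(sel) == 0L) {
    if (n_stable == 0L)
      stop_ts("no gene reaches occurrence >= ", min_occurrence)
    stop_ts(n_stable, " gene(s) reach occurrence >= ", min_occurrence,
            " but none is in the allowed universe")
  }
  sel <- sel[order(-sel$occurrence, sel$average_rank, sel$gene), , drop = FALSE]
  sel$gene
}

#' Format the occurrence ledger for reporting
#'
#' Renders occurrence as `"k/R"` and writes the table as tab-delimited
#' text, mirroring the published ledger layout (gene, occurrence, ranking
#' sum, average rank).
#'
#' @param table data.frame from [accumulate_occurrence()].
#' @param path optional output path; when `NULL` the formatted data.frame
#'   is returned without writing.
#' @return The formatted data.frame, invisibly when written.
#' @export
write_occurrence <- function(table, path = NULL) {
  rounds <- attr(table, "rounds") %||% max(table$occurrence)
  out <- data.frame(gene = table$gene,
                    occurrence = sprintf("%d/%d", table$occurrence, rounds),
                    ranking_sum = table$ranking_sum,
                    average_rank = table$average_rank,
                    stringsAsFactors = FALSE)
  if (is.null(path)) return(out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
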