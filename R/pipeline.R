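#' Build a validated pipeline configuration
#'
#' Collects the paths, thresholds and seed for a full run. Either
#' `matrix_path` + `labels_path` point at an existing cohort, or
#' `simulate` carries parameters for [generate_cohort()] and the run is
#' self-contained (the synthetic route also simulates an external
#' validation cohort and survival times from the planted truth).
#'
#' @param out_dir output directory (stage subdirectories are created).
#' @param seed master seed; every stage derives its own stream from it.
#' @param matrix_path,labels_path development cohort TSVs (matrix as in
#'   [read_matrix()]; labels two columns: sample, label 0/1).
#' @param probe_map_path optional probe map TSV for [collapse_probes()].
#' @param gmt_path optional GMT file enabling the enrichment stage.
#' @param signature_matrix_path,stemness_weights_path optional microenv
#'   inputs (cell-type signature TSV, gene-weight TSV).
#' @param external_matrix_path optional external cohort TSV; the fitted
#'   signature is scored on it (defaults to a second synthetic cohort for
#'   simulated runs, else the development cohort).
#' @param survival_path optional survival TSV (sample, time, event).
#' @param simulate optional named list of [generate_cohort()] arguments
#'   (without `seed`); mutually exclusive with `matrix_path`.
#' @param families model families to race (default all five).
#' @param lfc_min,q_max DEG thresholds (defaults 1.0 and 0.05, strict).
#' @param top_frac,min_occurrence,rounds stability-selection knobs
#'   (defaults 0.2, 8, 10).
#' @param threshold probability call threshold (default 0.5).
#' @param survival_beta,base_hazard,censor_rate synthetic survival model
#'   (log HR per unit score, baseline monthly hazard, censored fraction).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            matrix_path = NULL, labels_path = NULL,
                            probe_map_path = NULL, gmt_path = NULL,
                            signature_matrix_path = NULL,
                            stemness_weights_path = NULL,
                            external_matrix_path = NULL,
                            survival_path = NULL,
                            simulate = NULL,
                            families = model_families(),
                            lfc_min = 1.0, q_max = 0.05,
                            top_frac = 0.2, min_occurrence = 8L,
                            rounds = 10L, threshold = 0.5,
                            survival_beta = 1.5, base_hazard = 0.03,
                            censor_rate = 0.2) {
  if (missing(seed)) stop_ts("master seed is mandatory")
  if (is.null(simulate) && (is.null(matrix_path) || is.null(labels_path)))
    stop_ts("provide matrix_path + labels_path, or a simulate block")
  if (!is.null(simulate) && !is.null(matrix_path))
    stop_ts("matrix_path and simulate are mutually exclusive")
  if (lfc_min < 0 || q_max <= 0 || q_max > 1) stop_ts("invalid DEG thresholds")
  if (top_frac <= 0 || top_frac > 1) stop_ts("top_frac must be in (0, 1]")
  if (rounds < 1L) stop_ts("rounds must be >= 1")
  if (min_occurrence < 1L || min_occurrence > rounds)
    stop_ts("min_occurrence (", min_occurrence,
            ") must be in [1, rounds = ", rounds, "]")
  if (threshold <= 0 || threshold >= 1) stop_ts("threshold must be in (0, 1)")
  bad_fam <- setdiff(families, model_families())
  if (length(bad_fam)) stop_ts("unknown families: ", paste(bad_fam, collapse = ", "))
  paths <- c(matrix_path, labels_path, probe_map_path, gmt_path,
             signature_matrix_path, stemness_weights_path,
             external_matrix_path, survival_path)
  missing_paths <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_paths))
    stop_ts("missing input file(s): ", paste(missing_paths, collapse = ", "))
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    matrix_path = matrix_path, labels_path = labels_path,
    probe_map_path = probe_map_path, gmt_path = gmt_path,
    signature_matrix_path = signature_matrix_path,
    stemness_weights_path = stemness_weights_path,
    external_matrix_path = external_matrix_path,
    survival_path = survival_path, simulate = simulate,
    families = families, lfc_min = lfc_min, q_max = q_max,
    top_frac = top_frac, min_occurrence = as.integer(min_occurrence),
    rounds = as.integer(rounds), threshold = threshold,
    survival_beta = survival_beta, base_hazard = base_hazard,
    censor_rate = censor_rate), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields are [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, args)
}

stage_log <- function(stage, ...) message(sprintf("[%s] ", stage), ...)

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

# md5 of a text blob (config hash for resume bookkeeping)
digest_text <- function(txt) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes io -> deg -> gsea -> select -> fit -> predict -> survival ->
#' microenv in order, writing each stage's artifact under
#' `out_dir/<nn_stage>/` plus a `run_manifest.json` with input checksums,
#' the config, derived seeds and per-stage row counts. Identical inputs,
#' config and seed give byte-identical outputs. With `resume = TRUE` a
#' stage is skipped when its recorded output checksums are intact and no
#' upstream stage was recomputed; deleting one stage's output therefore
#' recomputes that stage and everything downstream, nothing upstream.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse intact stage outputs from a previous run.
#' @return List with the manifest plus the in-memory results (`selected`,
#'   `model`, `comparison`, `predictions`, `survival_results`), invisibly;
#'   the manifest is written to `out_dir/run_manifest.json`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "run_manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else NULL
  cfg_hash <- digest_text(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA, null = "null"))
  input_paths <- Filter(Negate(is.null),
                        config[c("matrix_path", "labels_path", "probe_map_path",
                                 "gmt_path", "signature_matrix_path",
                                 "stemness_weights_path",
                                 "external_matrix_path", "survival_path")])
  manifest <- list(config = unclass(config),
                   inputs = if (length(input_paths))
                     as.list(file_md5(unlist(input_paths))) else list(),
                   stages = list())
  state <- new.env(parent = emptyenv())
  state$dirty <- FALSE

  # fn(paths, load_only): computes this stage's state; writes its outputs
  # when load_only = FALSE and returns a list of row counts for the manifest
  run_stage <- function(name, outputs, fn) {
    dir_ <- file.path(out, name)
    dir.create(dir_, showWarnings = FALSE)
    paths <- file.path(dir_, outputs)
    prev <- old_manifest$stages[[name]]
    reusable <- !state$dirty && !is.null(prev) && all(file.exists(paths)) &&
      identical(as.list(file_md5(paths)), prev$outputs) &&
      identical(prev$config_hash, cfg_hash)
    if (reusable) {
      stage_log(name, "up to date, skipped")
      fn(paths, load_only = TRUE)
      manifest$stages[[name]] <<- prev
    } else {
      state$dirty <- TRUE
      counts <- fn(paths, load_only = FALSE)
      stage_log(name, "wrote ", paste(basename(paths), collapse = ", "))
      manifest$stages[[name]] <<- list(
        outputs = as.list(file_md5(paths)),
        config_hash = cfg_hash,
        seed = derive_seed(config$seed, name),
        counts = counts)
    }
    invisible(NULL)
  }

  # ---- 01_io ----
  run_stage("01_io", c("matrix_raw.tsv", "matrix_zscore.tsv", "labels.tsv"),
    function(paths, load_only) {
      if (!is.null(config$simulate)) {
        sim_args <- config$simulate
        sim_args$seed <- derive_seed(config$seed, "simulate")
        cohort <- do.call(generate_cohort, sim_args)
        state$m_raw <- cohort$matrix
        state$labels <- cohort$labels
        state$truth <- cohort$truth
      } else {
        m <- read_matrix(config$matrix_path)
        if (!is.null(config$probe_map_path))
          m <- collapse_probes(m, read_probe_map(config$probe_map_path))
        lab <- read.delim(config$labels_path)
        state$labels <- setNames(as_label01(lab[[2L]]), lab[[1L]])
        m <- unclass(m)[, names(state$labels), drop = FALSE]
        state$m_raw <- expression_matrix(m, "raw_log")
      }
      state$m_z <- zscore_genes(state$m_raw)
      if (!load_only) {
        write_matrix(state$m_raw, paths[1])
        write_matrix(state$m_z, paths[2])
        write.table(data.frame(sample = names(state$labels),
                               label = unname(state$labels)),
                    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(genes = nrow(state$m_raw), samples = ncol(state$m_raw))
    })

  # ---- 02_deg ----
  run_stage("02_deg", "deg_table.tsv", function(paths, load_only) {
    records <- moderated_t(state$m_raw, state$labels)
    degs <- filter_degs(records, config$lfc_min, config$q_max)
    state$degs <- degs
    if (!load_only) {
      con <- file(paths[1], "w")
      writeLines(paste("# log2FC = mean(nonresponder) - mean(responder);",
                       "positive = up in nonresponders"), con)
      suppressWarnings(write.table(degs, con, sep = "\t", quote = FALSE,
                                   row.names = FALSE))
      close(con)
    }
    cnt <- attr(degs, "counts")
    list(total = unname(cnt["total"]), up = unname(cnt["up"]),
         down = unname(cnt["down"]))
  })
  if (nrow(state$degs) < 2L)
    stop_ts("stage 02_deg: fewer than 2 DEGs pass the thresholds; ",
            "cannot continue to selection")

  # ---- 03_gsea (optional) ----
  if (!is.null(config$gmt_path)) {
    run_stage("03_gsea", c("set_scores.tsv", "set_contrasts.tsv"),
      function(paths, load_only) {
        sets <- read_gmt(config$gmt_path)
        scores <- sample_enrichment(state$m_z, sets)
        contrasts <- contrast_sets(scores, state$labels)
        if (!load_only) {
          write.table(data.frame(set = rownames(scores), scores,
                                 check.names = FALSE),
                      paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(contrasts, paths[2], sep = "\t", quote = FALSE,
                      row.names = FALSE)
        }
        list(sets = nrow(scores))
      })
  }

  # ---- 04_select ----
  run_stage("04_select",
            c(paste0("occurrence_", config$families, ".tsv"),
              "selected_genes.txt"),
    function(paths, load_only) {
      n_led <- length(config$families)
      if (load_only) {
        state$selected <- readLines(paths[n_led + 1L])
        return(NULL)
      }
      m_deg <- expression_matrix(
        unclass(state$m_z)[intersect(rownames(state$m_z), state$degs$gene), ,
                           drop = FALSE], "zscore")
      occ_fam <- list()
      for (fam in config$families) {
        res <- run_iterations(
          m_deg, state$labels, fam, rounds = config$rounds,
          base_seed = derive_seed(config$seed, paste0("select_", fam)))
        occ_fam[[fam]] <- accumulate_occurrence(res, config$top_frac)
      }
      state$occurrence <- occ_fam
      allowed <- if (!is.null(config$external_matrix_path))
        rownames(read_matrix(config$external_matrix_path)) else NULL
      # union rule: a gene is stable if any family reaches min_occurrence
      pooled <- occ_fam[[1L]]
      if (length(occ_fam) > 1L) {
        occ_mat <- sapply(occ_fam, function(o)
          o$occurrence[match(pooled$gene, o$gene)])
        pooled$occurrence <- as.integer(apply(occ_mat, 1, max))
      }
      state$selected <- select_genes(pooled, config$min_occurrence, allowed)
      for (i in seq_len(n_led)) write_occurrence(occ_fam[[i]], paths[i])
      writeLines(state$selected, paths[n_led + 1L])
      list(selected = length(state$selected))
    })

  # ---- 05_fit ----
  run_stage("05_fit", c("model_comparison.tsv", "signature_model.json"),
    function(paths, load_only) {
      if (load_only) {
        state$model <- read_signature_model(paths[2])
        state$comparison <- read.delim(paths[1])
        return(NULL)
      }
      m_sel <- expression_matrix(
        unclass(state$m_z)[state$selected, , drop = FALSE], "zscore")
      cmp <- compare_models(m_sel, state$labels, config$families,
                            rounds = config$rounds,
                            base_seed = derive_seed(config$seed, "compare"))
      winner <- attr(cmp, "winner")
      fit_fam <- if (winner %in% c("linear_svm", "lasso_logistic")) winner
                 else "linear_svm"
      state$model <- fit_final(m_sel, state$labels, fit_fam,
                               seed = derive_seed(config$seed, "fit"),
                               threshold = config$threshold)
      state$comparison <- cmp
      write.table(cbind(cmp, winner = cmp$family == winner), paths[1],
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_signature_model(state$model, paths[2])
      list(winner = winner, n_genes = length(state$model$genes))
    })

  # ---- 06_predict ----
  run_stage("06_predict", "predictions.tsv", function(paths, load_only) {
    if (!is.null(config$external_matrix_path)) {
      m_ext <- zscore_genes(read_matrix(config$external_matrix_path))
    } else if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- derive_seed(config$seed, "simulate_external")
      ext <- do.call(generate_cohort, sim_args)
      state$external_labels <- ext$labels
      state$external_truth <- ext$truth
      m_ext <- zscore_genes(ext$matrix)
    } else {
      m_ext <- state$m_z
    }
    state$m_ext <- m_ext
    state$predictions <- predict_cohort(state$model, m_ext)
    if (!load_only)
      write.table(state$predictions, paths[1], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    list(samples = nrow(state$predictions),
         nonresponse_calls = sum(state$predictions$call == "nonresponse"))
  })

  # ---- 07_survival ----
  surv_tab <- NULL
  if (!is.null(config$survival_path)) {
    surv_tab <- read.delim(config$survival_path)
  } else if (!is.null(config$simulate)) {
    # hazard driven by the planted informative-gene score of the scored cohort
    truth <- state$external_truth %||% state$truth
    w <- truth$informative_genes
    x <- unclass(state$m_ext)[names(w), , drop = FALSE]
    true_score <- drop(crossprod(x, sign(w))) / length(w)
    surv_tab <- generate_survival(
      setNames(true_score, colnames(state$m_ext)),
      beta = config$survival_beta, base_hazard = config$base_hazard,
      censor_rate = config$censor_rate,
      seed = derive_seed(config$seed, "survival"))
  }
  if (!is.null(surv_tab)) {
    run_stage("07_survival", c("survival_groups.tsv", "survival_results.json"),
      function(paths, load_only) {
        tab <- merge(surv_tab, state$predictions[, c("sample", "call")],
                     by = "sample")
        tab$nonresponse <- as.integer(tab$call == "nonresponse")
        if (length(unique(tab$nonresponse)) < 2L) {
          warning("all samples predicted into one group; survival contrast skipped")
          res <- list(note = "single predicted group")
        } else {
          lr <- logrank_test(tab$time, tab$event, tab$call)
          cox <- cox_fit(tab, "nonresponse")
          probs <- state$predictions$probability[
            match(tab$sample, state$predictions$sample)]
          td <- time_dependent_roc(probs, tab$time, tab$event)
          res <- list(logrank = lr[c("chi2", "p")],
                      cox = as.list(cox[1L, ]),
                      roc_auc = setNames(as.list(td$auc),
                                         paste0("m", td$horizon)))
        }
        state$survival_results <- res
        if (!load_only) {
          write.table(tab[order(tab$sample), ], paths[1], sep = "\t",
                      quote = FALSE, row.names = FALSE)
          jsonlite::write_json(res, paths[2], auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
        }
        list(samples = nrow(tab), events = sum(tab$event))
      })
  }

  # ---- 08_microenv ----
  if (!is.null(config$signature_matrix_path) ||
      !is.null(config$stemness_weights_path)) {
    run_stage("08_microenv", c("fractions.tsv", "stemness.tsv"),
      function(paths, load_only) {
        counts <- list()
        if (!is.null(config$signature_matrix_path)) {
          sig <- read_signature_matrix(config$signature_matrix_path)
          fr <- deconvolve(state$m_raw, sig)
          state$fractions <- fr
          if (!load_only)
            write.table(data.frame(sample = rownames(fr), fr,
                                   check.names = FALSE),
                        paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
          counts$cell_types <- ncol(fr)
        } else if (!load_only) writeLines("sample", paths[1])
        if (!is.null(config$stemness_weights_path)) {
          w <- read_weight_vector(config$stemness_weights_path)
          st <- stemness_index(state$m_raw, w)
          state$stemness <- st
          if (!load_only)
            write.table(st, paths[2], sep = "\t", quote = FALSE,
                        row.names = FALSE)
          counts$stemness_samples <- nrow(st)
        } else if (!load_only) writeLines("sample\trho\tmRNAsi", paths[2])
        counts
      })
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest,
                 selected = state$selected,
                 model = state$model,
                 comparison = state$comparison,
                 predictions = state$predictions,
                 survival_results = if (!is.null(state$survival_results))
                   state$survival_results else NULL))
}
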