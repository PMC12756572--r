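# End-to-end orchestration: fixed stage order
# simulate? -> preprocess -> endotype -> basicq -> de -> gsea -> deconvolve
# -> signature -> associate, with per-stage logging, seeds and a manifest
# sufficient to re-run any stage in isolation.

#' Default pipeline configuration
#'
#' Plain key-value configuration targeting the bundled synthetic cohort;
#' every stage parameter is validated before any stage runs.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param ... Overrides for any configuration entry.
#' @return A `run_config` list.
#' @export
default_config <- function(out_dir = tempfile("endokit_run_"), seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    simulate = TRUE, cohort = NULL, expression_path = NULL,
    clinical_path = NULL, gmt_path = NULL, signature_path = NULL,
    stages = c("preprocess", "endotype", "basicq", "de", "gsea",
               "deconvolve", "signature", "associate"),
    top_frac = 0.15, floor = 0, k_max = 6L, gap_B = 50L, n_restarts = 25L,
    n_perm = 1000L, nus = c(0.25, 0.5, 0.75), max_genes = 10L,
    fc_threshold = 1.5, alpha = 0.05, deconv_max_samples = 40L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$top_frac > 0, cfg$top_frac <= 1, cfg$k_max >= 2,
            cfg$gap_B >= 2, cfg$n_perm >= 10, cfg$max_genes >= 1,
            all(cfg$nus > 0 & cfg$nus < 1), cfg$alpha > 0, cfg$alpha < 1)
  bad <- setdiff(cfg$stages, c("preprocess", "endotype", "basicq", "de",
                               "gsea", "deconvolve", "signature", "associate"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full endotyping pipeline
#'
#' Executes the enabled stages in fixed order, writing each stage's tables
#' under `config$out_dir` and a JSON run manifest (stage, wall time, seed,
#' input hashes, outputs). A failing stage stops the run with the stage
#' named; stages whose upstream dependency was skipped raise a dependency
#' error before execution.
#'
#' @param config A [default_config()] list.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  manifest <- list(seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  note <- function(...) {
    msg <- sprintf(...)
    message("[endokit] ", msg)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = log_file,
        append = TRUE, sep = "")
  }
  record <- function(stage, t0, outputs, status = "ok") {
    manifest$stages[[stage]] <<- list(
      stage = stage, status = status, seed = config$seed,
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
      outputs = outputs,
      input_hashes = as.list(state$hashes %||% list()))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  run_stage <- function(stage, deps, fn) {
    if (!(stage %in% config$stages)) {
      manifest$stages[[stage]] <<- list(stage = stage, status = "skipped")
      note("stage %s skipped", stage)
      return(invisible(NULL))
    }
    missing <- deps[!vapply(deps, function(d) !is.null(state[[d]]), logical(1))]
    if (length(missing))
      stop(sprintf("stage '%s': missing dependency %s (upstream stage skipped?)",
                   stage, paste(missing, collapse = ", ")), call. = FALSE)
    t0 <- as.numeric(Sys.time())
    outputs <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    record(stage, t0, outputs)
    note("stage %s done (%.1fs)", stage,
         as.numeric(Sys.time()) - t0)
  }

  # inputs: simulate or load
  t0 <- as.numeric(Sys.time())
  if (isTRUE(config$simulate)) {
    sim <- simulate_cohort(config$cohort %||% cohort_spec(seed = config$seed))
    state$expr <- sim$expression; state$clinical <- sim$clinical
    state$sets <- sim$sets; state$signature <- sim$signature
    state$truth <- sim$truth
    write_expression(sim$expression, file.path(config$out_dir, "expression.tsv"))
    write_clinical(sim$clinical, file.path(config$out_dir, "clinical.csv"))
    write_gmt(sim$sets, file.path(config$out_dir, "sets.gmt"))
    sig_df <- data.frame(gene_id = rownames(sim$signature), sim$signature,
                         check.names = FALSE)
    utils::write.table(sig_df, file.path(config$out_dir, "signature.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(endotype = sim$truth$endotype,
                              marker_gene_ids = sim$truth$marker_gene_ids),
                         file.path(config$out_dir, "truth.json"))
    record("simulate", t0, c("expression.tsv", "clinical.csv", "sets.gmt",
                             "signature.tsv", "truth.json"))
  } else {
    paths <- c(expression = config$expression_path,
               clinical = config$clinical_path, gmt = config$gmt_path,
               signature = config$signature_path)
    absent <- paths[!vapply(paths, function(p) !is.null(p) && file.exists(p),
                            logical(1))]
    if (length(absent))
      stop("missing input file(s): ", paste(names(absent), collapse = ", "))
    state$expr <- read_expression(config$expression_path)
    state$clinical <- read_clinical(config$clinical_path)
    state$sets <- read_gmt(config$gmt_path)
    sig <- utils::read.delim(config$signature_path, check.names = FALSE)
    state$signature <- as.matrix(sig[, -1])
    rownames(state$signature) <- sig[[1]]
    state$hashes <- as.list(tools::md5sum(unlist(paths)))
    record("load", t0, character(0))
  }

  run_stage("preprocess", character(0), function() {
    pp <- preprocess_pipeline(state$expr, floor = config$floor,
                              top_frac = config$top_frac)
    state$features <- pp$features; state$genes <- pp$genes
    write_expression(pp$features, file.path(config$out_dir, "features.tsv"))
    jsonlite::write_json(unclass(pp$report),
                         file.path(config$out_dir, "preprocess_report.json"),
                         auto_unbox = TRUE, force = TRUE)
    c("features.tsv", "preprocess_report.json")
  })

  run_stage("endotype", "features", function() {
    x <- t(unclass(state$features))
    diag <- gap_statistic(x, k_max = config$k_max, B = config$gap_B,
                          seed = config$seed)
    res <- assign_endotypes(x, k = 2L, seed = config$seed,
                            n_restarts = config$n_restarts)
    val <- validate_endotypes(x, res$labels, seed = config$seed)
    state$endotype <- res
    utils::write.csv(data.frame(sample_id = names(res$labels),
                                endotype = res$labels),
                     file.path(config$out_dir, "labels.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(diagnostics = unclass(diag),
                              validation = unclass(val),
                              sizes = res$sizes),
                         file.path(config$out_dir, "endotype_diagnostics.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
    c("labels.csv", "endotype_diagnostics.json")
  })

  run_stage("basicq", "endotype", function() {
    model <- diffusion_map(t(unclass(state$features)))
    score <- basicq_score(model, state$endotype$labels)
    state$basicq <- score$basicq
    utils::write.csv(data.frame(sample_id = names(score$basicq),
                                basicq = score$basicq),
                     file.path(config$out_dir, "basicq.csv"), row.names = FALSE)
    jsonlite::write_json(list(sigma = model$sigma, alpha = model$alpha,
                              eigenvalues = model$eigenvalues,
                              orientation_sign = score$orientation_sign),
                         file.path(config$out_dir, "basicq_model.json"),
                         auto_unbox = TRUE, digits = NA)
    c("basicq.csv", "basicq_model.json")
  })

  run_stage("de", "endotype", function() {
    fits <- fit_gene_models(state$genes, state$endotype$labels)
    state$de <- ebayes_moderate(fits)
    tab <- volcano_table(state$de, fc_threshold = config$fc_threshold,
                         alpha = config$alpha)
    utils::write.table(tab[, c("gene", "log2fc", "t_mod", "p", "adj_p",
                               "flagged")],
                       file.path(config$out_dir, "de_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    "de_results.tsv"
  })

  run_stage("gsea", "de", function() {
    ranks <- rank_genes(state$de)
    res <- gsea_preranked(ranks, state$sets, n_perm = config$n_perm,
                          seed = config$seed)
    out <- res[, c("set", "size_used", "ES", "NES", "p", "adj_p")]
    utils::write.table(out, file.path(config$out_dir, "gsea_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    "gsea_results.tsv"
  })

  run_stage("deconvolve", "basicq", function() {
    # nu-SVR per sample is the slow stage; a deterministic subsample keeps
    # desk-scale runs fast while covering both endotypes
    idx <- seq_len(ncol(state$genes))
    if (length(idx) > config$deconv_max_samples) {
      set.seed(config$seed)
      idx <- sort(sample(idx, config$deconv_max_samples))
    }
    sub <- expression_matrix(unclass(state$genes)[, idx, drop = FALSE],
                             rownames(state$genes),
                             colnames(state$genes)[idx])
    dc <- deconvolve_cohort(sub, state$signature, nus = config$nus)
    assoc <- fractions_vs_score(dc$fractions,
                                state$basicq[rownames(dc$fractions)])
    utils::write.table(data.frame(sample_id = rownames(dc$fractions),
                                  dc$fractions, check.names = FALSE),
                       file.path(config$out_dir, "fractions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(assoc, file.path(config$out_dir, "associations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    c("fractions.tsv", "associations.tsv")
  })

  run_stage("signature", "de", function() {
    sig <- volcano_table(state$de, config$fc_threshold, config$alpha)
    de_genes <- sig$gene[sig$flagged]
    if (length(de_genes) < 2) stop("too few flagged genes for selection")
    x <- t(unclass(state$genes)[de_genes, , drop = FALSE])
    y <- as.integer(state$endotype$labels == 1)
    trace <- fspls_select(x, y, max_k = config$max_genes)
    cand <- utils::head(trace$selected_genes, 10L)
    panels <- best_combination(x, y, cand, sizes = 1:min(3, length(cand)))
    jsonlite::write_json(list(selected_genes = trace$selected_genes,
                              step_p = trace$step_p,
                              stop_reason = trace$stop_reason),
                         file.path(config$out_dir, "fspls_trace.json"),
                         auto_unbox = TRUE, digits = NA)
    ptab <- do.call(rbind, lapply(panels, function(p) data.frame(
      genes = paste(p$genes, collapse = "+"), auroc = p$auroc,
      threshold = p$threshold, sensitivity = p$sensitivity,
      specificity = p$specificity, youden_j = p$youden_j)))
    utils::write.table(ptab, file.path(config$out_dir, "panels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    state$panels <- panels
    c("fspls_trace.json", "panels.tsv")
  })

  run_stage("associate", c("endotype", "basicq"), function() {
    t1 <- endotype_table1(state$clinical, state$endotype$labels)
    vfd <- fit_vfd_regression(state$clinical,
                              endotype = state$endotype$labels)
    oc <- outcome_records(state$clinical)
    cox <- fit_cox_model(ifelse(oc$event_composite, 30L,
                                oc$time_to_extubation),
                         oc$event_composite, state$clinical,
                         endotype = state$endotype$labels)
    write_results(list(table1_continuous = t1$continuous,
                       vfd_model = vfd, cox_model = cox),
                  config$out_dir)
    c("table1_continuous.csv", "vfd_model.csv", "cox_model.csv",
      "manifest.json")
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, force = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
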