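#' Run the full analysis pipeline
#'
#' Executes filter -> normalize -> differential -> cluster -> enrich ->
#' egonet -> classify on the supplied inputs, writing every intermediate
#' table under `out_dir` and logging one line per stage (input/output
#' record counts) to stderr.  The run is a pure function of
#' (inputs, config, seed): per-stage child seeds are derived
#' deterministically from the master seed by stage index.  When no probe
#' survives stage 2 the pipeline terminates gracefully with status
#' `"no differential CpGs"` and the downstream stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @param beta probes x samples matrix (or TSV path).
#' @param annot probe annotation data.frame (or TSV path).
#' @param groups sample-group data.frame (or TSV path).
#' @param edges interaction edge data.frame (or TSV path).
#' @param gene_sets named list of gene sets (or GMT path).
#' @param out_dir output directory (created if needed).
#' @return a `run_manifest`: list with `status`, `stages` (data.frame of
#'   stage, n_in, n_out, output, elapsed), `seed`, and the in-memory
#'   stage results in `results`.
#' @export
run_pipeline <- function(config, beta, annot, groups, edges, gene_sets,
                         out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(beta)) beta <- read_beta_matrix(beta)
  if (is.character(annot)) annot <- read_probe_annotation(annot)
  if (is.character(groups)) groups <- read_group_table(groups)
  if (is.character(edges)) edges <- read_network_edges(edges)
  if (is.character(gene_sets)) gene_sets <- read_gene_sets(gene_sets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- list()
  results <- list()
  log_stage <- function(name, n_in, n_out, output, t0) {
    message(sprintf("[%s] in=%d out=%d -> %s", name, n_in, n_out, output))
    stages[[name]] <<- data.frame(
      stage = name, n_in = n_in, n_out = n_out, output = output,
      elapsed = round(as.numeric(Sys.time()) - t0, 3),
      stringsAsFactors = FALSE)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # 1. filter
  t0 <- as.numeric(Sys.time())
  report <- run_stage("filter", filter_probes(annot, config))
  beta_f <- beta[rownames(beta) %in% report$kept, , drop = FALSE]
  annot_f <- annot[annot$probe_id %in% report$kept, , drop = FALSE]
  write_result_table(
    data.frame(criterion = c(names(report$removed), "kept"),
               count = c(as.integer(report$removed), length(report$kept))),
    file.path(out_dir, "filter_report.tsv"))
  log_stage("filter", report$n_input, length(report$kept),
            "filter_report.tsv", t0)
  results$filter <- report

  # 2. normalize
  t0 <- as.numeric(Sys.time())
  beta_n <- run_stage("normalize",
                      withCallingHandlers(
                        normalize_typeII(beta_f, annot_f),
                        warning = function(w) {
                          message("[normalize] ", conditionMessage(w))
                          invokeRestart("muffleWarning")
                        }))
  write_beta_matrix(beta_n, file.path(out_dir, "beta_normalized.tsv"))
  log_stage("normalize", nrow(beta_f), nrow(beta_n),
            "beta_normalized.tsv", t0)
  results$beta <- beta_n

  # 3. differential
  t0 <- as.numeric(Sys.time())
  calls <- run_stage("differential",
                     test_differential(beta_n, groups, config))
  s1 <- stage1_select(calls, config)
  s2 <- stage2_refine(s1, config)
  write_result_table(calls, file.path(out_dir, "diffcalls.tsv"))
  write_result_table(s2, file.path(out_dir, "differential_cpgs.tsv"))
  diff_genes <- sort(unique(annot_f$gene[match(s2$probe_id,
                                               annot_f$probe_id)]))
  writeLines(diff_genes, file.path(out_dir, "differential_genes.txt"))
  log_stage("differential", nrow(calls), nrow(s2), "diffcalls.tsv", t0)
  results$calls <- calls; results$stage1 <- s1; results$stage2 <- s2
  results$diff_genes <- diff_genes

  manifest <- function(status) {
    out <- list(status = status,
                stages = do.call(rbind, unname(stages)),
                seed = config$rng_seed, results = results)
    class(out) <- "run_manifest"
    # elapsed stays in memory only so identical runs write identical bytes
    write_result_table(out$stages[, c("stage", "n_in", "n_out", "output")],
                       file.path(out_dir, "manifest.tsv"))
    out
  }
  if (nrow(s2) == 0L) {
    message("[pipeline] no differential CpGs; downstream stages skipped")
    return(manifest("no differential CpGs"))
  }

  # 4. cluster
  t0 <- as.numeric(Sys.time())
  clus <- run_stage("cluster",
                    cluster_samples(beta_n[s2$probe_id, , drop = FALSE],
                                    groups))
  write_result_table(
    data.frame(sample_id = names(clus$labels),
               cluster = as.integer(clus$labels)),
    file.path(out_dir, "cluster_labels.tsv"))
  log_stage("cluster", ncol(beta_n), 2L, "cluster_labels.tsv", t0)
  results$cluster <- clus

  # 5. enrich (universe: genes with >= 1 QC-surviving probe)
  t0 <- as.numeric(Sys.time())
  universe <- sort(unique(annot_f$gene))
  enr <- run_stage("enrich",
                   suppressWarnings(
                     fisher_enrich(diff_genes, universe, gene_sets,
                                   config)))
  write_result_table(enr, file.path(out_dir, "enrichment.tsv"))
  log_stage("enrich", length(gene_sets), sum(enr$significant),
            "enrichment.tsv", t0)
  results$enrichment <- enr

  # 6. egonet
  t0 <- as.numeric(Sys.time())
  ego <- run_stage("egonet",
                   egonet_analysis(beta_n, annot_f, calls, diff_genes,
                                   edges, config))
  if (!identical(ego$status, "ok")) {
    message("[pipeline] egonet: ", ego$status)
    results$egonet <- ego
    return(manifest(ego$status))
  }
  write_result_table(ego$subnet$edges, file.path(out_dir,
                                                 "subnetwork_edges.tsv"))
  write_result_table(ego$scores, file.path(out_dir, "ego_scores.tsv"))
  log_stage("egonet", nrow(edges), sum(ego$scores$is_ego),
            "ego_scores.tsv", t0)
  results$egonet <- ego

  # 7. classify on ego-gene features
  t0 <- as.numeric(Sys.time())
  ego_genes <- ego$scores$gene[ego$scores$is_ego]
  feat <- t(ego$gene_beta[ego_genes, , drop = FALSE])
  labels <- groups$group[match(rownames(feat), groups$sample_id)]
  rep7 <- run_stage("classify", {
    plan <- split_samples(rownames(feat), groups, config,
                          seed = stage_seed(config$rng_seed, 7L))
    model <- train_linear_svm(feat[plan$train, , drop = FALSE],
                              labels[match(plan$train, rownames(feat))],
                              config,
                              seed = stage_seed(config$rng_seed, 8L))
    ev <- evaluate(model, feat[plan$test, , drop = FALSE],
                   labels[match(plan$test, rownames(feat))])
    list(plan = plan, model = model, report = ev)
  })
  ev <- rep7$report
  write_result_table(
    data.frame(metric = c("TP", "FP", "TN", "FN", "AUC", "accuracy",
                          "MCC", "sensitivity", "specificity", "C"),
               value = c(ev$tp, ev$fp, ev$tn, ev$fn, ev$auc, ev$accuracy,
                         ev$mcc, ev$sensitivity, ev$specificity, ev$C)),
    file.path(out_dir, "classification_report.tsv"))
  write_result_table(
    data.frame(sample_id = names(ev$scores), score = unname(ev$scores)),
    file.path(out_dir, "test_scores.tsv"))
  log_stage("classify", length(rep7$plan$train), length(rep7$plan$test),
            "classification_report.tsv", t0)
  results$classify <- rep7

  manifest("ok")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest (status:", x$status, ")\n")
  print(x$stages[, c("stage", "n_in", "n_out", "output")], row.names = FALSE)
  invisible(x)
}
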