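#' Run the full integrative-network prognosis pipeline
#'
#' Chains preprocessing (filters, effective gene methylation), network
#' construction (combined-correlation similarity, soft-power adjacency),
#' module detection, eigengene computation, penalized-Cox module selection,
#' AFT fitting, risk classification and survival evaluation. Inputs may be
#' in-memory objects or file paths. Identical inputs + config (including
#' seed) give identical outputs.
#'
#' @param expression Gene-by-sample matrix or TSV path.
#' @param clinical A [survival_table()] or clinical TSV path.
#' @param methylation Optional locus-by-sample beta matrix or TSV path.
#' @param probe_map Optional [probe_gene_map()] or TSV path (required with
#'   `methylation`).
#' @param config A [run_config()].
#' @param output_dir If given, all artifacts (modules.tsv, eigengenes.tsv,
#'   weights.tsv, risk.tsv, model.json, report.json, relevance reports) are
#'   written there.
#' @return A list of class `"pipeline_result"` with every intermediate
#'   object plus a `report` list of counts and test statistics.
#' @export
run_pipeline <- function(expression, clinical, methylation = NULL,
                         probe_map = NULL, config = run_config(),
                         output_dir = NULL) {
  validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(expression))
    expression <- read_omics_matrix(expression, "expression")
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  if (is.character(methylation))
    methylation <- read_omics_matrix(methylation, "methylation")
  if (is.character(probe_map)) probe_map <- read_probe_map(probe_map)
  if (!is.null(methylation) && is.null(probe_map))
    stop("`probe_map` is required when methylation data are supplied")
  report <- list(config = unclass(config))

  # --- preprocess -----------------------------------------------------------
  expr <- expression
  if (config$log_transform)
    expr <- stage("preprocess", log_transform(expr, config$log_offset))
  expr_report <- stage("preprocess", filter_features(
    expr, clinical, tau = config$tau, variance_floor = config$variance_floor,
    missing_cap = config$missing_cap,
    deceased_only = config$censored_only_correlation))
  report$n_genes_input <- nrow(expr)
  report$n_genes_expression_pass <- sum(expr_report$retained)

  gene_meth <- NULL
  meth_report <- NULL
  use_meth <- !is.null(methylation) && config$methylation_weight < 1
  if (use_meth) {
    loci_report <- stage("preprocess", filter_features(
      methylation, clinical, tau = config$tau,
      variance_floor = config$variance_floor,
      missing_cap = config$missing_cap,
      deceased_only = config$censored_only_correlation))
    retained_loci <- attr(loci_report, "retained_ids")
    report$n_loci_input <- nrow(methylation)
    report$n_loci_pass <- length(retained_loci)
    if (length(retained_loci) > 0) {
      gene_meth <- stage("preprocess", effective_gene_methylation(
        methylation, probe_map, retained_loci,
        aggregate = config$aggregate, survival = clinical))
      meth_report <- stage("preprocess", filter_features(
        gene_meth$values, clinical, tau = config$tau,
        variance_floor = config$variance_floor,
        missing_cap = config$missing_cap,
        deceased_only = config$censored_only_correlation))
      report$n_genes_methylation_pass <- sum(meth_report$retained)
    }
  }

  genes <- if (!is.null(meth_report))
    stage("preprocess", select_relevant_genes(expr_report, meth_report))
  else attr(expr_report, "retained_ids")
  # eigengenes need expression: genes observed only on methylation are logged
  n_meth_only <- sum(!genes %in% rownames(expr))
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0)
    stop("[preprocess] no survival-relevant gene with expression data")
  report$n_genes_relevant <- length(genes)
  report$n_genes_methylation_only_dropped <- n_meth_only
  message(sprintf(
    "preprocess: %d/%d genes retained (%d expression-pass%s)",
    length(genes), nrow(expr), sum(expr_report$retained),
    if (!is.null(meth_report))
      sprintf(", %d methylation-pass", sum(meth_report$retained)) else ""))

  # --- network --------------------------------------------------------------
  gm_sub <- NULL
  if (!is.null(gene_meth)) {
    shared <- intersect(genes, rownames(gene_meth$values))
    if (length(shared) >= 2)
      gm_sub <- gene_meth$values[shared, , drop = FALSE]
  }
  network <- stage("network", build_network(
    expr[genes, , drop = FALSE], gm_sub, w = config$methylation_weight,
    beta = config$soft_power, min_pairs = config$min_pairs))

  # --- modules & eigengenes -------------------------------------------------
  assignment <- stage("modules", detect_modules(
    network, linkage = config$linkage, cut_method = config$cut_method,
    cut_height = config$cut_height,
    min_module_size = config$min_module_size))
  report$n_modules <- assignment$n_modules
  report$module_sizes <- as.integer(table(
    assignment$labels[assignment$labels > 0]))
  message(sprintf("modules: %d modules detected (%d background genes)",
                  assignment$n_modules, sum(assignment$labels == 0)))
  if (assignment$n_modules == 0)
    stop("[modules] no module of at least min_module_size genes")
  eigengenes <- stage("eigengenes",
                      compute_eigengenes(expr[genes, , drop = FALSE],
                                         assignment))

  # --- selection & AFT ------------------------------------------------------
  selection <- NULL
  if (assignment$n_modules >= 2) {
    selection <- stage("select", select_prognostic_modules(
      eigengenes, clinical, folds = config$cv_folds, seed = config$seed,
      lambda_rule = config$lambda_rule))
    selected <- selection$selected
    if (length(selected) == 0 && config$lambda_rule == "lambda.1se") {
      selection <- stage("select", select_prognostic_modules(
        eigengenes, clinical, folds = config$cv_folds, seed = config$seed,
        lambda_rule = "lambda.min"))
      selected <- selection$selected
    }
  } else selected <- character(0)
  if (length(selected) == 0) {
    # lasso found nothing: fall back to the single most survival-correlated
    msc <- module_survival_correlation(eigengenes, clinical)
    selected <- msc$module_id[1]
    report$selection_fallback <- TRUE
  }
  report$selected_modules <- selected
  message("select: ", paste(selected, collapse = ", "))
  model <- stage("classify", fit_aft_model(
    eigengenes, clinical, selected = selected, family = config$aft_family,
    cutpoint_scheme = config$cutpoint_scheme))
  pred <- stage("classify", predict_survival_time(model, eigengenes))
  risk <- stage("classify", classify_risk(pred, model$cutpoints))
  report$risk_counts <- as.list(table(risk$risk_class))

  # --- evaluation -----------------------------------------------------------
  grp <- stats::setNames(as.character(risk$risk_class), risk$sample_id)
  tests <- list()
  lh <- grp[grp %in% c("low", "high")]
  tests$logrank_low_vs_high <- tryCatch(
    logrank_test(clinical[clinical$sample_id %in% names(lh), , drop = FALSE],
                 lh), error = function(e) NULL)
  tests$logrank_three_group <- tryCatch(
    logrank_test(clinical, grp), error = function(e) NULL)
  tests$logrank_high_vs_rest <- tryCatch(
    logrank_test(clinical, factor(ifelse(grp == "high", "high", "rest"))[
      match(clinical$sample_id, names(grp))]),
    error = function(e) NULL)
  report$tests <- lapply(Filter(Negate(is.null), tests), unclass)

  result <- structure(list(expression = expr, clinical = clinical,
                           gene_meth = gene_meth, genes = genes,
                           expr_report = expr_report,
                           meth_report = meth_report, network = network,
                           assignment = assignment, eigengenes = eigengenes,
                           selection = selection, model = model,
                           risk = risk, report = report),
                      class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_outputs(result, output_dir)
  result
}

#' Write all pipeline artifacts to a directory
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_modules(result$assignment, file.path(dir, "modules.tsv"))
  write_eigengenes(result$eigengenes, file.path(dir, "eigengenes.tsv"))
  write_weights(result$eigengenes, file.path(dir, "weights.tsv"))
  write_risk_table(result$risk, file.path(dir, "risk.tsv"))
  write_risk_model(result$model, file.path(dir, "model.json"))
  write_relevance_report(result$expr_report,
                         file.path(dir, "relevance_expression.tsv"))
  if (!is.null(result$meth_report))
    write_relevance_report(result$meth_report,
                           file.path(dir, "relevance_methylation.tsv"))
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Apply a stored risk model to a new expression cohort
#'
#' Projects the cohort's standardized expression on the model's gene weight
#' vectors, predicts expected survival time from the stored AFT coefficients
#' and classifies with the stored (training) cutpoints — no refitting, so
#' validation cohorts lacking methylation can be scored.
#'
#' @param model A `risk_model` (or path to its JSON).
#' @param expression Gene-by-sample matrix or TSV path.
#' @param min_gene_frac Passed to [project_eigengenes()].
#' @return A `risk_table`.
#' @export
apply_risk_model <- function(model, expression, min_gene_frac = 0.5) {
  if (is.character(model)) model <- read_risk_model(model)
  if (is.character(expression))
    expression <- read_omics_matrix(expression, "expression")
  eg <- project_eigengenes(expression, model$weights,
                           min_gene_frac = min_gene_frac)
  pred <- predict_survival_time(model, eg)
  classify_risk(pred, model$cutpoints)
}
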