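#' Natural-log transform of a non-negative omics matrix
#'
#' `x -> ln(x + offset)`; missing values stay missing. Intended for RPKM-like
#' expression values.
#'
#' @param x Numeric matrix (values >= 0 where present).
#' @param offset Small positive constant added before the log. Default 1.
#' @return Transformed matrix (same class/attributes).
#' @export
log_transform <- function(x, offset = 1) {
  if (offset <= 0) stop("`offset` must be positive")
  if (any(!is.na(x) & x < 0)) stop("log_transform requires non-negative values")
  x[] <- log(x + offset)
  x
}

#' Pearson correlation of a feature with overall survival
#'
#' Correlates per-sample feature values with observed overall-survival time on
#' the shared sample set. By default all samples contribute their observed
#' (possibly censored) follow-up time; `deceased_only = TRUE` restricts to
#' samples with an observed death.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param survival A [survival_table()].
#' @param deceased_only Use only `event == 1` samples. Default `FALSE`.
#' @return Pearson correlation coefficient in \[-1,1\].
#' @export
survival_correlation <- function(values, survival, deceased_only = FALSE) {
  if (is.null(names(values))) stop("`values` must be named by sample id")
  surv <- survival
  if (deceased_only) surv <- surv[surv$event == 1, , drop = FALSE]
  shared <- intersect(names(values)[!is.na(values)], surv$sample_id)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  x <- values[shared]
  y <- surv$time[match(shared, surv$sample_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in feature or survival time")
  stats::cor(x, y)
}

#' Filter features on variance, missingness and survival correlation
#'
#' Retains features with variance above `variance_floor`, missing fraction at
#' most `missing_cap`, and absolute survival correlation at least `tau`.
#' Every feature's fate is recorded.
#'
#' @param x Features-by-samples numeric matrix with dimnames.
#' @param survival A [survival_table()].
#' @param tau Survival-correlation threshold in \[0,1\]. Default 0.2.
#' @param variance_floor Minimum (exclusive) variance. Default 0.
#' @param missing_cap Maximum tolerated missing fraction. Default 0.2.
#' @param deceased_only Passed to [survival_correlation()].
#' @return A `relevance_report`: data frame with columns `feature_id`, `r`,
#'   `variance`, `missing_frac`, `retained`, plus attribute `retained_ids`.
#' @export
filter_features <- function(x, survival, tau = 0.2, variance_floor = 0,
                            missing_cap = 0.2, deceased_only = FALSE) {
  if (tau < 0 || tau > 1) stop("`tau` must lie in [0,1]")
  fid <- rownames(x)
  variance <- apply(x, 1, stats::var, na.rm = TRUE)
  miss <- rowMeans(is.na(x))
  r <- rep(NA_real_, nrow(x))
  ok_var <- !is.na(variance) & variance > variance_floor
  ok_miss <- miss <= missing_cap
  for (i in which(ok_var & ok_miss)) {
    r[i] <- tryCatch(
      survival_correlation(x[i, ], survival, deceased_only = deceased_only),
      error = function(e) NA_real_)
  }
  retained <- ok_var & ok_miss & !is.na(r) & abs(r) >= tau
  rep_df <- data.frame(feature_id = fid, r = r, variance = variance,
                       missing_frac = miss, retained = retained,
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(rep_df, "retained_ids") <- fid[retained]
  class(rep_df) <- c("relevance_report", "data.frame")
  rep_df
}

#' Write a relevance report to TSV
#'
#' @param report A `relevance_report` from [filter_features()].
#' @param path Output path.
#' @export
write_relevance_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Effective per-gene methylation from retained loci
#'
#' Aggregates each gene's retained methylation loci into one value per sample.
#' The default is the missing-aware arithmetic mean over loci; `"max_abs_r"`
#' instead keeps the single locus most correlated (in absolute value) with
#' survival. Genes with no retained locus are absent from the output.
#'
#' @param meth Locus-by-sample methylation matrix.
#' @param map A [probe_gene_map()].
#' @param retained_loci Locus ids to use (subset of `rownames(meth)`).
#' @param aggregate `"mean"` (default) or `"max_abs_r"`.
#' @param survival Required for `"max_abs_r"`.
#' @return A list of class `"gene_methylation"`: `values` (gene-by-sample
#'   matrix) and `provenance` (named list gene -> contributing locus ids).
#' @export
effective_gene_methylation <- function(meth, map, retained_loci,
                                       aggregate = c("mean", "max_abs_r"),
                                       survival = NULL) {
  aggregate <- match.arg(aggregate)
  missing_loci <- setdiff(retained_loci, rownames(meth))
  if (length(missing_loci) > 0)
    stop("retained locus absent from methylation matrix: ", missing_loci[1])
  map_r <- map[map$locus_id %in% retained_loci, , drop = FALSE]
  if (nrow(map_r) == 0) stop("no retained locus maps to any gene")
  genes <- sort(unique(map_r$gene_id))
  values <- matrix(NA_real_, nrow = length(genes), ncol = ncol(meth),
                   dimnames = list(genes, colnames(meth)))
  provenance <- vector("list", length(genes))
  names(provenance) <- genes
  for (g in genes) {
    loci <- map_r$locus_id[map_r$gene_id == g]
    if (aggregate == "max_abs_r" && length(loci) > 1) {
      if (is.null(survival)) stop("`survival` required for max_abs_r")
      rs <- vapply(loci, function(l) tryCatch(
        abs(survival_correlation(meth[l, ], survival)),
        error = function(e) NA_real_), numeric(1))
      loci <- loci[which.max(rs)]
    }
    block <- meth[loci, , drop = FALSE]
    values[g, ] <- colMeans(block, na.rm = TRUE)
    values[g, ][is.nan(values[g, ])] <- NA_real_
    provenance[[g]] <- loci
  }
  structure(list(values = values, provenance = provenance),
            class = "gene_methylation")
}

#' Union of genes relevant to survival on either platform
#'
#' @param expr_report Relevance report over expression genes.
#' @param meth_report Relevance report over gene-level methylation.
#' @return Character vector of gene ids (deterministic order: expression
#'   passes in report order, then new methylation passes).
#' @export
select_relevant_genes <- function(expr_report, meth_report) {
  a <- attr(expr_report, "retained_ids")
  b <- attr(meth_report, "retained_ids")
  out <- union(a, b)
  if (length(out) == 0)
    stop("no gene passes either platform's filter; consider lowering tau")
  out
}
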