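#' Construct an omics matrix
#'
#' Features-in-rows, samples-in-columns numeric matrix with unique identifiers
#' on both axes. Methylation matrices hold beta values (fractions in \[0,1\]);
#' missing values are permitted on either platform.
#'
#' @param values Numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param kind `"expression"` or `"methylation"`. Methylation values are
#'   checked to lie in \[0,1\] (or be `NA`).
#' @return The matrix, classed `"omics_matrix"` with a `"kind"` attribute.
#' @export
omics_matrix <- function(values, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have rownames (features) and colnames (samples)")
  if (anyDuplicated(fid))
    stop("duplicate feature identifier(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample identifier(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (kind == "methylation") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta value outside [0,1] at feature '%s', sample '%s'",
                   fid[bad[1, 1]], sid[bad[1, 2]]))
  }
  structure(values, class = c("omics_matrix", class(values)), kind = kind)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a survival table
#'
#' Per-sample overall-survival time (days) and event indicator
#' (1 = death observed, 0 = right-censored), with optional `age` (years) and
#' `sex` covariates.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param time Non-negative survival/follow-up times.
#' @param event 0/1 event indicators.
#' @param age,sex Optional covariates, recycled `NA` if absent.
#' @return A `data.frame` of class `"survival_table"`.
#' @export
survival_table <- function(sample_id, time, event, age = NULL, sex = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample identifier(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  n <- length(sample_id)
  if (length(time) != n || length(event) != n)
    stop("`time` and `event` must match `sample_id` in length")
  if (any(!is.na(time) & time < 0)) stop("survival time must be >= 0")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  out <- data.frame(sample_id = sample_id, time = as.numeric(time),
                    event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(age)) out$age <- as.numeric(age)
  if (!is.null(sex)) out$sex <- as.character(sex)
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Construct a probe-to-gene map
#'
#' Many-to-many mapping between methylation loci and genes. Duplicate
#' (locus, gene) pairs are rejected.
#'
#' @param locus_id,gene_id Character vectors of equal length.
#' @return A `data.frame` with columns `locus_id`, `gene_id`.
#' @export
probe_gene_map <- function(locus_id, gene_id) {
  locus_id <- as.character(locus_id); gene_id <- as.character(gene_id)
  if (length(locus_id) != length(gene_id))
    stop("`locus_id` and `gene_id` must have equal length")
  if (length(locus_id) == 0) stop("probe map is empty")
  key <- paste(locus_id, gene_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (locus, gene) pair(s) in probe map")
  data.frame(locus_id = locus_id, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' All tunable parameters of the pipeline with their defaults. The object is
#' JSON-serializable (see [write_run_config()]); every CLI flag mirrors one
#' field, so the pipeline runs with inputs only.
#'
#' @param methylation_weight Weight `w` of the expression platform in the
#'   combined similarity `s = w|r_expr| + (1-w)|r_meth|`; `w = 1` is the
#'   expression-only ablation. Default 0.5.
#' @param soft_power Soft-thresholding exponent `beta >= 1` applied
#'   elementwise to the similarity. Default 6.
#' @param log_transform Apply `ln(x + offset)` to expression before analysis.
#' @param log_offset Offset for the log transform. Default 1.
#' @param tau Survival-correlation threshold: features with `|r| < tau` are
#'   filtered out. Default 0.2.
#' @param variance_floor Features with variance `<= variance_floor` are
#'   filtered out. Default 0.
#' @param missing_cap Maximum tolerated fraction of missing values per
#'   feature. Default 0.2.
#' @param censored_only_correlation If `TRUE`, survival correlations use
#'   deceased samples only; default `FALSE` (all samples' observed time).
#' @param aggregate One of `"mean"`, `"max_abs_r"`: per-gene aggregation of
#'   retained methylation loci.
#' @param min_pairs Minimum complete sample pairs for a pairwise correlation.
#' @param linkage Hierarchical-clustering linkage. Default `"average"`.
#' @param cut_method `"gap"` (adaptive height at the largest merge-height
#'   gap) or `"static"` (fixed `cut_height`).
#' @param cut_height Static cut height on `1 - adjacency`. Default 0.99.
#' @param min_module_size Smallest admissible module. Default 10.
#' @param cv_folds Folds for the penalized-Cox cross-validation. Default 10.
#' @param lambda_rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @param aft_family `"lognormal"` (default) or `"weibull"`.
#' @param cutpoint_scheme `"tertile"` (default) or `"quartile"` (25/50/25)
#'   split of training predicted times into high/intermediate/low.
#' @param seed Integer seed for all stochastic steps. Default 1.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(methylation_weight = 0.5,
                       soft_power = 6,
                       log_transform = FALSE,
                       log_offset = 1,
                       tau = 0.2,
                       variance_floor = 0,
                       missing_cap = 0.2,
                       censored_only_correlation = FALSE,
                       aggregate = c("mean", "max_abs_r"),
                       min_pairs = 10,
                       linkage = "average",
                       cut_method = c("gap", "static"),
                       cut_height = 0.99,
                       min_module_size = 10,
                       cv_folds = 10,
                       lambda_rule = c("lambda.1se", "lambda.min"),
                       aft_family = c("lognormal", "weibull"),
                       cutpoint_scheme = c("tertile", "quartile"),
                       seed = 1L) {
  cfg <- list(
    methylation_weight = methylation_weight,
    soft_power = soft_power,
    log_transform = isTRUE(log_transform),
    log_offset = log_offset,
    tau = tau,
    variance_floor = variance_floor,
    missing_cap = missing_cap,
    censored_only_correlation = isTRUE(censored_only_correlation),
    aggregate = match.arg(aggregate),
    min_pairs = min_pairs,
    linkage = linkage,
    cut_method = match.arg(cut_method),
    cut_height = cut_height,
    min_module_size = as.integer(min_module_size),
    cv_folds = as.integer(cv_folds),
    lambda_rule = match.arg(lambda_rule),
    aft_family = match.arg(aft_family),
    cutpoint_scheme = match.arg(cutpoint_scheme),
    seed = as.integer(seed)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$methylation_weight >= 0, cfg$methylation_weight <= 1,
    cfg$soft_power >= 1,
    cfg$log_offset > 0,
    cfg$tau >= 0, cfg$tau <= 1,
    cfg$variance_floor >= 0,
    cfg$missing_cap >= 0, cfg$missing_cap <= 1,
    cfg$min_pairs >= 3,
    cfg$cut_height > 0, cfg$cut_height <= 1,
    cfg$min_module_size >= 1,
    cfg$cv_folds >= 3
  )
  invisible(cfg)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `read_run_config` returns a `run_config`; unknown keys error.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}
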