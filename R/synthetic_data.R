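#' Simulation configuration for synthetic paired cohorts
#'
#' Describes a cohort with planted gene modules: one latent factor per module
#' drives both the expression of the module's genes (loading `rho_expr`) and
#' the methylation of those genes' loci (loading `rho_meth`, sign-flipped by
#' default to emulate the usual expression/methylation anticorrelation).
#' Survival times follow a log-linear accelerated failure time (AFT) model on
#' the factors of the prognostic modules, with right censoring by an
#' independent uniform horizon.
#'
#' @param n_samples_expression,n_samples_methylation Cohort sizes per
#'   platform. Defaults 200/200 (desk-scale analogue of the few-hundred-case
#'   cohorts, with unequal platform coverage, typical of public AML data).
#' @param sample_overlap Fraction of methylation samples that also have
#'   expression data. Default 0.8.
#' @param n_genes Total gene count (planted + background). Default 600.
#' @param module_sizes Integer vector of planted module sizes. Default ten
#'   modules of 30 genes (leaving 300 background genes).
#' @param rho_expr,rho_meth Latent-factor loadings in \[0,1\]. Default 0.85;
#'   two genes sharing a factor then correlate at about `rho^2`.
#' @param loci_per_gene Candidate loci counts per gene, sampled uniformly.
#'   Default `1:4` (most genes have at most four loci).
#' @param meth_sign `-1` (default) flips methylation loadings relative to
#'   expression; `+1` keeps them parallel.
#' @param prognostic_modules Indices of modules whose factors enter the AFT
#'   model. Default `c(1, 2)`.
#' @param beta AFT coefficients for the prognostic modules. Default
#'   `c(1, -0.5)`.
#' @param mu AFT intercept on the log-day scale. Default `log(365)`
#'   (median survival of about one year, typical of adult AML).
#' @param sigma AFT error scale. Default 0.3.
#' @param error_family `"lognormal"` (standard normal error on log time,
#'   default) or `"weibull"` (standard minimum extreme-value error).
#' @param censoring_rate Target censoring fraction in \[0,1). Default 0.2.
#' @param seed Integer seed. Default 1.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples_expression = 200,
                              n_samples_methylation = 200,
                              sample_overlap = 0.8,
                              n_genes = 600,
                              module_sizes = rep(30L, 10),
                              rho_expr = 0.85,
                              rho_meth = 0.85,
                              loci_per_gene = 1:4,
                              meth_sign = -1,
                              prognostic_modules = c(1L, 2L),
                              beta = c(1, -0.5),
                              mu = log(365),
                              sigma = 0.3,
                              error_family = c("lognormal", "weibull"),
                              censoring_rate = 0.2,
                              seed = 1L) {
  error_family <- match.arg(error_family)
  if (missing(module_sizes)) {
    # default: modules of ~30 genes covering half the genes, as at full scale
    k <- max(1L, as.integer(n_genes) %/% 60L)
    module_sizes <- rep(min(30L, max(2L, as.integer(n_genes) %/% (2L * k))), k)
  }
  if (missing(prognostic_modules)) {
    prognostic_modules <- intersect(c(1L, 2L), seq_along(module_sizes))
    if (missing(beta)) beta <- c(1, -0.5)[seq_along(prognostic_modules)]
  }
  cfg <- list(n_samples_expression = as.integer(n_samples_expression),
              n_samples_methylation = as.integer(n_samples_methylation),
              sample_overlap = sample_overlap, n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes), rho_expr = rho_expr,
              rho_meth = rho_meth, loci_per_gene = as.integer(loci_per_gene),
              meth_sign = meth_sign,
              prognostic_modules = as.integer(prognostic_modules),
              beta = as.numeric(beta), mu = mu, sigma = sigma,
              error_family = error_family, censoring_rate = censoring_rate,
              seed = as.integer(seed))
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("module sizes exceed total gene count")
  if (cfg$sample_overlap < 0 || cfg$sample_overlap > 1)
    stop("sample_overlap must lie in [0,1]")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stop("censoring_rate must lie in [0,1)")
  if (cfg$rho_expr < 0 || cfg$rho_expr > 1 ||
      cfg$rho_meth < 0 || cfg$rho_meth > 1)
    stop("factor loadings must lie in [0,1]")
  if (length(cfg$beta) != length(cfg$prognostic_modules))
    stop("`beta` must match `prognostic_modules` in length")
  if (length(cfg$module_sizes) > 0 &&
      any(cfg$prognostic_modules > length(cfg$module_sizes)))
    stop("prognostic module index out of range")
  if (!meth_sign %in% c(-1, 1)) stop("meth_sign must be -1 or +1")
  structure(cfg, class = "simulation_config")
}

#' Generate a synthetic paired expression/methylation cohort
#'
#' See [simulation_config()] for the generative model. The returned cohort
#' carries the full ground truth (module labels, latent factors, AFT
#' coefficients, uncensored times), sufficient to score module recovery
#' (adjusted Rand index) and AFT coefficient recovery downstream.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_cohort"` with elements `expression`,
#'   `methylation` (locus level), `probe_map`, `clinical`, `truth`, `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ne <- config$n_samples_expression
  nm <- config$n_samples_methylation
  n_shared <- round(config$sample_overlap * nm)
  if (n_shared > ne)
    stop("infeasible overlap: more shared samples than expression samples")
  expr_samples <- sprintf("S%04d", seq_len(ne))
  meth_only <- if (nm > n_shared) sprintf("M%04d", seq_len(nm - n_shared))
               else character(0)
  meth_samples <- c(expr_samples[seq_len(n_shared)], meth_only)
  all_samples <- union(expr_samples, meth_samples)
  n_all <- length(all_samples)

  K <- length(config$module_sizes)
  # one latent factor per planted module, shared across platforms
  factors <- matrix(stats::rnorm(K * n_all), nrow = K,
                    dimnames = list(paste0("module_", seq_len(K)),
                                    all_samples))

  genes <- sprintf("G%04d", seq_len(config$n_genes))
  labels <- integer(config$n_genes)
  idx <- 1L
  for (k in seq_len(K)) {
    labels[idx:(idx + config$module_sizes[k] - 1L)] <- k
    idx <- idx + config$module_sizes[k]
  }
  names(labels) <- genes

  rho_e <- config$rho_expr
  expr <- matrix(stats::rnorm(config$n_genes * ne), nrow = config$n_genes,
                 dimnames = list(genes, expr_samples))
  for (k in seq_len(K)) {
    g <- which(labels == k)
    fk <- factors[k, expr_samples]
    expr[g, ] <- rho_e * matrix(fk, nrow = length(g), ncol = ne, byrow = TRUE) +
      sqrt(1 - rho_e^2) * expr[g, ]
  }

  # methylation at locus level: logistic transform keeps betas inside (0,1)
  n_loci_per_gene <- sample(config$loci_per_gene, config$n_genes,
                            replace = TRUE)
  total_loci <- sum(n_loci_per_gene)
  locus_ids <- sprintf("cg%06d", seq_len(total_loci))
  locus_gene <- rep(genes, times = n_loci_per_gene)
  rho_m <- config$rho_meth
  latent <- matrix(stats::rnorm(total_loci * nm), nrow = total_loci,
                   dimnames = list(locus_ids, meth_samples))
  for (k in seq_len(K)) {
    rows <- which(labels[locus_gene] == k)
    fk <- factors[k, meth_samples]
    latent[rows, ] <- config$meth_sign * rho_m *
      matrix(fk, nrow = length(rows), ncol = nm, byrow = TRUE) +
      sqrt(1 - rho_m^2) * latent[rows, ]
  }
  beta_vals <- pmin(pmax(stats::plogis(latent), 0), 1)

  # AFT survival on expression samples: log T = mu + sum_k beta_k f_k + sigma*eps
  lp <- rep(config$mu, ne)
  for (j in seq_along(config$prognostic_modules)) {
    k <- config$prognostic_modules[j]
    lp <- lp + config$beta[j] * factors[k, expr_samples]
  }
  eps <- switch(config$error_family,
                lognormal = stats::rnorm(ne),
                weibull = log(stats::rexp(ne)))
  t_true <- exp(lp + config$sigma * eps)

  if (config$censoring_rate > 0) {
    # uniform horizon U(0, u): P(censor) = E[min(T,u)]/u; solve for u
    target <- config$censoring_rate
    f <- function(u) mean(pmin(t_true, u)) / u - target
    u <- stats::uniroot(f, lower = min(t_true) * 1e-6,
                        upper = max(t_true) * 1e4, tol = 1e-8)$root
    cens <- stats::runif(ne, 0, u)
    time <- pmin(t_true, cens)
    event <- as.integer(t_true <= cens)
  } else {
    time <- t_true
    event <- rep(1L, ne)
  }

  age <- round(stats::runif(ne, 20, 85))
  sex <- sample(c("male", "female"), ne, replace = TRUE)
  clinical <- survival_table(expr_samples, time, event, age = age, sex = sex)

  beta_full <- numeric(K)
  beta_full[config$prognostic_modules] <- config$beta
  truth <- list(labels = labels, factors = factors, beta = beta_full,
                mu = config$mu, sigma = config$sigma,
                error_family = config$error_family,
                uncensored_time = stats::setNames(t_true, expr_samples))

  structure(list(expression = omics_matrix(expr, "expression"),
                 methylation = omics_matrix(beta_vals, "methylation"),
                 probe_map = probe_gene_map(locus_ids, locus_gene),
                 clinical = clinical, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Realized event fraction of a cohort's clinical table
#'
#' @param cohort A `synthetic_cohort` (or any list with a `clinical`
#'   survival table).
#' @return Fraction of samples with `event == 1`.
#' @export
censoring_summary <- function(cohort) {
  clin <- cohort$clinical
  if (is.null(clin) || nrow(clin) == 0) stop("empty clinical table")
  mean(clin$event == 1)
}

#' Write a synthetic cohort as the four standard input files plus truth.json
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_omics_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_omics_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_probe_map(cohort$probe_map, file.path(dir, "probe_map.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$factors <- NULL  # large; labels/beta suffice for scoring
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
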