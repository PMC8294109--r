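align_eigengene_survival <- function(eigengenes, survival) {
  shared <- intersect(colnames(eigengenes$values), survival$sample_id)
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  list(x = t(eigengenes$values[, shared, drop = FALSE]),
       surv = survival[match(shared, survival$sample_id), , drop = FALSE])
}

#' Select survival-associated modules by L1-penalized Cox regression
#'
#' Fits a lasso-penalized Cox partial likelihood over a penalty grid with the
#' eigengenes as covariates and picks the penalty by seeded cross-validated
#' partial likelihood. Modules with nonzero coefficients at the chosen
#' penalty are returned.
#'
#' @param eigengenes An `eigengene_matrix`.
#' @param survival A [survival_table()].
#' @param folds Cross-validation folds. Default 10.
#' @param seed Seed for the fold assignment. Default 1.
#' @param lambda_rule `"lambda.1se"` (default, conservative) or
#'   `"lambda.min"`.
#' @return List with `selected` (module ids), `lambda`, `rule`, and `path`
#'   (per-lambda nonzero counts and CV partial likelihood).
#' @export
select_prognostic_modules <- function(eigengenes, survival, folds = 10,
                                      seed = 1,
                                      lambda_rule = c("lambda.1se",
                                                      "lambda.min")) {
  lambda_rule <- match.arg(lambda_rule)
  al <- align_eigengene_survival(eigengenes, survival)
  x <- al$x
  if (ncol(x) < 2) stop("need at least 2 modules for penalized selection")
  if (sum(al$surv$event) == 0) stop("no events in survival table")
  if (sum(al$surv$event) < folds)
    stop("fewer events than cross-validation folds")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) eigengene: ",
         colnames(x)[which(sds == 0)[1]])
  y <- survival::Surv(al$surv$time, al$surv$event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1, foldid = foldid)
  lam <- cv[[lambda_rule]]
  cf <- as.matrix(stats::coef(cv, s = lam))
  selected <- rownames(cf)[cf[, 1] != 0]
  list(selected = selected, lambda = lam, rule = lambda_rule,
       path = data.frame(lambda = cv$lambda, nzero = cv$nzero,
                         cvm = cv$cvm), folds = folds, seed = seed)
}

#' Fit an accelerated failure time model on selected eigengenes
#'
#' Maximum-likelihood AFT fit with right censoring,
#' `log T = mu + sum_k beta_k E_k + sigma * eps`, with log-normal (default)
#' or Weibull error. Risk cutpoints are set from the training cohort's
#' predicted times: tertiles by default, or a 25/50/25 quartile scheme.
#'
#' @param eigengenes An `eigengene_matrix` containing the selected modules.
#' @param survival A [survival_table()].
#' @param selected Module ids to include (default: all rows of
#'   `eigengenes`).
#' @param family `"lognormal"` (default) or `"weibull"`.
#' @param cutpoint_scheme `"tertile"` (default) or `"quartile"`.
#' @return A list of class `"risk_model"`: `selected_modules`, `weights`,
#'   `family`, `coefficients` (`mu`, `beta`, `scale`), `cutpoints`
#'   (`t_low < t_high`), `cutpoint_scheme`, `fit` diagnostics.
#' @export
fit_aft_model <- function(eigengenes, survival,
                          selected = rownames(eigengenes$values),
                          family = c("lognormal", "weibull"),
                          cutpoint_scheme = c("tertile", "quartile")) {
  family <- match.arg(family)
  cutpoint_scheme <- match.arg(cutpoint_scheme)
  if (length(selected) < 1) stop("need at least one selected module")
  missing_mod <- setdiff(selected, rownames(eigengenes$values))
  if (length(missing_mod) > 0)
    stop("selected module absent from eigengenes: ",
         paste(missing_mod, collapse = ", "))
  al <- align_eigengene_survival(eigengenes, survival)
  if (sum(al$surv$event) == 0) stop("no events in survival table")
  df <- as.data.frame(al$x[, selected, drop = FALSE])
  df$.time <- al$surv$time
  df$.event <- al$surv$event
  fml <- stats::reformulate(selected,
                            response = quote(survival::Surv(.time, .event)))
  fit <- survival::survreg(fml, data = df, dist = family)
  if (is.na(fit$scale) || any(is.na(stats::coef(fit))))
    stop(sprintf("AFT fit did not converge (%d iterations)", fit$iter))
  cf <- stats::coef(fit)
  model <- structure(list(
    selected_modules = selected,
    weights = eigengenes$weights[selected],
    family = family,
    coefficients = list(mu = unname(cf[1]),
                        beta = cf[-1],
                        scale = fit$scale),
    cutpoints = NULL,
    cutpoint_scheme = cutpoint_scheme,
    fit = list(loglik = fit$loglik[2], iter = fit$iter,
               n = nrow(df), events = sum(df$.event))),
    class = "risk_model")
  pred <- predict_survival_time(model, eigengenes)
  probs <- if (cutpoint_scheme == "tertile") c(1, 2) / 3 else c(0.25, 0.75)
  cp <- unname(stats::quantile(pred, probs))
  model$cutpoints <- list(t_low = cp[1], t_high = cp[2])
  model
}

#' Predicted expected survival time under a fitted AFT model
#'
#' For the log-normal family the expected time is
#' `exp(mu + sum beta E + scale^2 / 2)`; for Weibull it is
#' `exp(mu + sum beta E) * gamma(1 + scale)`. Strictly positive and monotone
#' in the linear predictor.
#'
#' @param model A `risk_model`.
#' @param eigengenes An `eigengene_matrix` containing the model's modules.
#' @return Named vector of predicted times (days).
#' @export
predict_survival_time <- function(model, eigengenes) {
  mods <- model$selected_modules
  missing_mod <- setdiff(mods, rownames(eigengenes$values))
  if (length(missing_mod) > 0)
    stop("eigengene matrix lacks module(s): ",
         paste(missing_mod, collapse = ", "))
  e <- eigengenes$values[mods, , drop = FALSE]
  lp <- model$coefficients$mu +
    as.vector(t(e) %*% model$coefficients$beta[mods])
  s <- model$coefficients$scale
  pred <- switch(model$family,
                 lognormal = exp(lp + s^2 / 2),
                 weibull = exp(lp) * gamma(1 + s))
  stats::setNames(pred, colnames(e))
}

#' Three-way risk classification from predicted survival times
#'
#' `high` if predicted time is strictly below `t_low`, `low` if strictly
#' above `t_high`, `intermediate` otherwise (boundary values fall in the
#' less extreme class).
#'
#' @param predicted_time Named vector of predicted times.
#' @param cutpoints List or vector with `t_low < t_high`.
#' @return A `risk_table` data frame (`sample_id`, `predicted_time`,
#'   `risk_class` factor with levels low/intermediate/high).
#' @export
classify_risk <- function(predicted_time, cutpoints) {
  t_low <- cutpoints$t_low %||% cutpoints[[1]]
  t_high <- cutpoints$t_high %||% cutpoints[[2]]
  if (!(t_low <= t_high)) stop("require t_low <= t_high")
  cls <- ifelse(predicted_time < t_low, "high",
                ifelse(predicted_time > t_high, "low", "intermediate"))
  out <- data.frame(sample_id = names(predicted_time),
                    predicted_time = as.numeric(predicted_time),
                    risk_class = factor(cls, levels = c("low", "intermediate",
                                                        "high")),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("risk_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quartile discretization of a continuous risk score
#'
#' For scores where higher means worse prognosis: the first quartile is
#' low-risk, the middle two quartiles intermediate, and the fourth quartile
#' high-risk. Boundary values (ties with the cutoffs) fall to intermediate.
#'
#' @param scores Numeric vector (optionally named), length >= 4.
#' @return Factor of risk classes (low/intermediate/high).
#' @export
discretize_quartile_risk <- function(scores) {
  if (length(scores) < 4) stop("need at least 4 samples")
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
  cls <- ifelse(scores < q[1], "low",
                ifelse(scores > q[2], "high", "intermediate"))
  out <- factor(cls, levels = c("low", "intermediate", "high"))
  names(out) <- names(scores)
  out
}

#' Restrict a risk classification to a sample subset
#'
#' The classification itself is unchanged (the trained model is applied, not
#' refit); the restriction is packaged with a high-vs-rest grouping for
#' log-rank evaluation of the subset.
#'
#' @param risk_table A `risk_table`.
#' @param subset Character vector of sample ids (must be a subset).
#' @return List with `risk_table` (the restriction) and `high_vs_rest`
#'   (named factor `"high"` / `"rest"`).
#' @export
restratify <- function(risk_table, subset) {
  if (length(subset) == 0) stop("empty subset")
  missing_s <- setdiff(subset, risk_table$sample_id)
  if (length(missing_s) > 0)
    stop("subset sample(s) absent from risk table: ",
         paste(utils::head(missing_s, 3), collapse = ", "))
  sub <- risk_table[match(subset, risk_table$sample_id), , drop = FALSE]
  rownames(sub) <- NULL
  grp <- factor(ifelse(sub$risk_class == "high", "high", "rest"),
                levels = c("high", "rest"))
  names(grp) <- sub$sample_id
  list(risk_table = sub, high_vs_rest = grp)
}

#' Serialize / restore a risk model as JSON
#'
#' The JSON document carries the selected modules, their gene weight
#' vectors, the AFT coefficients and the risk cutpoints, so `classify` can
#' run on a new expression matrix alone.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @export
write_risk_model <- function(model, path) {
  doc <- list(selected_modules = model$selected_modules,
              weights = lapply(model$weights, as.list),
              family = model$family,
              coefficients = list(mu = model$coefficients$mu,
                                  beta = as.list(model$coefficients$beta),
                                  scale = model$coefficients$scale),
              cutpoints = model$cutpoints,
              cutpoint_scheme = model$cutpoint_scheme)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  weights <- lapply(doc$weights, function(w)
    stats::setNames(as.numeric(unlist(w)), names(w)))
  beta <- stats::setNames(as.numeric(unlist(doc$coefficients$beta)),
                          names(doc$coefficients$beta))
  structure(list(selected_modules = unlist(doc$selected_modules),
                 weights = weights, family = doc$family,
                 coefficients = list(mu = doc$coefficients$mu, beta = beta,
                                     scale = doc$coefficients$scale),
                 cutpoints = doc$cutpoints,
                 cutpoint_scheme = doc$cutpoint_scheme),
            class = "risk_model")
}

#' Write a risk table as TSV
#'
#' @param risk_table A `risk_table`.
#' @param path Output path.
#' @export
write_risk_table <- function(risk_table, path) {
  utils::write.table(risk_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
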