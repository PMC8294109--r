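#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator: the curve steps only at observed
#' event times; censored times reduce the at-risk count without stepping the
#' curve.
#'
#' @param survival A [survival_table()] (or any data frame with `time`,
#'   `event`).
#' @return A data frame of class `"survival_curve"` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (probability just after that time).
#' @export
km_estimate <- function(survival) {
  if (is.null(survival) || nrow(survival) == 0) stop("empty survival table")
  time <- survival$time
  event <- survival$event
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Write survival curves per group as TSV
#'
#' @param survival A [survival_table()].
#' @param group Factor/character of group labels aligned with `survival`.
#' @param path Output path.
#' @export
write_km_curves <- function(survival, group, path) {
  rows <- do.call(rbind, lapply(split(seq_len(nrow(survival)), group),
    function(i) {
      cv <- km_estimate(survival[i, , drop = FALSE])
      cbind(group = as.character(group[i[1]]), cv)
    }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Log-rank O-E and covariance accumulated over pooled risk sets.
logrank_components <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  K <- nlevels(group)
  sorted <- lapply(split(time, group), sort)
  n_tot <- lengths(sorted)
  dt <- sort(unique(time[event == 1]))
  # at-risk per group at each event time (count of time_j >= t)
  n_j <- vapply(seq_len(K), function(j)
    n_tot[j] - findInterval(dt, sorted[[j]], left.open = TRUE), numeric(length(dt)))
  if (length(dt) == 1) n_j <- matrix(n_j, nrow = 1)
  d_j <- vapply(levels(group), function(g)
    vapply(dt, function(t) sum(time == t & event == 1 & group == g),
           numeric(1)), numeric(length(dt)))
  if (length(dt) == 1) d_j <- matrix(d_j, nrow = 1)
  n <- rowSums(n_j)
  d <- rowSums(d_j)
  O <- colSums(d_j)
  E <- colSums(d * n_j / n)
  V <- matrix(0, K, K)
  ok <- n > 1
  for (a in seq_len(K)) for (b in seq_len(K)) {
    delta <- as.numeric(a == b)
    V[a, b] <- sum((d[ok] * (n[ok] - d[ok]) / (n[ok] - 1)) *
                   (n_j[ok, a] / n[ok]) * (delta - n_j[ok, b] / n[ok]))
  }
  list(O = O, E = E, V = V, K = K, sizes = as.integer(table(group)))
}

logrank_statistic <- function(time, event, group) {
  cmp <- logrank_components(time, event, group)
  U <- (cmp$O - cmp$E)[-cmp$K]
  Vs <- cmp$V[-cmp$K, -cmp$K, drop = FALSE]
  if (length(U) == 1) {
    if (Vs[1, 1] <= 0) return(0)
    return(as.numeric(U^2 / Vs))
  }
  inv <- tryCatch(solve(Vs), error = function(e) {
    sv <- svd(Vs)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
      t(sv$u[, pos, drop = FALSE])
  })
  as.numeric(t(U) %*% inv %*% U)
}

#' Log-rank test for differences in survival between groups
#'
#' Standard chi-square log-rank test over pooled risk sets with the
#' hypergeometric variance (ties handled by simultaneous risk-set
#' accounting); `groups - 1` degrees of freedom; invariant under group
#' relabeling.
#'
#' @param survival A [survival_table()].
#' @param group Group labels: either a vector aligned with the table rows or
#'   a named vector matched on `sample_id`.
#' @return A list of class `"test_result"`: `name`, `statistic`, `df`, `p`,
#'   `group_sizes`.
#' @export
logrank_test <- function(survival, group) {
  if (!is.null(names(group)))
    group <- group[match(survival$sample_id, names(group))]
  if (length(group) != nrow(survival))
    stop("`group` must align with the survival table")
  keep <- !is.na(group)
  group <- droplevels(as.factor(group[keep]))
  time <- survival$time[keep]
  event <- survival$event[keep]
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  if (sum(event) == 0) stop("no events")
  stat <- logrank_statistic(time, event, group)
  df <- nlevels(group) - 1
  structure(list(name = "log-rank", statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 group_sizes = as.integer(table(group))),
            class = "test_result")
}

#' Log-rank test within age strata
#'
#' Splits the cohort at an age cutoff (default 60 years) and reruns the
#' log-rank test per stratum.
#'
#' @param survival A [survival_table()] with an `age` column.
#' @param group Group labels (as in [logrank_test()]).
#' @param cutoff Age cutoff. Default 60.
#' @return Named list of `test_result`s (`younger` = age < cutoff,
#'   `older` = age >= cutoff).
#' @export
age_stratified_logrank <- function(survival, group, cutoff = 60) {
  if (is.null(survival$age)) stop("survival table has no `age` column")
  if (!is.null(names(group)))
    group <- group[match(survival$sample_id, names(group))]
  strata <- ifelse(survival$age < cutoff, "younger", "older")
  out <- list()
  for (s in c("younger", "older")) {
    i <- which(strata == s)
    out[[s]] <- logrank_test(survival[i, , drop = FALSE], group[i])
  }
  out
}

#' Upper-tail chi-square / p-value correspondence
#'
#' Converts a p-value to the chi-square statistic with that upper-tail
#' probability, or a statistic to its p-value, at the given degrees of
#' freedom.
#'
#' @param p Upper-tail probability in (0,1); give exactly one of `p`,
#'   `statistic`.
#' @param statistic Chi-square statistic >= 0.
#' @param df Degrees of freedom >= 1. Default 1.
#' @return The other quantity.
#' @export
chisq_p_conversion <- function(p = NULL, statistic = NULL, df = 1) {
  if (df < 1) stop("`df` must be >= 1")
  if (is.null(p) == is.null(statistic))
    stop("give exactly one of `p` or `statistic`")
  if (!is.null(p)) {
    if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0,1)")
    stats::qchisq(p, df, lower.tail = FALSE)
  } else {
    if (any(statistic < 0)) stop("`statistic` must be >= 0")
    stats::pchisq(statistic, df, lower.tail = FALSE)
  }
}

#' Hypergeometric tail probability
#'
#' `P(X >= k)` (enrichment, default) or `P(X <= k)` for
#' `X ~ Hypergeometric(N, K, n)`: `k` observed successes among `n` draws
#' from a population of `N` containing `K` successes.
#'
#' @param k Observed overlap/successes.
#' @param K Successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @param lower If `TRUE` return the lower tail `P(X <= k)`.
#' @return Tail probability.
#' @export
hypergeometric_tail <- function(k, K, n, N, lower = FALSE) {
  if (K > N || n > N || k < 0 || k > min(K, n))
    stop("inconsistent counts: require 0 <= k <= min(K, n) <= N")
  if (lower) stats::phyper(k, K, N - K, n)
  else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param p Vector of p-values in \[0,1\].
#' @param method `"bonferroni"` (default) or `"benjamini-hochberg"`.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni",
                                         "benjamini-hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni"
                              else "BH")
}

#' Cross-tabulate two risk classifications
#'
#' @param classes_a,classes_b Named vectors/factors over the same sample
#'   set.
#' @return List with `table` (cross-tabulation with margins) and `chisq`
#'   (independence `test_result`, no continuity correction).
#' @export
crosstab_risk <- function(classes_a, classes_b) {
  if (!is.null(names(classes_a)) && !is.null(names(classes_b))) {
    if (!setequal(names(classes_a), names(classes_b)))
      stop("classifications cover different sample sets")
    classes_b <- classes_b[names(classes_a)]
  } else if (length(classes_a) != length(classes_b)) {
    stop("classifications cover different sample sets")
  }
  tab <- table(a = classes_a, b = classes_b)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = stats::addmargins(tab),
                 chisq = structure(list(name = "chi-square independence",
                                        statistic = unname(ct$statistic),
                                        df = unname(ct$parameter),
                                        p = ct$p.value,
                                        group_sizes = rowSums(tab)),
                                   class = "test_result")),
            class = "risk_crosstab")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label permutation), about 0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %d, p = %.4g\n",
              x$name, x$statistic, x$df, x$p))
  invisible(x)
}
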