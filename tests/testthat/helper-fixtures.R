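# Shared fixtures and independent oracles, all built in code.

make_surv <- function(time, event = rep(1L, length(time)),
                      ids = sprintf("P%02d", seq_along(time)), ...) {
  survival_table(ids, time, event, ...)
}

rand_mat <- function(nr, nc, seed = 1, prefix = "G") {
  set.seed(seed)
  matrix(stats::rnorm(nr * nc), nr, nc,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(nr)),
                         sprintf("S%03d", seq_len(nc))))
}

# independent Pearson oracle: textbook formula, no stats::cor
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# direct eigengene/survival generator for the prognosis stage: latent module
# scores are iid standard normal, survival follows the log-linear AFT model
sim_eigengene_surv <- function(n, K, beta = numeric(K), mu = log(365),
                               sigma = 0.3, censoring = 0.2, seed = 1) {
  set.seed(seed)
  values <- matrix(stats::rnorm(K * n), nrow = K,
                   dimnames = list(paste0("M", seq_len(K)),
                                   sprintf("S%04d", seq_len(n))))
  t_true <- exp(mu + as.vector(t(values) %*% beta) + sigma * stats::rnorm(n))
  if (censoring > 0) {
    f <- function(u) mean(pmin(t_true, u)) / u - censoring
    u <- stats::uniroot(f, lower = min(t_true) * 1e-6,
                        upper = max(t_true) * 1e4)$root
    cens <- stats::runif(n, 0, u)
    time <- pmin(t_true, cens)
    event <- as.integer(t_true <= cens)
  } else {
    time <- t_true
    event <- rep(1L, n)
  }
  eg <- structure(list(values = values,
                       weights = stats::setNames(
                         lapply(seq_len(K), function(k)
                           stats::setNames(1, paste0("G", k))),
                         paste0("M", seq_len(K))),
                       variance_explained = NULL),
                  class = "eigengene_matrix")
  list(eigengenes = eg,
       surv = survival_table(colnames(values), time, event),
       t_true = t_true, factors = values)
}

# permutation oracle for the two-group log-rank p-value: the statistic is
# recomputed from scratch here (counting loop, no shared code path)
logrank_stat_oracle <- function(time, event, g) {
  dt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in dt) {
    n1 <- sum(time >= t & g == levels(factor(g))[1])
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == levels(factor(g))[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  if (V <= 0) 0 else (O - E)^2 / V
}
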