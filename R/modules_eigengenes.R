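#' Detect gene modules by hierarchical clustering of the network
#'
#' Clusters the dissimilarity `d = 1 - adjacency` with the configured linkage
#' and cuts the tree either at a fixed height (`"static"`) or at an adaptive
#' height (`"gap"`): among the largest gaps in the merge-height distribution,
#' the cut producing the most clusters of at least `min_module_size` genes is
#' chosen (ties broken by larger gap, then lower height). Clusters below
#' `min_module_size` are relabeled 0 (background); surviving modules are
#' renumbered by decreasing size. Genes are pre-sorted lexicographically so
#' the result is deterministic.
#'
#' @param network An `integrated_network` (or a symmetric adjacency matrix).
#' @param linkage `stats::hclust` method. Default `"average"`.
#' @param cut_method `"gap"` (default) or `"static"`.
#' @param cut_height Height for the static cut. Default 0.99.
#' @param min_module_size Smallest admissible module. Default 10.
#' @return A list of class `"module_assignment"`: `gene_ids`, `labels`
#'   (named integer vector, 0 = background), `n_modules`, `params`.
#' @export
detect_modules <- function(network, linkage = "average",
                           cut_method = c("gap", "static"),
                           cut_height = 0.99, min_module_size = 10) {
  cut_method <- match.arg(cut_method)
  adj <- if (inherits(network, "integrated_network")) network$adjacency
         else network
  genes <- sort(rownames(adj))
  if (length(genes) < min_module_size)
    stop("fewer than min_module_size genes in total")
  adj <- adj[genes, genes]
  d <- 1 - adj
  d[is.na(d)] <- 1  # uncovered pairs carry no similarity evidence
  tree <- stats::hclust(stats::as.dist(d), method = linkage)

  if (cut_method == "static") {
    h_cut <- cut_height
  } else {
    h <- sort(tree$height)
    gaps <- diff(h)
    if (length(gaps) == 0 || max(gaps) <= 0) {
      h_cut <- max(tree$height) + 1  # degenerate tree: one cluster
    } else {
      ord <- order(gaps, decreasing = TRUE)
      cand <- ord[seq_len(min(30, length(ord)))]
      best <- NULL
      for (i in cand) {
        hc <- (h[i] + h[i + 1]) / 2
        cl <- stats::cutree(tree, h = hc)
        score <- sum(table(cl) >= min_module_size)
        key <- c(score, gaps[i], -hc)
        if (is.null(best) || isTRUE(all(key > best$key) ||
            (key[1] > best$key[1]) ||
            (key[1] == best$key[1] && key[2] > best$key[2]) ||
            (key[1] == best$key[1] && key[2] == best$key[2] &&
             key[3] > best$key[3]))) {
          best <- list(key = key, h = hc)
        }
      }
      h_cut <- best$h
    }
  }

  cl <- stats::cutree(tree, h = h_cut)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(genes))
  names(labels) <- genes
  if (length(keep) > 0) {
    # renumber by decreasing size; ties by first (lexicographic) member
    first_member <- vapply(keep, function(k) min(which(cl == k)), integer(1))
    ord <- order(-as.integer(sizes[as.character(keep)]), first_member)
    for (j in seq_along(ord)) labels[cl == keep[ord[j]]] <- j
  }
  structure(list(gene_ids = genes, labels = labels,
                 n_modules = length(keep),
                 params = list(linkage = linkage, cut_method = cut_method,
                               cut_height = h_cut,
                               min_module_size = min_module_size)),
            class = "module_assignment")
}

standardize_rows <- function(x) {
  # mean-impute missing values per gene, then center/scale across samples
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    if (anyNA(xi)) xi[is.na(xi)] <- mean(xi, na.rm = TRUE)
    x[i, ] <- xi
  }
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0))
    stop("constant gene in module (zero variance): ",
         rownames(x)[which(sdv == 0)[1]])
  (x - mu) / sdv
}

#' Compute module eigengenes from expression
#'
#' Each module's genes are standardized (mean 0, sd 1 across samples,
#' missing values mean-imputed first); the eigengene is the first principal
#' component score vector, i.e. the projection of the standardized submatrix
#' on its leading left singular vector (the unit-norm gene weight vector).
#' The sign is oriented so the eigengene correlates positively with the
#' module's mean standardized profile.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param assignment A `module_assignment`.
#' @return A list of class `"eigengene_matrix"`: `values` (module-by-sample
#'   matrix, rownames `"M1"`, `"M2"`, ...), `weights` (named list of
#'   unit-norm gene weight vectors), `variance_explained`.
#' @export
compute_eigengenes <- function(expr, assignment) {
  labels <- assignment$labels
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("assignment contains no modules")
  values <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
                   dimnames = list(paste0("M", mods), colnames(expr)))
  weights <- vector("list", length(mods))
  names(weights) <- paste0("M", mods)
  varexp <- stats::setNames(numeric(length(mods)), paste0("M", mods))
  for (j in seq_along(mods)) {
    k <- mods[j]
    genes <- intersect(names(labels)[labels == k], rownames(expr))
    if (length(genes) == 0)
      stop("module ", k, " has no gene with expression data")
    z <- standardize_rows(expr[genes, , drop = FALSE])
    sv <- svd(z)
    w <- sv$u[, 1]
    eg <- as.vector(t(z) %*% w)
    profile <- colMeans(z)
    orient <- sum(eg * profile)
    if (orient == 0) orient <- w[1]  # tie-break: first weight positive
    if (orient < 0) { w <- -w; eg <- -eg }
    values[j, ] <- eg
    weights[[j]] <- stats::setNames(w, genes)
    varexp[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(values = values, weights = weights,
                 variance_explained = varexp),
            class = "eigengene_matrix")
}

#' Project a new cohort's expression onto stored module weight vectors
#'
#' Used to score validation cohorts that lack methylation (or even some
#' genes): the new cohort's genes are standardized and projected on the
#' training weight vector restricted to the shared genes (renormalized to
#' unit norm). At least `min_gene_frac` of a module's training genes must be
#' present.
#'
#' @param expr New cohort gene-by-sample expression matrix.
#' @param weights Named list of training weight vectors (from
#'   [compute_eigengenes()] or a `risk_model`).
#' @param min_gene_frac Minimum shared-gene fraction per module. Default 0.5.
#' @return An `eigengene_matrix` (variance_explained is the fraction of the
#'   submatrix variance captured by the projection).
#' @export
project_eigengenes <- function(expr, weights, min_gene_frac = 0.5) {
  mods <- names(weights)
  values <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
                   dimnames = list(mods, colnames(expr)))
  varexp <- stats::setNames(numeric(length(mods)), mods)
  out_w <- vector("list", length(mods))
  names(out_w) <- mods
  for (m in mods) {
    w <- weights[[m]]
    shared <- intersect(names(w), rownames(expr))
    if (length(shared) < min_gene_frac * length(w))
      stop(sprintf("module %s: only %d of %d weight genes present (< %.0f%%)",
                   m, length(shared), length(w), 100 * min_gene_frac))
    z <- standardize_rows(expr[shared, , drop = FALSE])
    ws <- w[shared]
    ws <- ws / sqrt(sum(ws^2))
    eg <- as.vector(t(z) %*% ws)
    values[m, ] <- eg
    out_w[[m]] <- ws
    varexp[m] <- sum(eg^2) / sum(z^2)
  }
  structure(list(values = values, weights = out_w,
                 variance_explained = varexp),
            class = "eigengene_matrix")
}

#' Correlation of each eigengene with overall survival
#'
#' @param eigengenes An `eigengene_matrix`.
#' @param survival A [survival_table()].
#' @param deceased_only Passed to [survival_correlation()].
#' @return Data frame (module_id, r) sorted by decreasing `|r|`.
#' @export
module_survival_correlation <- function(eigengenes, survival,
                                        deceased_only = FALSE) {
  v <- eigengenes$values
  r <- vapply(rownames(v), function(m)
    survival_correlation(v[m, ], survival, deceased_only = deceased_only),
    numeric(1))
  out <- data.frame(module_id = rownames(v), r = r,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Write module assignment / eigengenes / weights as TSV
#'
#' @param assignment A `module_assignment`.
#' @param path Output path.
#' @export
write_modules <- function(assignment, path) {
  df <- data.frame(gene_id = names(assignment$labels),
                   module_id = as.integer(assignment$labels),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @param eigengenes An `eigengene_matrix`.
#' @export
write_eigengenes <- function(eigengenes, path) {
  df <- data.frame(module_id = rownames(eigengenes$values),
                   as.data.frame(eigengenes$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules
#' @export
write_weights <- function(eigengenes, path) {
  rows <- do.call(rbind, lapply(names(eigengenes$weights), function(m) {
    w <- eigengenes$weights[[m]]
    data.frame(module_id = m, gene_id = names(w), weight = as.numeric(w),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
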