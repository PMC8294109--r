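#' Pairwise-complete Pearson correlations between genes
#'
#' @param x Gene-by-sample numeric matrix (or a `gene_methylation` object).
#' @param min_pairs Minimum complete sample pairs per gene pair; entries with
#'   fewer are set to `NA`. Default 10.
#' @param platform Tag recorded on the result.
#' @return A list of class `"correlation_matrix"`: `values` (symmetric,
#'   unit diagonal), `n_pairs` (per-pair complete-sample counts),
#'   `platform`.
#' @export
pairwise_correlation <- function(x, min_pairs = 10,
                                 platform = c("expression", "methylation")) {
  platform <- match.arg(platform)
  if (inherits(x, "gene_methylation")) x <- x$values
  sds <- apply(x, 1, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0))
    stop("constant gene (should have been filtered): ",
         rownames(x)[which(sds == 0)[1]])
  obs <- !is.na(x)
  n_pairs <- tcrossprod(obs * 1)
  vals <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  vals[n_pairs < min_pairs] <- NA_real_
  diag(vals) <- 1
  structure(list(values = vals, n_pairs = n_pairs, platform = platform),
            class = "correlation_matrix")
}

#' Combine expression and methylation correlations into one similarity
#'
#' For gene pairs covered by both platforms the similarity is the convex
#' combination `s = w * |r_expr| + (1 - w) * |r_meth|`; pairs covered by a
#' single platform fall back to that platform's `|r|`. `w = 1` reproduces the
#' expression-only network exactly.
#'
#' @param r_expr,r_meth `correlation_matrix` objects; `r_meth` may be `NULL`
#'   (expression-only) or cover a subset of genes.
#' @param w Expression weight in \[0,1\]. Default 0.5.
#' @return Symmetric similarity matrix in \[0,1\] with unit diagonal over the
#'   union of gene sets.
#' @export
combine_similarity <- function(r_expr, r_meth = NULL, w = 0.5) {
  if (w < 0 || w > 1) stop("`w` must lie in [0,1]")
  e <- abs(r_expr$values)
  if (is.null(r_meth) || w == 1) {
    diag(e) <- 1
    return(e)
  }
  m <- abs(r_meth$values)
  genes <- union(rownames(e), rownames(m))
  s <- matrix(NA_real_, length(genes), length(genes),
              dimnames = list(genes, genes))
  he <- genes %in% rownames(e)
  hm <- genes %in% rownames(m)
  if (any(!he & !hm)) stop("gene present in neither platform")
  s[genes[he], genes[he]] <- e[genes[he], genes[he]]
  both <- genes[he & hm]
  # single-platform pairs keep that platform's |r|; both -> convex combination
  if (length(both) > 0) {
    eb <- e[both, both]; mb <- m[both, both]
    comb <- w * eb + (1 - w) * mb
    comb[is.na(mb)] <- eb[is.na(mb)]
    comb[is.na(eb)] <- mb[is.na(eb)]
    s[both, both] <- comb
  }
  meth_only <- genes[!he & hm]
  if (length(meth_only) > 0) {
    s[meth_only, c(meth_only, both)] <- m[meth_only, c(meth_only, both)]
    s[c(meth_only, both), meth_only] <- m[c(meth_only, both), meth_only]
  }
  diag(s) <- 1
  s
}

#' Soft-threshold a similarity into a weighted network adjacency
#'
#' Elementwise power `a = s^beta` (monotone in `s`), the usual weighted
#' gene-coexpression construction.
#'
#' @param similarity Symmetric similarity matrix in \[0,1\].
#' @param beta Soft power >= 1. Default 6.
#' @param w Expression weight recorded on the network (metadata only).
#' @return A list of class `"integrated_network"`: `gene_ids`, `similarity`,
#'   `adjacency`, `w`, `beta`.
#' @export
adjacency_from_similarity <- function(similarity, beta = 6, w = NA_real_) {
  if (beta < 1) stop("`beta` must be >= 1")
  adjacency <- similarity^beta
  structure(list(gene_ids = rownames(similarity), similarity = similarity,
                 adjacency = adjacency, w = w, beta = beta),
            class = "integrated_network")
}

#' Build the integrated network from per-platform matrices
#'
#' Convenience wrapper: correlations per platform on that platform's full
#' sample set, combined similarity, soft-power adjacency.
#'
#' @param expr Gene-by-sample expression matrix.
#' @param meth_gene Optional gene-level methylation (`gene_methylation` or
#'   matrix).
#' @param w Expression weight. Default 0.5.
#' @param beta Soft power. Default 6.
#' @param min_pairs Passed to [pairwise_correlation()].
#' @return An `integrated_network`.
#' @export
build_network <- function(expr, meth_gene = NULL, w = 0.5, beta = 6,
                          min_pairs = 10) {
  r_e <- pairwise_correlation(expr, min_pairs = min_pairs,
                              platform = "expression")
  r_m <- if (!is.null(meth_gene) && w < 1)
    pairwise_correlation(meth_gene, min_pairs = min_pairs,
                         platform = "methylation")
  s <- combine_similarity(r_e, r_m, w = w)
  adjacency_from_similarity(s, beta = beta, w = w)
}

#' Serialize a network as a gene-pair edge list
#'
#' @param network An `integrated_network`.
#' @param path Output TSV path (columns gene_a, gene_b, similarity,
#'   adjacency; upper triangle only).
#' @export
write_network_edges <- function(network, path) {
  s <- network$similarity
  ut <- upper.tri(s)
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(gene_a = rownames(s)[idx[, 1]],
                   gene_b = colnames(s)[idx[, 2]],
                   similarity = s[ut],
                   adjacency = network$adjacency[ut],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
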