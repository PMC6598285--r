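# Condition profiles: protein x condition log2-ratio matrix, row
# z-scores, hierarchical clustering, and hypergeometric pathway
# enrichment.

#' Build the protein x condition log2-ratio profile matrix
#'
#' One row per accession of interest (typically the union of DE proteins
#' over comparisons), one column per condition.  The control column is
#' identically 0 (every ratio is taken against it); each stress column
#' holds the log2 median ratio of that condition versus control.  A
#' comparison in which the protein was not quantified is imputed as 0
#' (no evidence of change) and flagged in the `"imputed"` attribute.
#'
#' @param quants A protein quantitation `data.frame` from
#'   [quantify_proteins()].
#' @param accessions Accessions to include; each must be quantified in at
#'   least one comparison.
#' @param channel_conditions Named numeric vector mapping channels to
#'   condition labels (default `c("114" = 0, "115" = 50, "116" = 100,
#'   "117" = 200)` mM); the first entry is the control.
#' @return A numeric matrix (rows = accessions, columns = conditions, in
#'   mM) with a logical `"imputed"` attribute of the same shape.
#' @export
build_profile <- function(quants, accessions,
                          channel_conditions = c("114" = 0, "115" = 50,
                                                 "116" = 100, "117" = 200)) {
  accessions <- unique(as.character(accessions))
  control <- names(channel_conditions)[1L]
  stress <- names(channel_conditions)[-1L]
  comparisons <- paste(stress, control, sep = "/")
  q <- quants[quants$status == "quantified", , drop = FALSE]
  absent <- setdiff(accessions, q$protein_acc)
  if (length(absent))
    stop_validation("accession(s) not quantified in any comparison: ",
                    paste(utils::head(absent, 5L), collapse = ", "))
  mat <- matrix(0, length(accessions), length(channel_conditions),
                dimnames = list(accessions, as.character(channel_conditions)))
  imputed <- matrix(FALSE, length(accessions), length(channel_conditions),
                    dimnames = dimnames(mat))
  for (j in seq_along(comparisons)) {
    idx <- match(paste(accessions, comparisons[j]),
                 paste(q$protein_acc, q$comparison))
    found <- !is.na(idx)
    mat[found, j + 1L] <- log2(q$median_ratio[idx[found]])
    imputed[!found, j + 1L] <- TRUE
  }
  attr(mat, "imputed") <- imputed
  mat
}

#' Row-standardize a profile matrix
#'
#' Each row is centred and scaled to sample SD 1 (n - 1 denominator), so
#' a z-score of 0 marks a condition where the protein sits at its own
#' average abundance.  Constant rows, which carry no profile shape, are
#' mapped to all-zero rows rather than NaN.
#'
#' @param mat Numeric matrix with at least 2 columns.
#' @return The z-scored matrix, same shape and dimnames.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop_validation("z-scoring needs at least 2 columns")
  mu <- rowMeans(mat)
  sd <- apply(mat, 1L, stats::sd)
  z <- (mat - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Cluster profile rows hierarchically
#'
#' Agglomerative hierarchical clustering of the z-scored profiles with
#' Euclidean distance and average linkage, cut to exactly `k` clusters.
#' The result is deterministic for a given input order.
#'
#' @param zmat Row-standardized profile matrix; see [zscore_rows()].
#' @param k Number of clusters (default 6).
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @param distance Distance measure passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return A list with `cluster` (named integer vector of assignments in
#'   `1..k`), `order` (dendrogram leaf order) and the `hclust` tree.
#' @export
cluster_rows <- function(zmat, k = 6, method = "average",
                         distance = "euclidean") {
  zmat <- as.matrix(zmat)
  if (k < 1L || k > nrow(zmat))
    stop_validation("k must lie between 1 and the number of rows")
  tree <- stats::hclust(stats::dist(zmat, method = distance), method = method)
  cl <- stats::cutree(tree, k = k)
  list(cluster = cl, order = tree$order, tree = tree)
}

#' Hypergeometric pathway enrichment
#'
#' For every pathway with at least one member in the background, computes
#' the upper-tail hypergeometric probability of drawing at least `k` of
#' its `K` background members in a query of size `n` from a background of
#' size `N`, i.e. `p = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Raw p <= `p_max` defines significance (matching the fidelity of the
#' original analysis); Benjamini-Hochberg adjusted values are reported
#' alongside.
#'
#' @param query Character vector of query accessions (e.g. a DE set or a
#'   cluster); must be a subset of `background`.
#' @param background Character vector of background accessions (e.g. all
#'   quantified proteins).
#' @param ann An [annotation_map()] supplying pathway membership.
#' @param p_max Raw significance threshold (default 0.05).
#' @return A `data.frame` sorted by p-value with columns `pathway_id`,
#'   `k`, `K`, `n`, `N`, `p`, `p_adj`, `significant`.
#' @export
enrich <- function(query, background, ann, p_max = 0.05) {
  stopifnot(inherits(ann, "annotation_map"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (!all(query %in% background))
    stop_validation("query must be a subset of the background")
  N <- length(background)
  n <- length(query)
  pw <- ann$pathways[names(ann$pathways) %in% background]
  members <- split(rep(names(pw), lengths(pw)), unlist(pw, use.names = FALSE))
  members <- members[lengths(members) > 0L]
  if (length(members) == 0L)
    return(data.frame(pathway_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  K <- lengths(members)
  k <- vapply(members, function(m) sum(query %in% m), 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway_id = names(members), k = unname(k), K = unname(K),
                    n = n, N = N, p = unname(p),
                    p_adj = stats::p.adjust(unname(p), method = "BH"),
                    significant = unname(p) <= p_max,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
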