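# Agglomerative clustering of SNPs, cophenetic diagnostics, redundancy
# filtering and group construction for the group-sparse stage.

LINKAGES <- c("single", "complete", "centroid", "average", "ward")

hclust_method <- function(linkage) {
  switch(linkage,
         single = "single", complete = "complete", centroid = "centroid",
         average = "average", ward = "ward.D2",
         stop(sprintf("unknown linkage '%s'", linkage)))
}

#' Agglomerative hierarchical clustering of SNPs
#'
#' Standard bottom-up agglomeration on a precomputed dissimilarity matrix:
#' at each step the two clusters at smallest linkage distance are merged.
#' Five linkage rules are supported: single (shortest distance), complete
#' (maximum distance), centroid, average (unweighted mean distance) and
#' ward (least variance, implemented as Ward's criterion on the given
#' dissimilarities). Merge heights are non-decreasing for single, complete,
#' average and ward; centroid linkage may produce inversions, which is
#' inherent to the method and left intact.
#'
#' @param d symmetric dissimilarity matrix from [snp_distance()] (or any
#'   symmetric non-negative matrix with zero diagonal).
#' @param linkage one of `"single"`, `"complete"`, `"centroid"`,
#'   `"average"`, `"ward"`.
#' @return An object of class `snp_dendrogram` wrapping the `hclust` merge
#'   tree, with elements `hclust`, `linkage` and `labels`.
#' @export
hierarchical_cluster <- function(d, linkage = c("single", "complete", "centroid",
                                                "average", "ward")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  p <- nrow(d)
  if (p < 2L) stop("need at least 2 SNPs to cluster")
  if (max(abs(d - t(d))) > 1e-12) stop("dissimilarity matrix is not symmetric")
  h <- stats::hclust(stats::as.dist(d), method = hclust_method(linkage))
  structure(list(hclust = h, linkage = linkage, labels = h$labels),
            class = "snp_dendrogram")
}

#' @export
print.snp_dendrogram <- function(x, ...) {
  cat(sprintf("snp_dendrogram: %d leaves, %s linkage, height range [%g, %g]\n",
              length(x$hclust$order), x$linkage,
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cophenetic correlation between a dendrogram and its input distances
#'
#' The cophenetic distance of a pair of SNPs is the merge height at which
#' they first fall into a common cluster. The cophenetic correlation is the
#' Pearson correlation between the p(p-1)/2 original dissimilarities and
#' the cophenetic distances; values near 1 indicate the tree faithfully
#' represents the distances.
#'
#' @param tree a `snp_dendrogram` from [hierarchical_cluster()].
#' @param d the dissimilarity matrix the tree was built from.
#' @return A single correlation value in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, d) {
  d <- as.matrix(d)
  p <- nrow(d)
  if (p < 3L) stop("cophenetic correlation needs at least 3 SNPs")
  if (length(tree$hclust$order) != p)
    stop("dendrogram and distance matrix have different numbers of SNPs")
  coph <- stats::cophenetic(tree$hclust)
  orig <- stats::as.dist(d)
  # cophenetic() orders by the hclust labels; align to the matrix order
  coph <- as.matrix(coph)[rownames(d), rownames(d)]
  stats::cor(as.vector(orig), as.vector(stats::as.dist(coph)))
}

#' Cut a dendrogram and keep one representative SNP per cluster
#'
#' Cuts the merge tree into `n_clusters` flat clusters and retains from each
#' the medoid: the member minimising the summed dissimilarity to the other
#' members of its cluster (ties broken by original column order). This is
#' the redundancy filter of stage one — SNPs in tight LD end up in one
#' cluster and only one of them survives.
#'
#' @param g the [genotype_matrix()] the distances were computed from.
#' @param tree a `snp_dendrogram` over the same SNPs.
#' @param d the dissimilarity matrix used to build `tree`.
#' @param n_clusters number of clusters to keep (1..p). Default `ncol(g)/2`
#'   rounded up.
#' @return A [genotype_matrix()] with `n_clusters` SNP columns, original
#'   column order preserved, and attribute `kept_snps`.
#' @export
filter_redundant <- function(g, tree, d, n_clusters = ceiling(ncol(g) / 2)) {
  p <- ncol(g)
  if (n_clusters < 1L || n_clusters > p)
    stop(sprintf("n_clusters must be in 1..%d, got %s", p, n_clusters))
  d <- as.matrix(d)
  cl <- stats::cutree(tree$hclust, k = n_clusters)
  cl <- cl[colnames(g)]  # cutree is keyed by labels
  keep <- integer(n_clusters)
  for (k in seq_len(n_clusters)) {
    members <- which(cl == k)
    if (length(members) == 1L) {
      keep[k] <- members
    } else {
      within <- colSums(d[members, members, drop = FALSE])
      keep[k] <- members[which.min(within)]
    }
  }
  keep <- sort(keep)
  gene_of <- attr(g, "gene_of")
  out <- genotype_matrix(unclass_matrix(g)[, keep, drop = FALSE],
                         gene_of = gene_of, position = attr(g, "position"))
  attr(out, "kept_snps") <- colnames(g)[keep]
  out
}

#' Build SNP groups for the group-sparse penalty
#'
#' Two grouping modes:
#' \itemize{
#'   \item `"ld"`: SNPs are grouped by linkage disequilibrium — an edge
#'     joins any pair with r-squared at or above `threshold` (default 0.2)
#'     and groups are the connected components of that graph. Pairwise
#'     grouping is not transitive, so components (single-linkage closure)
#'     are used to obtain a true partition.
#'   \item `"gene"`: one group per gene symbol; SNPs without an annotation
#'     become singleton groups.
#' }
#'
#' @param g a [genotype_matrix()].
#' @param mode `"ld"` or `"gene"`.
#' @param ld r-squared matrix from [ld_r2()]; required for `mode = "ld"`
#'   (computed from `g` when omitted).
#' @param threshold r-squared threshold for an LD edge.
#' @param gene_of named character vector (SNP id -> gene); required for
#'   `mode = "gene"`, defaulting to the annotation carried by `g`.
#' @return A [snp_groups()] partition over the SNPs of `g`.
#' @export
build_groups <- function(g, mode = c("ld", "gene"), ld = NULL, threshold = 0.2,
                         gene_of = attr(g, "gene_of")) {
  mode <- match.arg(mode)
  snp_ids <- colnames(g)
  p <- ncol(g)
  if (mode == "ld") {
    if (is.null(ld)) ld <- ld_r2(g)
    adj <- (as.matrix(ld) >= threshold)
    diag(adj) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
    snp_groups(comp[seq_len(p)], snp_ids = snp_ids)
  } else {
    if (is.null(gene_of)) stop("mode = 'gene' requires a gene_of annotation map")
    genes <- unname(gene_of[snp_ids])
    # unannotated SNPs get their own singleton labels
    miss <- is.na(genes) | !nzchar(genes)
    genes[miss] <- paste0(".singleton_", snp_ids[miss])
    snp_groups(genes, snp_ids = snp_ids)
  }
}

#' Screen distance measures against linkage rules by cophenetic correlation
#'
#' Runs the full grid of four distance kinds (euclidean, absolute,
#' minkowski, variance-weighted) by five linkages (single, complete,
#' centroid, average, ward), computing the cophenetic correlation of each
#' combination. The combination with the correlation closest to 1 gives the
#' most faithful tree and is the recommended setting for the redundancy
#' filter.
#'
#' @param g a [genotype_matrix()].
#' @param minkowski_r Minkowski exponent used for the minkowski row
#'   (default 0.23).
#' @return A list with `grid` (4 x 5 matrix of cophenetic correlations,
#'   rows = distance kinds, columns = linkages) and `best` (list with
#'   `distance`, `linkage`, `cophenetic`).
#' @export
linkage_distance_screen <- function(g, minkowski_r = 0.23) {
  kinds <- c("euclidean", "absolute", "minkowski", "variance_weighted")
  grid <- matrix(NA_real_, length(kinds), length(LINKAGES),
                 dimnames = list(kinds, LINKAGES))
  for (kind in kinds) {
    d <- suppressWarnings(snp_distance(g, kind, r = minkowski_r))
    for (lk in LINKAGES) {
      tree <- hierarchical_cluster(d, lk)
      grid[kind, lk] <- cophenetic_correlation(tree, d)
    }
  }
  best_idx <- which(grid == max(grid), arr.ind = TRUE)[1L, ]
  list(grid = grid,
       best = list(distance = kinds[best_idx[1L]],
                   linkage = LINKAGES[best_idx[2L]],
                   cophenetic = max(grid)))
}

#' Export a dendrogram as a Newick tree
#'
#' Branch lengths derive from the merge heights, so tools reading Newick can
#' redraw the tree.
#'
#' @param tree a `snp_dendrogram`.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
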