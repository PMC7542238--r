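# Pairwise SNP dissimilarities and linkage-disequilibrium r-squared.
# Distances are between SNP columns, taken over samples.

#' Pairwise SNP dissimilarity matrix
#'
#' Computes a p x p dissimilarity matrix between SNP genotype columns
#' \eqn{u, v} over the n samples:
#' \itemize{
#'   \item `euclidean`: \eqn{(\sum_i (u_i - v_i)^2)^{1/2}}
#'   \item `absolute`: \eqn{\sum_i |u_i - v_i|} (Manhattan)
#'   \item `minkowski`: \eqn{(\sum_i |u_i - v_i|^r)^{1/r}}; any `r > 0` is
#'     accepted as a power dissimilarity — for `r < 1` the triangle
#'     inequality fails and a warning is emitted, but agglomerative
#'     clustering only needs a dissimilarity
#'   \item `variance_weighted`: \eqn{(\sum_i (u_i - v_i)^2 / s_i^2)^{1/2}}
#'     where \eqn{s_i^2} is the variance of sample i's genotypes across SNPs
#' }
#'
#' @param g a [genotype_matrix()].
#' @param kind one of `"euclidean"`, `"absolute"`, `"minkowski"`,
#'   `"variance_weighted"`.
#' @param r Minkowski exponent (> 0); only used for `kind = "minkowski"`.
#' @return A symmetric p x p numeric matrix with zero diagonal, SNP ids as
#'   dimnames, and attribute `kind`.
#' @export
snp_distance <- function(g, kind = c("euclidean", "absolute", "minkowski",
                                     "variance_weighted"), r = 2) {
  kind <- match.arg(kind)
  vals <- unclass_matrix(g)        # n x p, columns are SNPs
  m <- t(vals)                     # rows are SNPs for stats::dist
  d <- switch(kind,
    euclidean = stats::dist(m, method = "euclidean"),
    absolute = stats::dist(m, method = "manhattan"),
    minkowski = {
      if (!is.numeric(r) || length(r) != 1L || r <= 0)
        stop("minkowski exponent r must be a positive number")
      if (r < 1)
        warning(sprintf("minkowski r = %g < 1 is a power dissimilarity, not a metric", r))
      stats::dist(m, method = "minkowski", p = r)
    },
    variance_weighted = {
      s2 <- apply(vals, 1L, stats::var)  # per-sample variance across SNPs
      zero <- which(s2 <= 0)
      if (length(zero) > 0L)
        stop(sprintf("sample '%s' has zero genotype variance across SNPs; variance-weighted distance undefined",
                     rownames(vals)[zero[1L]]))
      stats::dist(t(vals / sqrt(s2)), method = "euclidean")
    })
  out <- as.matrix(d)
  dimnames(out) <- list(colnames(vals), colnames(vals))
  attr(out, "kind") <- kind
  if (kind == "minkowski") attr(out, "r") <- r
  out
}

#' Linkage-disequilibrium r-squared matrix
#'
#' r-squared between two SNPs is the squared Pearson correlation of their
#' additive genotype codes across samples. Constant SNPs (zero variance)
#' have undefined correlation; they get r-squared 0 off-diagonal, 1 on the
#' diagonal, and are reported in the `constant_snps` attribute.
#'
#' @param g a [genotype_matrix()].
#' @return Symmetric p x p matrix of values in `[0, 1]`, unit diagonal, with
#'   attribute `constant_snps` (character vector, possibly empty).
#' @export
ld_r2 <- function(g) {
  vals <- unclass_matrix(g)
  sds <- apply(vals, 2L, stats::sd)
  constant <- colnames(vals)[sds == 0]
  if (length(constant) > 0L)
    message(sprintf("ld_r2: %d constant SNP(s) assigned r-squared 0 off-diagonal", length(constant)))
  cc <- suppressWarnings(stats::cor(vals))
  cc[is.na(cc)] <- 0
  r2 <- cc^2
  r2 <- pmin(pmax(r2, 0), 1)
  diag(r2) <- 1
  attr(r2, "constant_snps") <- constant
  r2
}
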