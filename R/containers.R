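#' Construct a validated genotype matrix
#'
#' A `genotype_matrix` holds additively coded genotypes for `n` samples
#' (rows) by `p` SNPs (columns). Codes are 0 (wild-type homozygote),
#' 1 (heterozygote) and 2 (mutant homozygote); a single designated missing
#' code (default -1) is allowed only when `allow_missing = TRUE`.
#'
#' @param values integer-valued matrix, samples x SNPs.
#' @param snp_ids character vector of unique SNP identifiers (defaults to
#'   the column names of `values`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to the row names of `values`).
#' @param gene_of optional named character vector mapping SNP id to gene
#'   symbol; SNPs absent from the map are treated as unannotated.
#' @param position optional data frame with columns `snp_id`, `chrom`, `bp`.
#' @param missing_code integer code standing for a missing genotype.
#' @param allow_missing logical; if `FALSE` any `missing_code` entry is an
#'   error.
#' @return An object of class `genotype_matrix`: the integer matrix with
#'   `dimnames` set, plus attributes `gene_of` and `position`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("rs1", "rs2"))))
#' dim(g)
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values),
                            sample_ids = rownames(values),
                            gene_of = NULL, position = NULL,
                            missing_code = -1L, allow_missing = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  n <- nrow(values); p <- ncol(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (length(snp_ids) != p) stop("length(snp_ids) must equal ncol(values)")
  if (length(sample_ids) != n) stop("length(sample_ids) must equal nrow(values)")
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  ok <- values %in% c(0L, 1L, 2L) | (allow_missing & values == missing_code)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    bad_row <- (bad - 1L) %% n + 1L
    bad_col <- (bad - 1L) %/% n + 1L
    stop(sprintf(
      "invalid genotype code %s for SNP '%s', sample '%s' (allowed: 0, 1, 2%s)",
      values[bad], snp_ids[bad_col], sample_ids[bad_row],
      if (allow_missing) sprintf(", %d for missing", missing_code) else ""))
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(values,
            gene_of = gene_of, position = position,
            missing_code = missing_code,
            class = c("genotype_matrix", "matrix", "array"))
}

#' Construct a validated phenotype matrix
#'
#' Holds continuous ROI phenotype values (e.g. volume, thickness or density
#' summaries) for `n` samples (rows) by `q` ROIs (columns). All entries must
#' be finite.
#'
#' @param values numeric matrix, samples x ROIs.
#' @param roi_ids,sample_ids unique identifiers; default to `dimnames`.
#' @return An object of class `phenotype_matrix`.
#' @examples
#' ph <- phenotype_matrix(matrix(rnorm(4, 100), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("roi1", "roi2"))))
#' @export
phenotype_matrix <- function(values, roi_ids = colnames(values),
                             sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); q <- ncol(values)
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(q))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  if (length(roi_ids) != q) stop("length(roi_ids) must equal ncol(values)")
  if (length(sample_ids) != n) stop("length(sample_ids) must equal nrow(values)")
  if (anyDuplicated(roi_ids)) stop("ROI ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite phenotype value at sample '%s', ROI '%s'",
                 sample_ids[(bad - 1L) %% n + 1L],
                 roi_ids[(bad - 1L) %/% n + 1L]))
  }
  dimnames(values) <- list(sample_ids, roi_ids)
  structure(values, class = c("phenotype_matrix", "matrix", "array"))
}

#' Partition SNPs into groups
#'
#' Represents the partition used by the group-sparse penalty: every SNP
#' belongs to exactly one group, no group is empty. Groups are relabelled to
#' consecutive integers 1..K in order of first appearance.
#'
#' @param assignment integer (or factor/character) vector of length p giving
#'   each SNP's group label.
#' @param snp_ids optional SNP ids carried along as names.
#' @return An object of class `snp_groups`: an integer vector with attributes
#'   `K` (number of groups) and `sizes`.
#' @export
snp_groups <- function(assignment, snp_ids = names(assignment)) {
  if (length(assignment) == 0L) stop("empty group assignment")
  f <- factor(assignment, levels = unique(assignment))
  a <- as.integer(f)
  if (anyNA(a)) stop("group assignment contains NA")
  sizes <- tabulate(a)
  if (any(sizes == 0L)) stop("empty SNP group after relabelling")
  names(a) <- snp_ids
  structure(a, K = max(a), sizes = sizes, class = "snp_groups")
}

#' @export
print.snp_groups <- function(x, ...) {
  cat(sprintf("snp_groups: %d SNPs in %d groups (sizes %s)\n",
              length(x), attr(x, "K"),
              paste(utils::head(attr(x, "sizes"), 10L), collapse = ", ")))
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix: %d samples x %d ROIs\n", nrow(x), ncol(x)))
  invisible(x)
}

# Drop the domain class but keep the plain matrix (used internally where
# numeric matrix semantics are wanted).
unclass_matrix <- function(x) {
  y <- as.matrix(x)
  attr(y, "gene_of") <- NULL
  attr(y, "position") <- NULL
  attr(y, "missing_code") <- NULL
  class(y) <- c("matrix", "array")
  y
}

#' Align a genotype and a phenotype matrix on shared samples
#'
#' Restricts both matrices to the intersection of their sample ids, in the
#' same (genotype-side) order. Alignment is always by id, never by row
#' position, so shuffled inputs are handled correctly.
#'
#' @param g a [genotype_matrix()].
#' @param ph a [phenotype_matrix()].
#' @return A list with elements `genotypes` and `phenotypes`, row-aligned.
#' @export
align_samples <- function(g, ph) {
  common <- intersect(rownames(g), rownames(ph))
  if (length(common) == 0L) stop("no samples shared between genotypes and phenotypes")
  dropped_g <- nrow(g) - length(common)
  dropped_ph <- nrow(ph) - length(common)
  if (dropped_g > 0L || dropped_ph > 0L)
    message(sprintf("align_samples: kept %d samples (dropped %d genotype-only, %d phenotype-only)",
                    length(common), dropped_g, dropped_ph))
  g2 <- genotype_matrix(unclass_matrix(g)[common, , drop = FALSE],
                        gene_of = attr(g, "gene_of"),
                        position = attr(g, "position"))
  ph2 <- phenotype_matrix(unclass_matrix(ph)[common, , drop = FALSE])
  list(genotypes = g2, phenotypes = ph2)
}
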