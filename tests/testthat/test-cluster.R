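# Toy 1-D point set {0, 1, 10}: distances d(1,2)=1, d(1,3)=10, d(2,3)=9.
toy3 <- function() {
  d <- as.matrix(dist(c(0, 1, 10)))
  dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  d
}

test_that("single and complete linkage reproduce hand agglomeration", {
  d <- toy3()
  ts <- hierarchical_cluster(d, "single")
  expect_equal(ts$hclust$height, c(1, 9))        # {a,b} at 1, then +c at min(10,9)
  expect_equal(sort(-ts$hclust$merge[1, ]), c(1, 2))
  tc <- hierarchical_cluster(d, "complete")
  expect_equal(tc$hclust$height, c(1, 10))       # +c at max(10,9)
})

test_that("two SNPs produce exactly one merge at their distance", {
  g <- genotype_matrix(matrix(c(0L, 0L, 1L, 2L), 2, 2))
  d <- snp_distance(g, "euclidean")
  t2 <- hierarchical_cluster(d, "average")
  expect_equal(length(t2$hclust$height), 1L)
  expect_equal(t2$hclust$height, d[1, 2])
  expect_error(hierarchical_cluster(d[1, 1, drop = FALSE], "single"), "at least 2")
})

test_that("cophenetic correlation is 1 on an ultrametric matrix", {
  d <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  for (lk in c("single", "complete", "average")) {
    tree <- hierarchical_cluster(d, lk)
    expect_equal(cophenetic_correlation(tree, d), 1.0)
  }
  expect_error(cophenetic_correlation(hierarchical_cluster(toy3(), "single"),
                                      toy3()[1:2, 1:2]), "different numbers|at least 3")
})

test_that("cophenetic correlation matches a brute-force merge-replay oracle", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(runif(36, 1, 10), 6, 6)
    d <- as.matrix(dist(m))
    dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
    for (lk in c("single", "complete", "average", "ward")) {
      tree <- hierarchical_cluster(d, lk)
      coph <- cophenetic_bruteforce(tree$hclust)[rownames(d), rownames(d)]
      oracle <- cor(as.vector(as.dist(d)), as.vector(as.dist(coph)))
      expect_equal(cophenetic_correlation(tree, d), oracle, tolerance = 1e-12)
    }
  }
})

test_that("cophenetic correlation is invariant to leaf relabeling", {
  set.seed(7)
  d <- as.matrix(dist(matrix(runif(24), 6)))
  dimnames(d) <- list(paste0("x", 1:6), paste0("x", 1:6))
  perm <- sample(6)
  dp <- d[perm, perm]
  c1 <- cophenetic_correlation(hierarchical_cluster(d, "average"), d)
  c2 <- cophenetic_correlation(hierarchical_cluster(dp, "average"), dp)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("single-linkage cophenetic distances never exceed the originals", {
  set.seed(19)
  d <- as.matrix(dist(matrix(runif(40), 8)))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  tree <- hierarchical_cluster(d, "single")
  coph <- cophenetic_bruteforce(tree$hclust)[rownames(d), rownames(d)]
  expect_true(all(coph <= d + 1e-12))
})

test_that("filter_redundant keeps the per-cluster medoid", {
  # 5 SNPs in 2 well-separated clusters; exhaustive medoid search oracle
  set.seed(5)
  base1 <- sample(0:2, 30, replace = TRUE)
  base2 <- sample(0:2, 30, replace = TRUE)
  flip <- function(v, k) { i <- sample(30, k); v[i] <- (v[i] + 1L) %% 3L; v }
  vals <- cbind(base1, flip(base1, 2), flip(base1, 3), base2, flip(base2, 2))
  g <- genotype_matrix(matrix(as.integer(vals), 30, 5))
  d <- snp_distance(g, "euclidean")
  tree <- hierarchical_cluster(d, "average")
  kept <- attr(filter_redundant(g, tree, d, n_clusters = 2), "kept_snps")
  cl <- cutree(tree$hclust, k = 2)[colnames(g)]
  oracle <- sort(vapply(1:2, function(k) {
    members <- which(cl == k)
    members[which.min(colSums(d[members, members, drop = FALSE]))]
  }, 1L))
  expect_identical(kept, colnames(g)[oracle])
})

test_that("filter_redundant keeps all SNPs at n_clusters = p and dedups duplicates", {
  g <- random_genotypes(12, 5, seed = 13)
  vals <- unclass(g)[, ]
  vals[, 5] <- vals[, 4]  # duplicate column
  g <- genotype_matrix(vals)
  d <- snp_distance(g, "euclidean")
  tree <- hierarchical_cluster(d, "single")
  expect_identical(colnames(filter_redundant(g, tree, d, 5)), colnames(g))
  kept <- attr(filter_redundant(g, tree, d, 4), "kept_snps")
  expect_equal(length(kept), 4L)
  expect_equal(sum(c("snp4", "snp5") %in% kept), 1L)  # exactly one duplicate survives
  expect_error(filter_redundant(g, tree, d, 0), "n_clusters")
  expect_error(filter_redundant(g, tree, d, 6), "n_clusters")
})

test_that("LD groups are connected components of the r2-threshold graph", {
  g <- random_genotypes(10, 4, seed = 1)
  ld <- diag(4)
  ld[1, 2] <- ld[2, 1] <- 0.5
  ld[2, 3] <- ld[3, 2] <- 0.3
  ld[1, 3] <- ld[3, 1] <- 0.01
  gr <- build_groups(g, "ld", ld = ld, threshold = 0.2)
  expect_equal(unname(gr[1]), unname(gr[2]))   # direct edge
  expect_equal(unname(gr[2]), unname(gr[3]))   # chained through snp2
  expect_false(gr[4] == gr[1])                 # isolated
  # threshold above 1: everything singleton
  gr_none <- build_groups(g, "ld", ld = ld, threshold = 1.01)
  expect_equal(attr(gr_none, "K"), 4L)
})

test_that("gene-mode grouping pools by symbol with singleton fallback", {
  g <- random_genotypes(8, 3, seed = 2)
  gene_of <- c(snp1 = "G1", snp2 = "G1", snp3 = "G2")
  gr <- build_groups(g, "gene", gene_of = gene_of)
  expect_equal(attr(gr, "K"), 2L)
  expect_equal(unname(gr[1]), unname(gr[2]))
  gr2 <- build_groups(g, "gene", gene_of = c(snp1 = "G1"))  # snp2, snp3 unannotated
  expect_equal(attr(gr2, "K"), 3L)
  expect_error(build_groups(g, "gene", gene_of = NULL), "gene_of")
})

test_that("LD grouping is invariant to SNP order up to relabeling", {
  g <- random_genotypes(40, 10, seed = 21)
  gr <- build_groups(g, "ld", threshold = 0.1)
  perm <- sample(10)
  gp <- genotype_matrix(unclass(g)[, perm])
  gr_p <- build_groups(gp, "ld", threshold = 0.1)
  # same partition: co-membership matrices agree after permutation
  co <- function(a) outer(as.integer(a), as.integer(a), `==`)
  expect_identical(co(gr)[perm, perm], co(gr_p))
})

test_that("the distance-by-linkage screen composes its parts and stays in [-1,1]", {
  g <- random_genotypes(25, 8, seed = 6)
  scr <- linkage_distance_screen(g, minkowski_r = 0.23)
  expect_equal(dim(scr$grid), c(4L, 5L))
  expect_true(all(scr$grid >= -1 & scr$grid <= 1))
  expect_equal(scr$best$cophenetic, max(scr$grid))
  # compositional oracle: recompute two cells by explicit calls
  d <- snp_distance(g, "euclidean")
  tree <- hierarchical_cluster(d, "ward")
  expect_equal(scr$grid["euclidean", "ward"],
               cophenetic_correlation(tree, d), tolerance = 1e-12)
  dm <- suppressWarnings(snp_distance(g, "minkowski", r = 0.23))
  tm <- hierarchical_cluster(dm, "single")
  expect_equal(scr$grid["minkowski", "single"],
               cophenetic_correlation(tm, dm), tolerance = 1e-12)
})

test_that("dendrograms export to Newick with all leaf labels", {
  g <- random_genotypes(12, 5, seed = 8)
  d <- snp_distance(g, "euclidean")
  tree <- hierarchical_cluster(d, "average")
  nwk <- write_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, colnames(g))
  f <- tmpfile(".nwk")
  write_newick(tree, f)
  expect_setequal(ape::read.tree(f)$tip.label, colnames(g))
})
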