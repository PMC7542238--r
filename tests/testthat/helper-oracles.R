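# Independent oracles and fixture builders for the test suite. Each oracle
# deliberately avoids the code path it validates.

# --- proximal-gradient (FISTA) oracle for the group-sparse objective -------
# Minimises ||W'X - Y||_F^2 + g1 sum_k ||W_k||_F + g2 sum_i ||w^i||_2 by
# accelerated proximal gradient. Rows nest inside groups, so the prox of the
# combined penalty is exact: row-wise shrinkage followed by group-wise
# shrinkage (tree-structured sparse group lasso).
fista_oracle <- function(X, Y, groups, gamma1, gamma2, iters = 20000L) {
  d <- nrow(X)
  XXt <- tcrossprod(X)
  XYt <- tcrossprod(X, Y)
  L <- 2 * max(eigen(XXt, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  K <- max(groups)
  grp_rows <- lapply(seq_len(K), function(k) which(groups == k))
  shrink_rows <- function(W, lam) {
    rn <- sqrt(rowSums(W^2))
    W * pmax(0, 1 - lam / pmax(rn, 1e-300))
  }
  shrink_groups <- function(W, lam) {
    for (rows in grp_rows) {
      gn <- sqrt(sum(W[rows, ]^2))
      W[rows, ] <- W[rows, , drop = FALSE] * max(0, 1 - lam / max(gn, 1e-300))
    }
    W
  }
  objective <- function(W) {
    gn <- vapply(grp_rows, function(rows) sqrt(sum(W[rows, ]^2)), 0)
    sum((crossprod(W, X) - Y)^2) + gamma1 * sum(gn) +
      gamma2 * sum(sqrt(rowSums(W^2)))
  }
  W <- matrix(0, d, nrow(Y))
  Z <- W
  tk <- 1
  best_obj <- objective(W)
  best_W <- W
  for (it in seq_len(iters)) {
    G <- Z - step * 2 * (XXt %*% Z - XYt)
    W_new <- shrink_groups(shrink_rows(G, step * gamma2), step * gamma1)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- W_new + ((tk - 1) / tk_new) * (W_new - W)
    W <- W_new
    tk <- tk_new
    if (it %% 50L == 0L || it == iters) {
      ob <- objective(W)
      if (ob < best_obj) {
        best_obj <- ob
        best_W <- W
      }
    }
  }
  list(W = best_W, objective = best_obj)
}

# --- brute-force cophenetic distances ---------------------------------------
# Replays the merge sequence of an hclust tree, recording for every leaf
# pair the height at which the two leaves first share a cluster. O(p^2)
# enumeration, independent of stats::cophenetic.
cophenetic_bruteforce <- function(h) {
  p <- length(h$order)
  D <- matrix(0, p, p)
  members <- vector("list", nrow(h$merge))
  leaves <- function(j, i) if (j < 0) -j else members[[j]]
  for (i in seq_len(nrow(h$merge))) {
    a <- leaves(h$merge[i, 1L], i)
    b <- leaves(h$merge[i, 2L], i)
    for (x in a) for (y in b) D[x, y] <- D[y, x] <- h$height[i]
    members[[i]] <- c(a, b)
  }
  dimnames(D) <- list(h$labels, h$labels)
  D
}

# --- generic QP oracle for the epsilon-SVR dual -----------------------------
# Solves the standard 2l-variable dual
#   max -0.5 (a - a*)' K (a - a*) - eps sum(a + a*) + y'(a - a*)
#   s.t. sum(a - a*) = 0, 0 <= a, a* <= C
# with kernlab's interior-point QP solver and returns the dual objective.
svr_dual_oracle <- function(K, y, C, eps) {
  l <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * l)
  cvec <- c(eps - y, eps + y)  # ipop minimises 0.5 z'Hz + c'z
  A <- matrix(c(rep(1, l), rep(-1, l)), 1)
  sol <- kernlab::ipop(cvec, H, A, b = 0, l = rep(0, 2 * l),
                       u = rep(C, 2 * l), r = 0, sigf = 9, maxiter = 200)
  z <- kernlab::primal(sol)
  alpha <- z[1:l]
  alpha_star <- z[(l + 1):(2 * l)]
  beta <- alpha - alpha_star
  as.numeric(-0.5 * t(beta) %*% K %*% beta - eps * sum(alpha + alpha_star) +
               sum(y * beta))
}

# Dual objective of a fitted svr_model, evaluated over all training points
# (non-support vectors carry beta = 0).
svr_dual_objective <- function(model, X_train, y) {
  Xs <- sweep(sweep(as.matrix(X_train), 2L, model$scale$center), 2L,
              model$scale$scale, `/`)
  K <- snproi:::kernel_matrix(model$spec, Xs, Xs)
  beta <- rep(0, length(y))
  # match support vectors back to training rows by coordinates
  for (i in seq_along(model$beta)) {
    hit <- which(apply(Xs, 1L, function(r) all(abs(r - model$sv[i, ]) < 1e-12)))
    beta[hit[1L]] <- beta[hit[1L]] + model$beta[i]
  }
  as.numeric(-0.5 * t(beta) %*% K %*% beta -
               model$eps_tube * sum(abs(beta)) + sum(y * beta))
}

# --- fixtures ---------------------------------------------------------------
random_genotypes <- function(n, p, seed = 1L) {
  set.seed(seed)
  genotype_matrix(matrix(sample(0:2, n * p, replace = TRUE), n, p))
}

random_design <- function(d, n, c_rois, seed = 1L, standardize = TRUE) {
  set.seed(seed)
  g <- matrix(rnorm(n * d), n, d)
  y <- matrix(rnorm(n * c_rois), n, c_rois)
  design_pair(g, y, standardize = standardize)
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
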