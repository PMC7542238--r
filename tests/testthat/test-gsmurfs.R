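singleton_groups <- function(d) snp_groups(seq_len(d))

test_that("design_pair standardizes SNP rows and centers ROI rows", {
  dp <- random_design(8, 40, 3, seed = 2)
  expect_lt(max(abs(rowMeans(dp$X))), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(dp$X^2) / (ncol(dp$X) - 1)) - 1)), 1e-10)
  expect_lt(max(abs(rowMeans(dp$Y))), 1e-10)
})

test_that("the objective reduces correctly in its limiting cases", {
  dp <- random_design(6, 15, 2, seed = 3)
  gr <- snp_groups(c(1, 1, 2, 2, 3, 3))
  W0 <- matrix(0, 6, 2)
  expect_equal(gsmurfs_objective(W0, dp, gr, 5, 7), sum(dp$Y^2))  # W=0
  W <- matrix(rnorm(12), 6, 2)
  expect_equal(gsmurfs_objective(W, dp, gr, 0, 0),
               sum((crossprod(W, dp$X) - dp$Y)^2))                # pure residual
  # all-singleton groups: G2,1 and l2,1 terms coincide
  expect_equal(gsmurfs_objective(W, dp, singleton_groups(6), 3, 0),
               gsmurfs_objective(W, dp, singleton_groups(6), 0, 3))
  expect_error(gsmurfs_objective(matrix(0, 5, 2), dp, gr, 1, 1), "W must be")
})

test_that("ridge solves the identity design exactly and shrinks monotonically", {
  n <- 5
  Yv <- matrix(rnorm(n * 2), n, 2)
  dp <- design_pair(diag(n), Yv, standardize = FALSE)
  expect_lt(max(abs(fit_ridge(dp, 0) - t(dp$Y))), 1e-10)  # X = I -> W = Y'
  dp2 <- random_design(6, 20, 2, seed = 5)
  norms <- sapply(c(0.01, 0.1, 1, 10, 100, 1000),
                  function(g) sqrt(sum(fit_ridge(dp2, g)^2)))
  expect_true(all(diff(norms) < 0))
  # singular at gamma = 0 when p > n
  dp3 <- random_design(10, 4, 2, seed = 6)
  expect_error(fit_ridge(dp3, 0), "singular")
})

test_that("ridge matches a generic convex optimizer on a random instance", {
  dp <- random_design(5, 8, 2, seed = 7)
  gamma <- 0.7
  W_closed <- fit_ridge(dp, gamma)
  obj <- function(w) {
    W <- matrix(w, 5, 2)
    sum((crossprod(W, dp$X) - dp$Y)^2) + gamma * sum(W^2)
  }
  grad <- function(w) {
    W <- matrix(w, 5, 2)
    as.vector(2 * (tcrossprod(dp$X) %*% W - tcrossprod(dp$X, dp$Y)) + 2 * gamma * W)
  }
  o <- optim(rep(0, 10), obj, grad, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(abs(obj(as.vector(W_closed)) - o$value) / max(1, o$value), 1e-6)
})

test_that("vanishing penalties recover the least-squares solution", {
  dp <- random_design(8, 50, 3, seed = 8)
  gr <- snp_groups(rep(1:4, each = 2))
  fit <- fit_gsmurfs(dp, gr, gamma1 = 1e-10, gamma2 = 1e-10)
  W_ls <- solve(tcrossprod(dp$X), tcrossprod(dp$X, dp$Y))
  expect_lt(max(abs(fit$W - W_ls)), 1e-6)
})

test_that("a large group penalty silences inactive groups", {
  set.seed(9)
  d <- 12; n <- 80; cc <- 3
  gr <- snp_groups(rep(1:4, each = 3))
  W_true <- matrix(0, d, cc)
  W_true[1:3, ] <- rnorm(9, sd = 2)           # only group 1 active
  X <- matrix(rnorm(d * n), d, n)
  Y <- crossprod(W_true, X) + matrix(rnorm(cc * n, sd = 0.05), cc, n)
  dp <- structure(list(X = X, Y = Y, snp_ids = paste0("s", 1:d),
                       roi_ids = paste0("r", 1:cc),
                       x_center = rep(0, d), x_scale = rep(1, d),
                       y_center = rep(0, cc), standardized = FALSE),
                  class = "design_pair")
  fit <- fit_gsmurfs(dp, gr, gamma1 = 200, gamma2 = 0)
  rn <- sqrt(rowSums(fit$W^2))
  expect_lt(max(rn[4:12]), 1e-3 * max(rn))
})

test_that("IRLS attains the convex optimum found by a proximal-gradient oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    d <- sample(10:25, 1); n <- sample(15:30, 1); cc <- sample(2:5, 1)
    K <- sample(3:6, 1)
    gr <- snp_groups(sort(sample(K, d, replace = TRUE)))
    X <- matrix(rnorm(d * n), d, n)
    Y <- matrix(rnorm(cc * n), cc, n)
    dp <- structure(list(X = X, Y = Y, snp_ids = paste0("s", 1:d),
                         roi_ids = paste0("r", 1:cc),
                         x_center = rep(0, d), x_scale = rep(1, d),
                         y_center = rep(0, cc), standardized = FALSE),
                    class = "design_pair")
    g1 <- runif(1, 0.5, 5); g2 <- runif(1, 0.5, 5)
    fit <- fit_gsmurfs(dp, gr, gamma1 = g1, gamma2 = g2)
    oracle <- fista_oracle(X, Y, as.integer(gr), g1, g2, iters = 20000L)
    gap <- (fit$objective - oracle$objective) / max(1, abs(oracle$objective))
    expect_lt(abs(gap), 1e-4)
    expect_lt(fit$stationarity, 1e-5)
  }
})

test_that("the smoothed IRLS objective trace is non-increasing", {
  for (seed in 1:5) {
    dp <- random_design(10, 25, 3, seed = seed)
    gr <- snp_groups(rep(1:5, each = 2))
    fit <- fit_gsmurfs(dp, gr, gamma1 = 2, gamma2 = 2)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
  }
})

test_that("row-norm mass shrinks monotonically in the row penalty", {
  dp <- random_design(8, 30, 2, seed = 10)
  gr <- snp_groups(rep(1:2, each = 4))
  mass <- sapply(c(0.01, 0.1, 1, 10, 100),
                 function(g2) sum(sqrt(rowSums(fit_gsmurfs(dp, gr, 0.1, g2)$W^2))))
  expect_true(all(diff(mass) <= 1e-8))
})

test_that("snp importance is the row norm and respects orthogonal task rotations", {
  W <- matrix(0, 4, 3)
  expect_equal(unname(snp_importance(W)), rep(0, 4))
  W[2, ] <- c(3, 0, 4)
  expect_equal(which.max(snp_importance(W)), 2L)
  expect_equal(max(snp_importance(W)), 5)
  set.seed(11)
  Wr <- matrix(rnorm(12), 4, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(snp_importance(Wr %*% Q), snp_importance(Wr), tolerance = 1e-12)
})

test_that("top-k selection orders by score with index tie-breaks", {
  expect_identical(select_top_k(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_top_k(c(3, 1, 2), 3), c(1L, 3L, 2L))
  expect_identical(select_top_k(c(1, 1, 0), 1), 1L)
  expect_error(select_top_k(c(1, 2), 0), "k must be")
  expect_error(select_top_k(c(1, 2), 3), "k must be")
})
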