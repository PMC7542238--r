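toy_xy <- function(n = 30, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n, -2, 2), n, 1)
  list(x = x, y = 2 * x[, 1] + 0.5)
}

test_that("hyperparameters are validated", {
  t <- toy_xy()
  expect_error(fit_svr(t$x, t$y, C = -1), "C must be")
  expect_error(fit_svr(t$x, t$y, C = 0), "C must be")
  expect_error(fit_svr(t$x, t$y, eps_tube = -0.1), "eps_tube")
  expect_error(fit_svr(t$x[1, , drop = FALSE], t$y[1]), "at least 2")
  expect_error(predict_svr(fit_svr(t$x, t$y), cbind(t$x, t$x)), "expected 1 features")
})

test_that("exactly linear data is interpolated within the insensitive tube", {
  t <- toy_xy(40, seed = 2)
  m <- fit_svr(t$x, t$y, kernel = "linear", C = 1e4, eps_tube = 0.1)
  expect_lte(max(abs(predict_svr(m, t$x) - t$y)), 0.1 + 1e-4)
})

test_that("a constant response degenerates to its mean", {
  x <- matrix(rnorm(10), 10, 1)
  expect_warning(m <- fit_svr(x, rep(3.5, 10)), "constant response")
  expect_equal(predict_svr(m, x), rep(3.5, 10))
})

test_that("dual constraints hold on every fitted model", {
  set.seed(3)
  for (kernel in c("linear", "polynomial", "rbf")) {
    x <- matrix(rnorm(60), 20, 3)
    y <- x[, 1]^2 + rnorm(20, sd = 0.3) + 5
    C <- 2.5
    m <- fit_svr(x, y, kernel = kernel, C = C, eps_tube = 0.05)
    expect_lt(abs(sum(m$beta)), 1e-6)
    expect_true(all(abs(m$beta) <= C + 1e-8))
  }
})

test_that("prediction is deterministic and matches the stored fitted values", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  y <- sin(x[, 1]) + 10
  m <- fit_svr(x, y, kernel = "rbf")
  expect_equal(predict_svr(m, x), m$fitted, tolerance = 1e-10)
  expect_identical(predict_svr(m, x), predict_svr(m, x))
})

test_that("a linear-kernel model equals its explicit primal expansion", {
  set.seed(5)
  x <- matrix(rnorm(50), 25, 2)
  y <- x %*% c(1.5, -2) + rnorm(25, sd = 0.1) + 100
  m <- fit_svr(x, y, kernel = "linear", C = 50, eps_tube = 0.05)
  w <- crossprod(m$sv, m$beta)                      # primal weights on scaled x
  xs <- sweep(sweep(x, 2, m$scale$center), 2, m$scale$scale, `/`)
  expect_equal(predict_svr(m, x), as.numeric(xs %*% w + m$b), tolerance = 1e-10)
})

test_that("with a huge box and a tiny tube, linear SVR approaches least squares", {
  # the limit of eps-SVR as C grows and the tube shrinks is least-absolute-
  # deviation regression, which coincides with least squares exactly when
  # the data are noiselessly linear — the regime this limit is stated for
  set.seed(6)
  x <- matrix(runif(60, -1, 1), 30, 2)
  y <- as.numeric(x %*% c(2, -1) + 3)
  m <- fit_svr(x, y, kernel = "linear", C = 1e4, eps_tube = 1e-4)
  ols <- lm.fit(cbind(1, x), y)
  pred_ols <- as.numeric(cbind(1, x) %*% ols$coefficients)
  expect_lt(max(abs(predict_svr(m, x) - pred_ols)), 1e-3)
})

test_that("the dual objective matches a generic QP oracle on a 6-point problem", {
  x <- matrix(c(-2, -1, -0.3, 0.4, 1.1, 2), 6, 1)
  y <- c(4.1, 0.8, 0.2, 0.1, 1.4, 3.9)   # roughly quadratic
  C <- 3; eps <- 0.1
  m <- fit_svr(x, y, kernel = "rbf", C = C, eps_tube = eps)
  xs <- sweep(sweep(x, 2, m$scale$center), 2, m$scale$scale, `/`)
  K <- snproi:::kernel_matrix(m$spec, xs, xs)
  obj_fit <- svr_dual_objective(m, x, y)
  obj_qp <- svr_dual_oracle(K, y, C, eps)
  expect_lt(abs(obj_fit - obj_qp) / max(1, abs(obj_qp)), 1e-4)
})

test_that("fit_all_rois trains one model per ROI and honors CV grids", {
  set.seed(7)
  x <- matrix(rnorm(80), 40, 2)
  ph <- phenotype_matrix(matrix(c(x %*% c(1, 1) + 20,
                                  x %*% c(-1, 2) + 30,
                                  x[, 1]^2 + 10), 40, 3,
                                dimnames = list(paste0("s", 1:40),
                                                c("rA", "rB", "rC"))))
  models <- fit_all_rois(x, ph, kernel = "rbf")
  expect_named(models, c("rA", "rB", "rC"))
  # q = 1 reduces to a single fit_svr
  m1 <- fit_all_rois(x, ph[, 1, drop = FALSE], kernel = "rbf")
  expect_equal(predict_svr(m1[[1]], x),
               predict_svr(fit_svr(x, unclass(ph)[, 1], kernel = "rbf"), x))
  # CV grid selection agrees with an exhaustive refit comparison
  grid <- list(C = c(0.5, 50), eps_tube = c(0.01, 0.5))
  y <- unclass(ph)[, 3]
  sel <- fit_all_rois(x, ph[, 3, drop = FALSE], kernel = "rbf",
                      cv_grid = grid, folds = 3, seed = 11)[[1]]
  fold_of <- snproi:::make_folds(40, 3, 11)
  best <- NULL; best_rmse <- Inf
  for (C in grid$C) for (eps in grid$eps_tube) {
    se <- 0
    for (f in 1:3) {
      tr <- fold_of != f
      mm <- fit_svr(x[tr, , drop = FALSE], y[tr], "rbf", C = C, eps_tube = eps)
      se <- se + sum((predict_svr(mm, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }
    if (sqrt(se / 40) < best_rmse) { best_rmse <- sqrt(se / 40); best <- c(C, eps) }
  }
  expect_equal(c(sel$C, sel$eps_tube), best)
})
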