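# Stage 3: epsilon-insensitive support vector regression per ROI.
#
# The predictor has the dual form f(x) = sum_i beta_i K(x_i, x) + b with
# beta_i = alpha_i* - alpha_i the dual coefficients of the support vectors,
# subject to sum_i beta_i = 0 and |beta_i| <= C. The dual quadratic program
# is solved by libsvm (via e1071); the model object stores the dual solution
# explicitly so predictions can be formed (and checked) from the kernel
# expansion itself.

kernel_spec <- function(kernel, k, x_var, degree, coef0, gamma) {
  kernel <- match.arg(kernel, c("linear", "polynomial", "rbf"))
  if (is.null(gamma)) gamma <- 1 / (k * max(x_var, .Machine$double.eps))
  list(kernel = kernel, degree = degree, coef0 = coef0, gamma = gamma)
}

kernel_matrix <- function(spec, A, B) {
  # A: m x k, B: l x k -> m x l Gram matrix
  switch(spec$kernel,
    linear = tcrossprod(A, B),
    polynomial = (spec$gamma * tcrossprod(A, B) + spec$coef0)^spec$degree,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
      exp(-spec$gamma * pmax(d2, 0))
    })
}

#' Fit epsilon-insensitive support vector regression
#'
#' Features are standardized inside the stage (the scale record is stored in
#' the model and re-applied at prediction time), then the SVR dual is solved.
#' A constant response cannot support a regression; the model then predicts
#' `mean(y)` with a warning.
#'
#' @param X_sel numeric matrix, samples x k selected feature SNPs.
#' @param y numeric response vector (one ROI).
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param C box constraint (> 0). The default `NULL` uses the
#'   response-scaled heuristic of Cherkassky & Ma (2004),
#'   \eqn{C = \max(|\bar y + 3\sigma_y|, |\bar y - 3\sigma_y|)}: the box
#'   constraint must live on the scale of the response, and ROI phenotypes
#'   (volumes, thicknesses) are far from unit scale.
#' @param eps_tube half-width of the insensitive tube (>= 0).
#' @param gamma kernel coefficient for rbf/polynomial; default
#'   `1 / (k * Var(X_sel))` computed on the standardized features.
#' @param degree,coef0 polynomial kernel parameters.
#' @return An object of class `svr_model` holding the kernel spec, support
#'   vectors, dual coefficients `beta`, bias `b`, the feature scale record
#'   and the hyperparameters.
#' @export
fit_svr <- function(X_sel, y, kernel = "rbf", C = NULL, eps_tube = 0.1,
                    gamma = NULL, degree = 3, coef0 = 0) {
  X_sel <- as.matrix(X_sel)
  if (nrow(X_sel) < 2L) stop("need at least 2 samples to fit SVR")
  if (length(y) != nrow(X_sel)) stop("length(y) must match nrow(X_sel)")
  if (is.null(C)) C <- max(abs(mean(y) + 3 * stats::sd(y)),
                           abs(mean(y) - 3 * stats::sd(y)), 1)
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  if (!is.numeric(eps_tube) || eps_tube < 0) stop("eps_tube must be >= 0")
  center <- colMeans(X_sel)
  scl <- apply(X_sel, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X_sel, 2L, center), 2L, scl, `/`)
  spec <- kernel_spec(kernel, ncol(Xs), stats::var(as.vector(Xs)), degree, coef0, gamma)
  scale_rec <- list(center = center, scale = scl)

  if (stats::sd(y) == 0) {
    warning("constant response; SVR degenerates to predicting mean(y)")
    return(structure(list(spec = spec, sv = Xs[0, , drop = FALSE],
                          beta = numeric(0), b = mean(y), scale = scale_rec,
                          C = C, eps_tube = eps_tube, fitted = rep(mean(y), length(y)),
                          n_features = ncol(X_sel)),
                     class = "svr_model"))
  }
  m <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                  kernel = switch(spec$kernel, linear = "linear",
                                  polynomial = "polynomial", rbf = "radial"),
                  cost = C, epsilon = eps_tube, gamma = spec$gamma,
                  degree = spec$degree, coef0 = spec$coef0, scale = FALSE)
  model <- structure(list(spec = spec,
                          sv = Xs[m$index, , drop = FALSE],
                          beta = as.numeric(m$coefs),
                          b = -m$rho, scale = scale_rec,
                          C = C, eps_tube = eps_tube,
                          n_features = ncol(X_sel)),
                     class = "svr_model")
  model$fitted <- predict_svr(model, X_sel)
  model
}

#' Predict from a fitted SVR model
#'
#' Evaluates the kernel expansion
#' \eqn{f(x) = \sum_i \beta_i K(x_i, x) + b} over the stored support
#' vectors, after applying the training-time feature scaling.
#'
#' @param m an `svr_model` from [fit_svr()].
#' @param X_new numeric matrix, samples x k (same features as training).
#' @return Numeric vector of predictions.
#' @export
predict_svr <- function(m, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != m$n_features)
    stop(sprintf("expected %d features, got %d", m$n_features, ncol(X_new)))
  Xs <- sweep(sweep(X_new, 2L, m$scale$center), 2L, m$scale$scale, `/`)
  if (length(m$beta) == 0L) return(rep(m$b, nrow(Xs)))
  as.numeric(kernel_matrix(m$spec, Xs, m$sv) %*% m$beta + m$b)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("svr_model: %s kernel, %d support vectors, C=%g, eps=%g\n",
              x$spec$kernel, length(x$beta), x$C, x$eps_tube))
  invisible(x)
}

#' Fit one SVR per ROI
#'
#' @param X_sel samples x k matrix of selected feature SNPs.
#' @param ph a [phenotype_matrix()] (samples x ROIs).
#' @param kernel,C,eps_tube,gamma,degree,coef0 shared hyperparameters, as in
#'   [fit_svr()].
#' @param cv_grid optional named list with candidate vectors `C` and/or
#'   `eps_tube`; when given, each ROI picks its own pair by `folds`-fold
#'   cross-validated RMSE on the training data.
#' @param folds CV folds used with `cv_grid`.
#' @param seed seed controlling the CV fold assignment.
#' @return Named list of `svr_model`s, one per ROI column.
#' @export
fit_all_rois <- function(X_sel, ph, kernel = "rbf", C = NULL, eps_tube = 0.1,
                         gamma = NULL, degree = 3, coef0 = 0,
                         cv_grid = NULL, folds = 5L, seed = 1L) {
  ph <- as.matrix(ph)
  models <- vector("list", ncol(ph))
  names(models) <- colnames(ph)
  for (j in seq_len(ncol(ph))) {
    y <- ph[, j]
    Cj <- C; ej <- eps_tube
    if (!is.null(cv_grid)) {
      best <- svr_cv_select(X_sel, y, kernel,
                            C_grid = cv_grid$C %||% C %||% 1,
                            eps_grid = cv_grid$eps_tube %||% eps_tube,
                            gamma = gamma, degree = degree, coef0 = coef0,
                            folds = folds, seed = seed)
      Cj <- best$C; ej <- best$eps_tube
    }
    models[[j]] <- fit_svr(X_sel, y, kernel, C = Cj, eps_tube = ej,
                           gamma = gamma, degree = degree, coef0 = coef0)
  }
  models
}

`%||%` <- function(a, b) if (is.null(a)) b else a

svr_cv_select <- function(X_sel, y, kernel, C_grid, eps_grid, gamma, degree,
                          coef0, folds, seed) {
  n <- nrow(X_sel)
  fold_of <- make_folds(n, folds, seed)
  best <- list(C = C_grid[1L], eps_tube = eps_grid[1L], rmse = Inf)
  for (C in C_grid) for (eps in eps_grid) {
    se <- 0
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      m <- fit_svr(X_sel[tr, , drop = FALSE], y[tr], kernel, C = C,
                   eps_tube = eps, gamma = gamma, degree = degree, coef0 = coef0)
      pr <- predict_svr(m, X_sel[!tr, , drop = FALSE])
      se <- se + sum((pr - y[!tr])^2)
    }
    rmse <- sqrt(se / n)
    if (rmse < best$rmse) best <- list(C = C, eps_tube = eps, rmse = rmse)
  }
  best
}

# Seeded, balanced fold assignment; isolated from the global RNG stream.
make_folds <- function(n, folds, seed) {
  stopifnot(folds >= 2L, n >= folds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}
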