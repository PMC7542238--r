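# Stage 2: group-sparse multi-task regression.
#
# The model couples a G2,1 penalty (sum over SNP groups of the Frobenius
# norms of the group's weight rows) with an l2,1 penalty (sum over SNP rows
# of their l2 norms):
#
#   min_W ||W'X - Y||_F^2 + gamma1 * sum_k ||W_k||_F + gamma2 * sum_i ||w^i||_2
#
# with X (d x n) holding one subject per column and Y (c x n) the ROI
# responses. Setting the gradient to zero gives the stationarity condition
#   (XX' + gamma1 D + gamma2 Dt) W = XY'
# where D is block diagonal with k-th block 1/(2||W_k||_F) I and Dt is
# diagonal with i-th entry 1/(2||w^i||_2). Iterating the linear solve with
# reweighting is an iteratively-reweighted-least-squares scheme; with norms
# floored at eps it is an exact majorize-minimize iteration for the
# Huber-smoothed penalty, so the smoothed objective decreases monotonically.

#' Assemble a standardized design pair for multi-task regression
#'
#' Transposes the sample-major genotype/phenotype matrices into the
#' feature-major layout the solver uses (X: SNPs x samples, Y: ROIs x
#' samples) and optionally standardizes: each SNP row centered and scaled to
#' unit variance (constant SNPs are centered only), each ROI row centered.
#' The centering/scaling record is kept so predictions can be mapped back to
#' the original phenotype scale.
#'
#' @param g a [genotype_matrix()] (or plain numeric samples x SNPs matrix).
#' @param ph a [phenotype_matrix()] (or plain numeric samples x ROIs matrix).
#' @param standardize logical; default `TRUE`.
#' @return An object of class `design_pair`: list with `X` (d x n), `Y`
#'   (c x n), `snp_ids`, `roi_ids`, and the `center`/`scale` records.
#' @export
design_pair <- function(g, ph, standardize = TRUE) {
  Xs <- t(as.matrix(g))   # d x n
  Ys <- t(as.matrix(ph))  # c x n
  if (ncol(Xs) != ncol(Ys)) stop("genotypes and phenotypes have different sample counts")
  if (anyNA(Xs) || anyNA(Ys)) stop("design pair contains NA values")
  x_center <- rowMeans(Xs); x_scale <- rep(1, nrow(Xs))
  y_center <- rowMeans(Ys)
  if (standardize) {
    Xs <- Xs - x_center
    sds <- sqrt(rowSums(Xs^2) / (ncol(Xs) - 1L))
    x_scale <- ifelse(sds > 0, sds, 1)
    Xs <- Xs / x_scale
    Ys <- Ys - y_center
  } else {
    x_center <- rep(0, nrow(Xs)); y_center <- rep(0, nrow(Ys))
  }
  structure(list(X = Xs, Y = Ys,
                 snp_ids = rownames(Xs), roi_ids = rownames(Ys),
                 x_center = x_center, x_scale = x_scale, y_center = y_center,
                 standardized = standardize),
            class = "design_pair")
}

#' @export
print.design_pair <- function(x, ...) {
  cat(sprintf("design_pair: d=%d SNPs, n=%d samples, c=%d ROIs (%s)\n",
              nrow(x$X), ncol(x$X), nrow(x$Y),
              if (x$standardized) "standardized" else "raw"))
  invisible(x)
}

group_norms <- function(W, groups) {
  K <- attr(groups, "K")
  gn <- numeric(K)
  for (k in seq_len(K)) {
    rows <- which(groups == k)
    gn[k] <- sqrt(sum(W[rows, , drop = FALSE]^2))
  }
  gn
}

row_norms <- function(W) sqrt(rowSums(W^2))

#' Group-sparse multi-task objective
#'
#' The penalised least-squares objective
#' \eqn{\|W^\top X - Y\|_F^2 + \gamma_1 \sum_k \|W_k\|_F +
#'      \gamma_2 \sum_i \|w^i\|_2}.
#'
#' @param W weight matrix, d x c.
#' @param dp a [design_pair()].
#' @param groups a [snp_groups()] partition of the d SNPs.
#' @param gamma1 group-level (G2,1) penalty weight, >= 0.
#' @param gamma2 row-level (l2,1) penalty weight, >= 0.
#' @return The objective value.
#' @export
gsmurfs_objective <- function(W, dp, groups, gamma1, gamma2) {
  if (nrow(W) != nrow(dp$X) || ncol(W) != nrow(dp$Y))
    stop(sprintf("W must be %d x %d, got %d x %d",
                 nrow(dp$X), nrow(dp$Y), nrow(W), ncol(W)))
  if (length(groups) != nrow(W)) stop("groups length must match nrow(W)")
  resid <- crossprod(W, dp$X) - dp$Y
  sum(resid^2) + gamma1 * sum(group_norms(W, groups)) + gamma2 * sum(row_norms(W))
}

# Huber smoothing of t -> t used by the monotonicity guarantee: linear above
# eps, quadratic below.
huber_norm <- function(t, eps) ifelse(t >= eps, t, (t^2 + eps^2) / (2 * eps))

smoothed_objective <- function(W, dp, groups, gamma1, gamma2, eps) {
  resid <- crossprod(W, dp$X) - dp$Y
  sum(resid^2) +
    gamma1 * sum(huber_norm(group_norms(W, groups), eps)) +
    gamma2 * sum(huber_norm(row_norms(W), eps))
}

#' Ridge multi-task regression (closed form)
#'
#' Minimises \eqn{\sum_i \|W^\top x_i - y_i\|^2 + \gamma \sum_i \|w_i\|^2},
#' solved in closed form as \eqn{W = (XX^\top + \gamma I)^{-1} X Y^\top}.
#'
#' @param dp a [design_pair()].
#' @param gamma ridge penalty, >= 0; with `gamma = 0` the Gram matrix
#'   \eqn{XX^\top} must be nonsingular (requires n >= d in practice).
#' @return Weight matrix W, d x c, with SNP/ROI dimnames.
#' @export
fit_ridge <- function(dp, gamma = 1) {
  if (gamma < 0) stop("gamma must be >= 0")
  d <- nrow(dp$X)
  M <- tcrossprod(dp$X) + diag(gamma, d)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("XX' + gamma I is singular; use gamma > 0 (e.g. when p >= n)")
  W <- chol2inv(ch) %*% tcrossprod(dp$X, dp$Y)
  dimnames(W) <- list(dp$snp_ids, dp$roi_ids)
  W
}

#' Fit the group-sparse multi-task regression model by IRLS
#'
#' Alternates (i) the linear solve
#' \eqn{(XX^\top + \gamma_1 D + \gamma_2 \tilde D) W = X Y^\top} with
#' (ii) reweighting: the rows of group k get D-entry
#' \eqn{1 / (2 \max(\|W_k\|_F, \epsilon))} and row i gets the diagonal
#' \eqn{\tilde D_{ii} = 1 / (2 \max(\|w^i\|_2, \epsilon))}. D and
#' \eqn{\tilde D} start as identity matrices, so the first iterate is a
#' ridge solution with penalty \eqn{(\gamma_1 + \gamma_2) I}. Iteration
#' stops when the relative change of the smoothed objective falls below
#' `tol` or after `max_iter` sweeps.
#'
#' @param dp a [design_pair()].
#' @param groups a [snp_groups()] partition of the SNPs.
#' @param gamma1,gamma2 penalty weights (>= 0). Default `NULL` picks the
#'   scale-aware heuristic \eqn{0.05 \max_i \|(XY^\top)^i\|_2}.
#' @param tol convergence tolerance on the relative stationarity residual
#'   \eqn{\|XX^\top W - XY^\top + \gamma_1 D W + \gamma_2 \tilde D W\|_F /
#'   \|XY^\top\|_F}, the natural optimality measure of the zero-gradient
#'   condition the solver targets. Iteration stops when it drops below
#'   `tol`.
#' @param max_iter maximum IRLS sweeps.
#' @param epsilon_smooth floor applied to block/row norms in the
#'   reweighting; keeps the linear systems well posed when norms shrink to
#'   zero.
#' @return An object of class `gsmurfs_fit`: list with `W` (d x c),
#'   `objective_trace` (smoothed objective per iterate, non-increasing),
#'   `objective` (exact final objective), `n_iter`, `converged`,
#'   `stationarity` (relative residual of the optimality condition), and the
#'   hyperparameters.
#' @export
fit_gsmurfs <- function(dp, groups, gamma1 = NULL, gamma2 = NULL,
                        tol = 1e-6, max_iter = 10000L, epsilon_smooth = 1e-8) {
  d <- nrow(dp$X); cc <- nrow(dp$Y)
  if (length(groups) != d) stop("groups length must match the number of SNPs")
  XXt <- tcrossprod(dp$X)
  XYt <- tcrossprod(dp$X, dp$Y)
  if (is.null(gamma1) || is.null(gamma2)) {
    lam <- default_gamma(XYt)
    if (is.null(gamma1)) gamma1 <- lam
    if (is.null(gamma2)) gamma2 <- lam
  }
  if (gamma1 < 0 || gamma2 < 0) stop("gamma1 and gamma2 must be >= 0")
  group_of <- as.integer(groups)

  d_diag <- rep(1, d)   # D initialised to identity
  dt_diag <- rep(1, d)  # Dt initialised to identity
  trace <- numeric(0)
  converged <- FALSE
  W <- NULL
  xyt_norm <- max(sqrt(sum(XYt^2)), .Machine$double.eps)
  stationarity <- Inf
  for (it in seq_len(max_iter)) {
    M <- XXt
    diag(M) <- diag(M) + gamma1 * d_diag + gamma2 * dt_diag
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) stop(sprintf("IRLS linear system not positive definite at iteration %d", it))
    rc <- rcond_chol(ch)
    if (rc < 1e-12)
      warning(sprintf("IRLS system ill-conditioned at iteration %d (rcond ~ %.1e)", it, rc))
    W <- backsolve(ch, forwardsolve(t(ch), XYt))
    if (!all(is.finite(W)))
      stop(sprintf("solver diverged: non-finite weights at iteration %d", it))
    obj <- smoothed_objective(W, dp, groups, gamma1, gamma2, epsilon_smooth)
    if (!is.finite(obj))
      stop(sprintf("solver diverged: non-finite objective at iteration %d", it))
    trace <- c(trace, obj)
    gn <- pmax(group_norms(W, groups), epsilon_smooth)
    rn <- pmax(row_norms(W), epsilon_smooth)
    d_diag <- 1 / (2 * gn[group_of])
    dt_diag <- 1 / (2 * rn)
    grad <- XXt %*% W - XYt + gamma1 * (d_diag * W) + gamma2 * (dt_diag * W)
    stationarity <- sqrt(sum(grad^2)) / xyt_norm
    if (stationarity < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(W) <- list(dp$snp_ids, dp$roi_ids)
  structure(list(W = W, objective_trace = trace,
                 objective = gsmurfs_objective(W, dp, groups, gamma1, gamma2),
                 n_iter = length(trace), converged = converged,
                 stationarity = stationarity,
                 gamma1 = gamma1, gamma2 = gamma2,
                 epsilon_smooth = epsilon_smooth),
            class = "gsmurfs_fit")
}

# Scale-aware default penalty: a fixed fraction of the largest row norm of
# the SNP-response cross-products, so the same setting behaves comparably
# across sample sizes and phenotype scales.
default_gamma <- function(XYt) 0.05 * max(sqrt(rowSums(XYt^2)))

# Reciprocal condition estimate from a Cholesky factor (ratio of squared
# extreme diagonal entries bounds the condition of the factorization).
rcond_chol <- function(ch) (min(diag(ch)) / max(diag(ch)))^2

#' @export
print.gsmurfs_fit <- function(x, ...) {
  cat(sprintf("gsmurfs_fit: %d x %d weights, %d IRLS iterations (%s), objective %.6g\n",
              nrow(x$W), ncol(x$W), x$n_iter,
              if (x$converged) "converged" else "max_iter reached", x$objective))
  invisible(x)
}

#' SNP importance scores from a weight matrix
#'
#' A SNP's importance is the l2 norm of its weight-matrix row, i.e. the
#' joint effect size across all ROIs.
#'
#' @param W weight matrix (d x c) or a `gsmurfs_fit`.
#' @return Numeric vector of length d, named by SNP when W has row names.
#' @export
snp_importance <- function(W) {
  if (inherits(W, "gsmurfs_fit")) W <- W$W
  stats::setNames(row_norms(as.matrix(W)), rownames(W))
}

#' Select the top-k SNPs by importance
#'
#' @param scores numeric importance vector (from [snp_importance()]).
#' @param k number of SNPs to select, 1..length(scores).
#' @return Integer indices of the k largest scores, sorted by descending
#'   score; ties broken towards the smaller original index.
#' @export
select_top_k <- function(scores, k) {
  d <- length(scores)
  if (k < 1L || k > d) stop(sprintf("k must be in 1..%d, got %s", d, k))
  ord <- order(-scores, seq_len(d))
  ord[seq_len(k)]
}
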