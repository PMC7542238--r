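# End-to-end orchestration of the three stages and the multi-method
# comparison. All methods are evaluated on identical seeded sample-level
# cross-validation folds; metrics come from held-out predictions only.

#' Pipeline configuration
#'
#' Collects every stage parameter. Serializable to JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param distance,minkowski_r,linkage stage-1 dissimilarity and linkage;
#'   defaults are the screen's best combination (Minkowski r = 0.23, single
#'   linkage).
#' @param n_clusters clusters kept by the redundancy filter; `NULL` means
#'   half the SNPs (rounded up).
#' @param group_mode `"ld"` or `"gene"` grouping for the sparse stage.
#' @param r2_threshold LD edge threshold for `group_mode = "ld"`.
#' @param gamma1,gamma2 group-sparse penalties; `NULL` uses the scale-aware
#'   default in [fit_gsmurfs()].
#' @param ridge_gamma penalty of the ridge baseline and refits.
#' @param top_k number of feature SNPs passed to the SVR stage.
#' @param kernel,svr_c,svr_eps,svr_gamma SVR stage settings.
#' @param cv_folds sample-level cross-validation folds.
#' @param seed seed controlling folds (and anything stochastic downstream).
#' @param out_dir optional run directory; when set, [run_three_stage()]
#'   writes selected_snps.tsv, weights.tsv, metrics.tsv/.json,
#'   dendrogram.nwk and a config snapshot there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(distance = "minkowski", minkowski_r = 0.23,
                            linkage = "single", n_clusters = NULL,
                            group_mode = "ld", r2_threshold = 0.2,
                            gamma1 = NULL, gamma2 = NULL, ridge_gamma = 1,
                            top_k = 100L, kernel = "rbf", svr_c = NULL,
                            svr_eps = 0.1, svr_gamma = NULL,
                            cv_folds = 5L, seed = 1L, out_dir = NULL) {
  structure(list(distance = distance, minkowski_r = minkowski_r,
                 linkage = linkage, n_clusters = n_clusters,
                 group_mode = group_mode, r2_threshold = r2_threshold,
                 gamma1 = gamma1, gamma2 = gamma2, ridge_gamma = ridge_gamma,
                 top_k = as.integer(top_k), kernel = kernel, svr_c = svr_c,
                 svr_eps = svr_eps, svr_gamma = svr_gamma,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration as JSON
#' @param cfg a [pipeline_config()].
#' @param path output file.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals[!vapply(vals, is.null, TRUE)])
}

# --- internal stage helpers -------------------------------------------------

stage1_filter <- function(g, cfg) {
  d <- suppressWarnings(snp_distance(g, cfg$distance, r = cfg$minkowski_r))
  tree <- hierarchical_cluster(d, cfg$linkage)
  nc <- cfg$n_clusters %||% ceiling(ncol(g) / 2)
  list(filtered = filter_redundant(g, tree, d, n_clusters = nc), tree = tree)
}

stage2_fit <- function(g_filt, ph, cfg) {
  groups <- build_groups(g_filt, mode = cfg$group_mode,
                         threshold = cfg$r2_threshold)
  dp <- design_pair(g_filt, ph)
  fit <- fit_gsmurfs(dp, groups, gamma1 = cfg$gamma1, gamma2 = cfg$gamma2)
  list(fit = fit, groups = groups, dp = dp)
}

# Linear prediction on the original phenotype scale from a standardized fit.
predict_linear <- function(dp, W, g_new) {
  Xn <- (t(as.matrix(g_new)) - dp$x_center) / dp$x_scale
  t(crossprod(W, Xn) + dp$y_center)
}

ols_weights <- function(dp) {
  # least-norm least squares; pseudoinverse covers p > n
  W <- MASS::ginv(tcrossprod(dp$X)) %*% tcrossprod(dp$X, dp$Y)
  dimnames(W) <- list(dp$snp_ids, dp$roi_ids)
  W
}

#' Run the three-stage pipeline with cross-validated evaluation
#'
#' Within each training fold: stage 1 (dissimilarity, clustering, redundancy
#' filter), stage 2 (group construction and group-sparse fit, importance
#' ranking, top-k selection), stage 3 (one SVR per ROI on the selected
#' SNPs). Held-out samples are predicted by the fold's models; the metrics
#' report is computed on the assembled held-out predictions. A final fit on
#' all samples provides the reported selected SNP set, weights and models.
#'
#' @param g a [genotype_matrix()].
#' @param ph a [phenotype_matrix()] over the same samples.
#' @param cfg a [pipeline_config()].
#' @return A `three_stage_result`: list with `selected_snps`, `models`
#'   (per-ROI `svr_model`s from the full-data fit), `metrics`
#'   (held-out [evaluate()] report), `importance`, `weights`, `groups`,
#'   `predictions` (held-out, samples x ROIs), and `config`.
#' @export
run_three_stage <- function(g, ph, cfg = pipeline_config()) {
  if (!identical(rownames(g), rownames(ph)))
    stop("genotypes and phenotypes must be sample-aligned (see align_samples)")
  n <- nrow(g)
  fold_of <- make_folds(n, cfg$cv_folds, cfg$seed)
  pred <- matrix(NA_real_, n, ncol(ph), dimnames = dimnames(ph))
  for (f in seq_len(cfg$cv_folds)) {
    tr <- fold_of != f
    g_tr <- genotype_matrix(unclass_matrix(g)[tr, , drop = FALSE],
                            gene_of = attr(g, "gene_of"))
    ph_tr <- phenotype_matrix(unclass_matrix(ph)[tr, , drop = FALSE])
    st <- fit_three_stage_once(g_tr, ph_tr, cfg)
    g_te <- unclass_matrix(g)[!tr, st$selected_snps, drop = FALSE]
    for (j in seq_along(st$models))
      pred[!tr, j] <- predict_svr(st$models[[j]], g_te)
  }
  metrics <- evaluate(pred, ph, n_features_used = cfg$top_k)
  full <- fit_three_stage_once(g, ph, cfg)
  res <- structure(list(selected_snps = full$selected_snps,
                        models = full$models, metrics = metrics,
                        importance = full$importance, weights = full$weights,
                        groups = full$groups, tree = full$tree,
                        predictions = pred, fold_of = fold_of, config = cfg),
                   class = "three_stage_result")
  if (!is.null(cfg$out_dir)) write_run_artifacts(res, g, cfg)
  res
}

# One training pass of the three stages; no held-out evaluation.
fit_three_stage_once <- function(g, ph, cfg) {
  s1 <- stage1_filter(g, cfg)
  s2 <- stage2_fit(s1$filtered, ph, cfg)
  imp <- snp_importance(s2$fit)
  if (cfg$top_k > length(imp))
    stop(sprintf("top_k = %d exceeds the %d SNPs surviving the filter",
                 cfg$top_k, length(imp)))
  sel <- select_top_k(imp, cfg$top_k)
  sel_ids <- names(imp)[sel]
  X_sel <- unclass_matrix(g)[, sel_ids, drop = FALSE]
  models <- fit_all_rois(X_sel, ph, kernel = cfg$kernel, C = cfg$svr_c,
                         eps_tube = cfg$svr_eps, gamma = cfg$svr_gamma,
                         seed = cfg$seed)
  list(selected_snps = sel_ids, models = models, importance = imp,
       weights = s2$fit$W, groups = s2$groups, tree = s1$tree)
}

write_run_artifacts <- function(res, g, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  utils::write.table(data.frame(snp_id = res$selected_snps,
                                importance = res$importance[res$selected_snps]),
                     p("selected_snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_weights(res$weights, p("weights.tsv"))
  write_metrics(res$metrics, p("metrics.tsv"))
  write_metrics(res$metrics, p("metrics.json"))
  write_newick(res$tree, p("dendrogram.nwk"))
  write_pipeline_config(cfg, p("config.json"))
  invisible(cfg$out_dir)
}

#' @export
print.three_stage_result <- function(x, ...) {
  cat(sprintf("three_stage_result: %d feature SNPs, held-out aggregate RMSE %.4g, R2 %.4g\n",
              length(x$selected_snps), x$metrics$aggregate["RMSE"],
              x$metrics$aggregate["R2"]))
  invisible(x)
}

#' Compare regression methods on identical cross-validation folds
#'
#' Evaluates, for every `k` in `k_list`, the held-out performance of:
#' \itemize{
#'   \item `linear_regression` — per-ROI ordinary least squares refit on the
#'     top-k SNPs ranked by the OLS row norms (pseudoinverse when p > n);
#'   \item `ridge` — multi-task ridge refit on its own top-k ranking;
#'   \item `gsmurfs_linear` — the group-sparse fit used directly as a linear
#'     predictor restricted to its top-k rows (no refit, no SVR);
#'   \item `three_stage_gene` / `three_stage_cluster` — the full pipeline
#'     with gene-based or LD-based grouping, SVR readout.
#' }
#' Every method sees the same seeded fold assignment, so differences are
#' attributable to the methods alone.
#'
#' @param g a [genotype_matrix()] (gene annotations required for
#'   `three_stage_gene`).
#' @param ph an aligned [phenotype_matrix()].
#' @param cfg a [pipeline_config()].
#' @param k_list integer vector of feature-set sizes.
#' @param methods subset of the five method names to run.
#' @return A `comparison_result`: list with `table` (long data frame:
#'   method, k, the six aggregate metrics, folds, seed), `per_roi` (named
#'   list of per-ROI metric matrices keyed `"method@k"`), and `fold_of`.
#' @export
compare_methods <- function(g, ph, cfg = pipeline_config(),
                            k_list = c(20L, 40L, 60L, 80L, 100L),
                            methods = c("linear_regression", "ridge",
                                        "gsmurfs_linear", "three_stage_gene",
                                        "three_stage_cluster")) {
  methods <- match.arg(methods, several.ok = TRUE)
  n <- nrow(g); q <- ncol(ph)
  fold_of <- make_folds(n, cfg$cv_folds, cfg$seed)
  preds <- list()
  blank <- function() matrix(NA_real_, n, q, dimnames = dimnames(ph))
  for (m in methods) for (k in k_list) preds[[key_mk(m, k)]] <- blank()

  for (f in seq_len(cfg$cv_folds)) {
    tr <- fold_of != f
    g_tr <- genotype_matrix(unclass_matrix(g)[tr, , drop = FALSE],
                            gene_of = attr(g, "gene_of"))
    ph_tr <- phenotype_matrix(unclass_matrix(ph)[tr, , drop = FALSE])
    g_te_raw <- unclass_matrix(g)[!tr, , drop = FALSE]
    dp_tr <- design_pair(g_tr, ph_tr)

    if ("linear_regression" %in% methods) {
      W_ols <- ols_weights(dp_tr)
      rank_ols <- snp_importance(W_ols)
      for (k in k_list) {
        ids <- names(rank_ols)[select_top_k(rank_ols, k)]
        dp_k <- design_pair(unclass_matrix(g_tr)[, ids, drop = FALSE], ph_tr)
        preds[[key_mk("linear_regression", k)]][!tr, ] <-
          predict_linear(dp_k, ols_weights(dp_k), g_te_raw[, ids, drop = FALSE])
      }
    }
    if ("ridge" %in% methods) {
      W_r <- fit_ridge(dp_tr, cfg$ridge_gamma)
      rank_r <- snp_importance(W_r)
      for (k in k_list) {
        ids <- names(rank_r)[select_top_k(rank_r, k)]
        dp_k <- design_pair(unclass_matrix(g_tr)[, ids, drop = FALSE], ph_tr)
        preds[[key_mk("ridge", k)]][!tr, ] <-
          predict_linear(dp_k, fit_ridge(dp_k, cfg$ridge_gamma),
                         g_te_raw[, ids, drop = FALSE])
      }
    }
    if ("gsmurfs_linear" %in% methods) {
      groups <- build_groups(g_tr, mode = cfg$group_mode,
                             threshold = cfg$r2_threshold)
      fit <- fit_gsmurfs(dp_tr, groups, gamma1 = cfg$gamma1, gamma2 = cfg$gamma2)
      rank_g <- snp_importance(fit)
      for (k in k_list) {
        sel <- select_top_k(rank_g, k)
        Wk <- fit$W
        Wk[-sel, ] <- 0
        preds[[key_mk("gsmurfs_linear", k)]][!tr, ] <-
          predict_linear(dp_tr, Wk, g_te_raw)
      }
    }
    for (variant in intersect(methods, c("three_stage_gene", "three_stage_cluster"))) {
      cfg_v <- cfg
      cfg_v$group_mode <- if (variant == "three_stage_gene") "gene" else "ld"
      s1 <- stage1_filter(g_tr, cfg_v)
      s2 <- stage2_fit(s1$filtered, ph_tr, cfg_v)
      imp <- snp_importance(s2$fit)
      for (k in k_list) {
        if (k > length(imp))
          stop(sprintf("k = %d exceeds the %d filtered SNPs", k, length(imp)))
        ids <- names(imp)[select_top_k(imp, k)]
        X_sel <- unclass_matrix(g_tr)[, ids, drop = FALSE]
        models <- fit_all_rois(X_sel, ph_tr, kernel = cfg_v$kernel,
                               C = cfg_v$svr_c, eps_tube = cfg_v$svr_eps,
                               gamma = cfg_v$svr_gamma, seed = cfg_v$seed)
        pm <- preds[[key_mk(variant, k)]]
        for (j in seq_along(models))
          pm[!tr, j] <- predict_svr(models[[j]], g_te_raw[, ids, drop = FALSE])
        preds[[key_mk(variant, k)]] <- pm
      }
    }
  }

  rows <- list(); per_roi <- list()
  for (m in methods) for (k in k_list) {
    rep <- evaluate(preds[[key_mk(m, k)]], ph, n_features_used = k)
    per_roi[[key_mk(m, k)]] <- rep$per_roi
    rows[[key_mk(m, k)]] <- data.frame(method = m, k = k,
                                       t(rep$aggregate),
                                       folds = cfg$cv_folds, seed = cfg$seed)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 per_roi = per_roi, fold_of = fold_of, config = cfg),
            class = "comparison_result")
}

key_mk <- function(m, k) sprintf("%s@%d", m, k)

#' @export
print.comparison_result <- function(x, ...) {
  cat("comparison_result:\n")
  print(x$table[, c("method", "k", "MAE", "RMSE", "R2")], digits = 4)
  invisible(x)
}
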