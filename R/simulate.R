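# Synthetic imaging-genetics data: block-LD genotypes, group-row-sparse
# true effects, and noisy linear or quadratic ROI phenotypes. The defaults
# mirror the scale of the motivating cohort: 632 samples, 486 SNPs, 56 ROIs.

#' Simulation configuration
#'
#' @param n_samples,p_snps,q_rois problem dimensions.
#' @param n_blocks number of LD blocks; SNPs are split evenly, any remainder
#'   joins the last block.
#' @param within_block_rho latent exchangeable correlation inside a block,
#'   in `[0, 1)`; between-block correlation is 0.
#' @param maf_range range the per-SNP minor allele frequency is drawn from,
#'   a sub-interval of `(0, 0.5]`.
#' @param n_active_groups number of LD blocks carrying true effects.
#' @param effect_scale standard deviation of the nonzero true weights.
#' @param snr per-ROI signal-to-noise ratio `Var(signal)/Var(noise)`.
#' @param link `"linear"` or `"quadratic"`; the quadratic link adds a
#'   centered elementwise-squared genotype term driven by the same active
#'   weights, giving the phenotype a component no additive linear model can
#'   capture.
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 632L, p_snps = 486L, q_rois = 56L,
                              n_blocks = 40L, within_block_rho = 0.7,
                              maf_range = c(0.05, 0.5), n_active_groups = 4L,
                              effect_scale = 1, snr = 5, link = "linear",
                              seed = 1L) {
  link <- match.arg(link, c("linear", "quadratic"))
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must be in [0, 1)")
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L])
    stop("maf_range must be an increasing interval inside (0, 0.5]")
  if (n_active_groups > n_blocks) stop("n_active_groups cannot exceed n_blocks")
  if (effect_scale <= 0) stop("effect_scale must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  if (p_snps < n_blocks) stop("need at least one SNP per block")
  structure(list(n_samples = as.integer(n_samples), p_snps = as.integer(p_snps),
                 q_rois = as.integer(q_rois), n_blocks = as.integer(n_blocks),
                 within_block_rho = within_block_rho, maf_range = maf_range,
                 n_active_groups = as.integer(n_active_groups),
                 effect_scale = effect_scale, snr = snr, link = link,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

block_assignment <- function(p, n_blocks) {
  size <- p %/% n_blocks
  a <- rep(seq_len(n_blocks), each = size)
  if (length(a) < p) a <- c(a, rep(n_blocks, p - length(a)))
  a
}

#' Simulate block-LD genotypes
#'
#' Each LD block draws a latent multivariate normal with exchangeable
#' correlation `within_block_rho` (one shared factor per block); blocks are
#' independent. Each latent coordinate is thresholded at the Hardy-Weinberg
#' quantiles of a per-SNP minor allele frequency drawn uniformly from
#' `maf_range`, yielding codes 0/1/2 with the expected genotype frequencies
#' \eqn{(1-m)^2, 2m(1-m), m^2}.
#'
#' @param cfg a [simulation_config()].
#' @return A [genotype_matrix()]; SNPs carry a pseudo-gene annotation
#'   (`GENE<k>` per block) so gene-mode grouping works on simulated data.
#' @export
simulate_genotypes <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$p_snps
    blocks <- block_assignment(p, cfg$n_blocks)
    rho <- cfg$within_block_rho
    mafs <- stats::runif(p, cfg$maf_range[1L], cfg$maf_range[2L])
    G <- matrix(0L, n, p)
    for (b in seq_len(cfg$n_blocks)) {
      cols <- which(blocks == b)
      shared <- stats::rnorm(n)
      Z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(cols)), n)
      for (jj in seq_along(cols)) {
        m <- mafs[cols[jj]]
        lo <- stats::qnorm((1 - m)^2)     # below: homozygous wild type
        hi <- stats::qnorm(1 - m^2)       # above: homozygous mutant
        G[, cols[jj]] <- (Z[, jj] >= lo) + (Z[, jj] > hi)
      }
    }
    snp_ids <- sprintf("snp%04d", seq_len(p))
    gene_of <- stats::setNames(sprintf("GENE%02d", blocks), snp_ids)
    g <- genotype_matrix(G, snp_ids = snp_ids,
                         sample_ids = sprintf("subj%04d", seq_len(n)),
                         gene_of = gene_of)
    attr(g, "maf") <- stats::setNames(mafs, snp_ids)
    attr(g, "blocks") <- stats::setNames(blocks, snp_ids)
    g
  })
}

#' Simulate a complete genotype/phenotype dataset with known truth
#'
#' Draws genotypes via [simulate_genotypes()], picks `n_active_groups` LD
#' blocks whose SNPs carry i.i.d. normal effects (scale `effect_scale`) on
#' every ROI, and builds phenotypes as
#' `baseline + signal + noise`, with per-ROI baselines ~ U(80, 120) (so all
#' phenotype values are positive, as ROI volumes and thicknesses are) and
#' per-ROI Gaussian noise scaled so that `Var(signal)/Var(noise) = snr`.
#' With `link = "quadratic"` the signal adds a centered squared-genotype
#' term with the same sparsity pattern.
#'
#' @param cfg a [simulation_config()].
#' @return A `synthetic_dataset` list: `genotypes`, `phenotypes`, `true_W`
#'   (p x q, rows outside active blocks exactly zero), `true_groups`
#'   ([snp_groups()] = the LD blocks), `active_groups`, `active_snps`,
#'   `noise_sd` (per ROI), `realized_snr` (per ROI), and `config`.
#' @export
simulate_dataset <- function(cfg) {
  g <- simulate_genotypes(cfg)
  with_seed(cfg$seed + 1000003L, {
    n <- cfg$n_samples; p <- cfg$p_snps; q <- cfg$q_rois
    blocks <- attr(g, "blocks")
    active <- sort(sample(cfg$n_blocks, cfg$n_active_groups))
    active_rows <- which(blocks %in% active)
    W <- matrix(0, p, q, dimnames = list(colnames(g), sprintf("roi%02d", seq_len(q))))
    W[active_rows, ] <- stats::rnorm(length(active_rows) * q, sd = cfg$effect_scale)
    Gs <- scale(unclass_matrix(g))
    Gs[, attr(Gs, "scaled:scale") == 0] <- 0
    signal <- Gs %*% W
    if (cfg$link == "quadratic") {
      Q <- scale(Gs^2)
      Q[!is.finite(Q)] <- 0
      signal <- signal + Q %*% W
    }
    sig_sd <- apply(signal, 2L, stats::sd)
    noise_sd <- sig_sd / sqrt(cfg$snr)
    noise <- matrix(stats::rnorm(n * q), n) * rep(noise_sd, each = n)
    baseline <- stats::runif(q, 80, 120)
    Y <- sweep(signal + noise, 2L, baseline, `+`)
    ph <- phenotype_matrix(Y, roi_ids = colnames(W), sample_ids = rownames(g))
    realized_snr <- apply(signal, 2L, stats::var) / apply(noise, 2L, stats::var)
    structure(list(genotypes = g, phenotypes = ph, true_W = W,
                   true_groups = snp_groups(blocks, snp_ids = colnames(g)),
                   active_groups = active,
                   active_snps = colnames(g)[active_rows],
                   noise_sd = noise_sd, realized_snr = realized_snr,
                   baseline = baseline, config = cfg),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic_dataset: n=%d, p=%d, q=%d, %d/%d active blocks, snr=%g, link=%s\n",
              cfg$n_samples, cfg$p_snps, cfg$q_rois,
              cfg$n_active_groups, cfg$n_blocks, cfg$snr, cfg$link))
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}
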