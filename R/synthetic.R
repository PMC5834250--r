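#' Condition specification for synthetic GEM generation
#'
#' @param name condition label.
#' @param n_samples number of samples carrying this label (>= 1).
#' @return a `condition_spec` list.
#' @export
condition_spec <- function(name, n_samples) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n_samples >= 1)
  structure(list(name = name, n_samples = as.integer(n_samples)),
            class = "condition_spec")
}

#' Planted condition-specific co-expression module
#'
#' Describes a block of genes that share a single latent factor within
#' the samples of one condition and are independent noise everywhere
#' else. With per-gene expression `a * z_s + e` (`z_s` the per-sample
#' latent factor, `e ~ N(0, noise_sd^2)`), the implied pairwise
#' correlation within the active condition is `a^2 / (a^2 + noise_sd^2)`.
#' Supplying `target_correlation` derives the loading `a` from the
#' generator's `noise_sd`; supplying `latent_loading` fixes `a` as a
#' multiple of `noise_sd` directly.
#'
#' @param gene_indices 1-based row indices of the module's genes;
#'   disjoint across planted modules.
#' @param active_condition label of the condition in which the module
#'   co-expresses.
#' @param target_correlation implied within-condition pairwise
#'   correlation, in (0,1).
#' @param latent_loading optional loading in (0,1) interpreted relative
#'   to a unit-noise model; overrides `target_correlation` when given.
#' @param active_shift additive log2-scale expression shift applied to
#'   the module's genes in active-condition samples (default 6). A
#'   condition-specific module is both co-expressed and strongly
#'   differentially expressed in its condition — near-silent elsewhere —
#'   and the shift is what lets the pairwise mixture model isolate the
#'   active samples as their own component instead of a cloud buried in
#'   the inactive blob.
#' @param module_noise_sd residual (non-shared) log2 noise of the
#'   module's genes within the active condition (default 0.45, tighter
#'   than the background noise): genes under strong common regulation
#'   scatter less about their shared factor, and the resulting compact
#'   active cluster keeps the module's dynamic range inside the span
#'   the background genes can rank-resolve under quantile
#'   normalization.
#' @return a `planted_module_spec` list.
#' @export
planted_module_spec <- function(gene_indices, active_condition,
                                target_correlation = 0.9,
                                latent_loading = NULL,
                                active_shift = 6,
                                module_noise_sd = 0.45) {
  stopifnot(length(gene_indices) >= 2L, all(gene_indices >= 1L),
            is.character(active_condition), length(active_condition) == 1L,
            module_noise_sd > 0)
  if (is.null(latent_loading)) {
    stopifnot(target_correlation > 0, target_correlation < 1)
  } else {
    stopifnot(latent_loading > 0, latent_loading < 1)
    target_correlation <- latent_loading^2 / (latent_loading^2 + 1)
  }
  structure(list(gene_indices = as.integer(gene_indices),
                 active_condition = active_condition,
                 target_correlation = target_correlation,
                 latent_loading = latent_loading,
                 active_shift = active_shift,
                 module_noise_sd = module_noise_sd),
            class = "planted_module_spec")
}

#' Parameters for multi-condition GEM simulation
#'
#' @param n_genes total number of genes.
#' @param conditions list of [condition_spec] objects; names unique.
#' @param planted list of [planted_module_spec] objects; gene index sets
#'   pairwise disjoint, active conditions drawn from `conditions`.
#' @param noise_sd standard deviation of the log2-scale noise (default 1).
#' @param baseline_log_mean centre of the per-gene baseline log2
#'   expression levels (default 5, a mid-range FPKM of ~32).
#' @param gene_baseline_sd spread of the per-gene baselines (default 3):
#'   real transcriptomes span orders of magnitude, and that spread is
#'   what gives quantile normalization the rank resolution to preserve
#'   between-gene correlation structure.
#' @param zero_fraction fraction of background entries set to exactly 0,
#'   emulating dropout (default 0.05).
#' @param seed integer seed; identical parameters give identical GEMs.
#' @return a `gem_sim_params` list.
#' @export
gem_sim_params <- function(n_genes, conditions, planted = list(),
                           noise_sd = 1, baseline_log_mean = 5,
                           gene_baseline_sd = 3,
                           zero_fraction = 0.05, seed = 1L) {
  stopifnot(n_genes >= 1, length(conditions) >= 1, noise_sd > 0,
            zero_fraction >= 0, zero_fraction < 1)
  cond_names <- vapply(conditions, `[[`, "", "name")
  if (anyDuplicated(cond_names)) stop("condition names must be unique")
  all_idx <- unlist(lapply(planted, `[[`, "gene_indices"))
  if (anyDuplicated(all_idx))
    stop("planted gene sets must be disjoint across modules")
  if (length(all_idx) && max(all_idx) > n_genes)
    stop("planted gene index exceeds n_genes")
  for (pm in planted)
    if (!pm$active_condition %in% cond_names)
      stop("unknown active_condition: ", pm$active_condition)
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 planted = planted, noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 gene_baseline_sd = gene_baseline_sd,
                 zero_fraction = zero_fraction, seed = as.integer(seed)),
            class = "gem_sim_params")
}

#' Generate a multi-condition GEM with planted condition-specific modules
#'
#' Expression is simulated directly on the log2 scale: gene `g` draws a
#' baseline level `b_g ~ N(baseline_log_mean, gene_baseline_sd^2)` and
#' background entries are `N(b_g, noise_sd^2)` noise; genes of a
#' planted module, within the samples of their active condition, follow
#' the single-latent-factor model `b_g + shift + a * z_s + e` so
#' that every within-module gene pair has the module's target
#' correlation. The returned raw GEM holds `2^x` of the simulated
#' values, so the pipeline's log2 step restores them exactly and the
#' generator's realism stays decoupled from normalization correctness.
#' A `zero_fraction` of background entries is set to exactly 0 (zeros
#' are never injected into planted-module entries, so the planted
#' correlations are undiluted).
#'
#' @param params a [gem_sim_params] object.
#' @return a raw-scale [gem].
#' @export
generate_multicondition_gem <- function(params) {
  stopifnot(inherits(params, "gem_sim_params"))
  set.seed(params$seed)
  cond_labels <- unlist(lapply(params$conditions, function(cs)
    rep(cs$name, cs$n_samples)))
  n <- params$n_genes
  m <- length(cond_labels)
  sample_id <- sprintf("S%04d", seq_len(m))
  baseline <- stats::rnorm(n, params$baseline_log_mean,
                           params$gene_baseline_sd)
  # planted genes are near-silent outside their condition: a low, tight
  # baseline keeps the inactive blob compact and the shifted active
  # cloud inside the background's dynamic range (so quantile
  # normalization retains rank resolution for it)
  for (pm in params$planted)
    baseline[pm$gene_indices] <-
      stats::rnorm(length(pm$gene_indices),
                   params$baseline_log_mean - 3, 0.5)
  vals <- baseline +
    matrix(stats::rnorm(n * m, 0, params$noise_sd),
           nrow = n, ncol = m,
           dimnames = list(sprintf("G%04d", seq_len(n)), sample_id))
  planted_mask <- matrix(FALSE, n, m)
  for (pm in params$planted) {
    cols <- which(cond_labels == pm$active_condition)
    rho <- pm$target_correlation
    a <- pm$module_noise_sd * sqrt(rho / (1 - rho))
    z <- stats::rnorm(length(cols))
    block <- outer(rep(a, length(pm$gene_indices)), z) +
      matrix(stats::rnorm(length(pm$gene_indices) * length(cols),
                          0, pm$module_noise_sd),
             nrow = length(pm$gene_indices))
    vals[pm$gene_indices, cols] <- baseline[pm$gene_indices] +
      pm$active_shift + block
    planted_mask[pm$gene_indices, cols] <- TRUE
  }
  vals <- 2^vals
  if (params$zero_fraction > 0) {
    bg <- which(!planted_mask)
    nz <- round(params$zero_fraction * length(bg))
    if (nz > 0) vals[sample(bg, nz)] <- 0
  }
  gem(vals, stats::setNames(cond_labels, sample_id), scale_tag = "raw")
}

#' Generate a structureless random GEM (RMT / enrichment null)
#'
#' i.i.d. Gaussian noise on the log2 scale with a single condition
#' label; no pair of genes carries planted correlation.
#'
#' @param n_genes,n_samples dimensions (both >= 2).
#' @param seed integer seed.
#' @param condition label applied to all samples (default "random").
#' @param baseline_log_mean,noise_sd noise model, as in
#'   [gem_sim_params].
#' @return a [gem].
#' @export
generate_random_gem <- function(n_genes, n_samples, seed = 1L,
                                condition = "random",
                                baseline_log_mean = 5, noise_sd = 1) {
  stopifnot(n_genes >= 2, n_samples >= 2)
  generate_multicondition_gem(gem_sim_params(
    n_genes = n_genes,
    conditions = list(condition_spec(condition, n_samples)),
    planted = list(), noise_sd = noise_sd,
    baseline_log_mean = baseline_log_mean,
    zero_fraction = 0, seed = seed))
}

#' Inject a distributional outlier sample into a GEM
#'
#' Shifts (and mildly rescales) one sample's expression profile so its
#' empirical distribution separates from the cohort; with a large
#' `shift` the sample's two-sample KS statistic against the pooled
#' remaining samples exceeds the 0.15 outlier cutoff.
#'
#' @param gem a [gem].
#' @param sample_index column index of the sample to perturb.
#' @param shift additive shift in expression units; 0 returns the GEM
#'   unchanged.
#' @return a modified copy of `gem`.
#' @export
inject_outlier_sample <- function(gem, sample_index, shift) {
  stopifnot(inherits(gem, "gem"),
            sample_index >= 1L, sample_index <= ncol(gem$values))
  if (shift == 0) return(gem)
  v <- gem$values
  col <- v[, sample_index]
  nz <- col > 0
  col[nz] <- col[nz] * 1.1 + shift
  col[col < 0] <- 0
  v[, sample_index] <- col
  gem(v, gem$condition, scale_tag = gem$scale_tag)
}

#' Generate a methylation beta-value matrix with one hypo-methylated
#' condition
#'
#' Per gene and sample, beta values are drawn from Beta distributions
#' parameterized by mean and a common precision: samples of
#' `hypo_condition` use mean `mean_hypo`, all other samples use
#' `mean_other` (`0 < mean_hypo < mean_other < 1`).
#'
#' @param genes character vector of gene IDs.
#' @param conditions list of [condition_spec] objects.
#' @param hypo_condition label of the hypo-methylated condition.
#' @param mean_hypo,mean_other Beta means, strictly inside (0,1) with
#'   `mean_hypo < mean_other`.
#' @param precision Beta precision (alpha + beta), default 20.
#' @param seed integer seed.
#' @return a `beta_matrix`: list with `values` (genes x samples matrix
#'   in \[0,1\]) and `condition` (named labels), class `"beta_matrix"`.
#' @export
generate_methylation_betas <- function(genes, conditions, hypo_condition,
                                       mean_hypo = 0.3, mean_other = 0.6,
                                       precision = 20, seed = 1L) {
  if (!(mean_hypo > 0 && mean_other < 1 && mean_hypo < mean_other))
    stop("require 0 < mean_hypo < mean_other < 1")
  cond_names <- vapply(conditions, `[[`, "", "name")
  if (!hypo_condition %in% cond_names)
    stop("unknown hypo_condition: ", hypo_condition)
  set.seed(seed)
  labels <- unlist(lapply(conditions, function(cs)
    rep(cs$name, cs$n_samples)))
  sample_id <- sprintf("B%04d", seq_along(labels))
  mu <- ifelse(labels == hypo_condition, mean_hypo, mean_other)
  vals <- matrix(0, length(genes), length(labels),
                 dimnames = list(genes, sample_id))
  for (j in seq_along(labels)) {
    vals[, j] <- stats::rbeta(length(genes),
                              mu[j] * precision,
                              (1 - mu[j]) * precision)
  }
  structure(list(values = vals,
                 condition = stats::setNames(labels, sample_id)),
            class = "beta_matrix")
}
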