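#' Parameters for pairwise mixture deconvolution
#'
#' @param max_components maximum number of mixture components tried per
#'   gene pair (BIC selects among k = 1..max_components; default 5).
#' @param min_cluster_size smallest mixture cluster processed further
#'   (default 30, the Pearson power-analysis minimum at alpha = 0.05,
#'   beta = 0.2, effect size 0.5; see [pearson_min_sample_size]).
#' @param em_tol EM convergence tolerance on the relative log-likelihood
#'   change (default 1e-6).
#' @param em_max_iter maximum EM iterations (default 200).
#' @param screen_iters length of the short-EM multimodality screen: a
#'   k = 2 fit limited to this many EM iterations is tried first, and
#'   the full k = 2..max_components fits run only when its BIC already
#'   beats the closed-form k = 1 fit (default 10; 0 disables the
#'   screen). On unimodal pairs — the vast majority in any real GEM —
#'   the screen leaves model selection unchanged while removing the
#'   dominant cost of the exhaustive pair scan.
#' @param seed integer seed carried for provenance. The mixture fit is
#'   initialized deterministically (principal-axis quantile slices), so
#'   results are identical for any seed; the field is retained so that
#'   run manifests record one seed per run.
#' @return a `pairwise_params` list.
#' @export
pairwise_params <- function(max_components = 5L, min_cluster_size = 30L,
                            em_tol = 1e-6, em_max_iter = 200L,
                            screen_iters = 10L, seed = 1L) {
  stopifnot(max_components >= 1, min_cluster_size >= 3, em_tol > 0,
            em_max_iter >= 1, screen_iters >= 0)
  structure(list(max_components = as.integer(max_components),
                 min_cluster_size = as.integer(min_cluster_size),
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
                 screen_iters = as.integer(screen_iters),
                 seed = as.integer(seed)),
            class = "pairwise_params")
}

#' Minimum sample size to detect a correlation (Fisher z power analysis)
#'
#' Computes `ceil(((z[1-alpha/2] + z[1-beta]) / atanh(r))^2 + 3)`, the
#' classic Fisher-z minimum number of samples needed to detect a
#' Pearson correlation of magnitude `r` at false-positive rate `alpha`
#' and false-negative rate `beta`. At the conventional alpha = 0.05,
#' beta = 0.2 and effect size r = 0.5 this gives 30 — the cluster-size
#' floor used throughout the pipeline.
#'
#' @param alpha false positive rate, in (0,1).
#' @param beta false negative rate, in (0,1).
#' @param effect_size correlation magnitude r to detect, in (0,1).
#' @return integer minimum sample size.
#' @export
pearson_min_sample_size <- function(alpha = 0.05, beta = 0.2,
                                    effect_size = 0.5) {
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta < 1)
  if (effect_size <= 0 || effect_size >= 1)
    stop("effect_size must be in (0,1); r = 0 needs infinite n")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta)
  as.integer(ceiling((z / atanh(effect_size))^2 + 3))
}

#' Spearman rank correlation with mean-rank tie handling
#'
#' @param x,y numeric vectors of equal length >= 3 with no missing
#'   values (callers pre-filter zeros/missing).
#' @return correlation in \[-1, 1\].
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  rho <- cpp_spearman(as.numeric(x), as.numeric(y))
  if (!is.finite(rho))
    stop("Spearman correlation undefined for a constant vector")
  rho
}

#' Deconvolute one gene pair's scatter with a bivariate Gaussian mixture
#'
#' Samples where either gene is 0 (the missing sentinel) are excluded
#' up front. Full-covariance 2-D GMMs are fit for k = 1..max_components
#' with deterministic k-means initialization, the order selected by
#' BIC, and every included sample hard-assigned to its
#' maximum-responsibility component. One mask is returned per component
#' with at least `min_cluster_size` members.
#'
#' @param x,y expression vectors of the two genes over the same
#'   samples.
#' @param params a [pairwise_params] object.
#' @return list of sample masks, one per retained cluster; each mask is
#'   an integer vector over all samples with codes 1 (in-cluster),
#'   0 (out-of-cluster), 9 (excluded/missing). Empty list when fewer
#'   than `min_cluster_size` samples are included.
#' @export
pairwise_gmm_cluster <- function(x, y, params = pairwise_params()) {
  stopifnot(length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  incl <- which(x != 0 & y != 0 & is.finite(x) & is.finite(y))
  if (length(incl) < params$min_cluster_size) return(list())
  fit <- cpp_pair_gmm(x[incl], y[incl], params$max_components,
                      params$em_tol, params$em_max_iter,
                      params$screen_iters)
  if (fit$k == 0L) return(list())
  assign <- fit$assign
  counts <- tabulate(assign + 1L, nbins = fit$k)
  keep <- which(counts >= params$min_cluster_size)
  # stable ordering: size desc, then mean x asc
  if (length(keep) > 1L) {
    mx <- vapply(keep, function(c) mean(x[incl][assign == c - 1L]),
                 numeric(1))
    keep <- keep[order(-counts[keep], mx)]
  }
  lapply(keep, function(c) {
    mask <- rep(9L, length(x))
    mask[incl] <- 0L
    mask[incl[assign == c - 1L]] <- 1L
    mask
  })
}

#' Serialize a sample mask as a composition string
#'
#' One character per sample in GEM column order: `'1'` in-cluster,
#' `'0'` out-of-cluster, `'9'` excluded/missing.
#'
#' @param mask integer mask with codes 1/0/9 (as returned by
#'   [pairwise_gmm_cluster]).
#' @return a single string.
#' @export
sample_composition_string <- function(mask) {
  if (!all(mask %in% c(0L, 1L, 9L))) stop("mask codes must be 0, 1 or 9")
  paste(mask, collapse = "")
}

#' @rdname sample_composition_string
#' @param string a composition string of characters 0/1/9.
#' @return `parse_composition_string`: the integer mask.
#' @export
parse_composition_string <- function(string) {
  chars <- strsplit(string, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("0", "1", "9"))) stop("invalid composition character")
  as.integer(chars)
}

#' Build the pairwise similarity matrix (edge-candidate list) of a GEM
#'
#' Enumerates every unordered gene pair (complete enumeration, no
#' sampling), deconvolutes each pair's scatter with the bivariate GMM,
#' and computes a Spearman correlation within every retained cluster.
#' Emits one edge candidate per (pair, cluster).
#'
#' @param gem a preprocessed [gem].
#' @param params a [pairwise_params] object.
#' @return data.frame of class `edge_candidates` with columns `gene_a`,
#'   `gene_b` (canonical order `gene_a < gene_b`), `cluster_index`,
#'   `n_samples`, `spearman`, `mean_expression`, `composition`; the
#'   attribute `sample_ids` records the GEM's column order the
#'   composition strings refer to.
#' @export
build_similarity_matrix <- function(gem, params = pairwise_params()) {
  stopifnot(inherits(gem, "gem"))
  if (nrow(gem$values) > 2000L)
    warning("more than 2,000 genes: exhaustive pair enumeration will be slow")
  res <- cpp_build_similarity(gem$values, params$max_components,
                              params$min_cluster_size, params$em_tol,
                              params$em_max_iter, params$screen_iters)
  ids <- rownames(gem$values)
  a <- ids[res$i]; b <- ids[res$j]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b,
                    cluster_index = res$cluster_index,
                    n_samples = res$n_samples,
                    spearman = res$spearman,
                    mean_expression = res$mean_expression,
                    composition = res$composition,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, out$cluster_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- colnames(gem$values)
  class(out) <- c("edge_candidates", "data.frame")
  out
}

#' Read/write the edge-candidate TSV interchange format
#'
#' One row per (gene pair, mixture cluster): `gene_a`, `gene_b`,
#' `cluster_index`, `n_samples`, `spearman`, `mean_expression`,
#' `composition`. A header comment line (`#samples=`) preserves the
#' sample order the composition strings index.
#'
#' @param candidates an `edge_candidates` data.frame.
#' @param path file path.
#' @return `write_edge_candidates`: `path` invisibly;
#'   `read_edge_candidates`: the `edge_candidates` data.frame.
#' @export
write_edge_candidates <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- attr(candidates, "sample_ids")
  if (!is.null(ids))
    writeLines(paste0("#samples=", paste(ids, collapse = ",")), con)
  df <- as.data.frame(candidates)
  df$spearman <- signif(df$spearman, 15)
  df$mean_expression <- signif(df$mean_expression, 15)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_candidates
#' @export
read_edge_candidates <- function(path) {
  first <- readLines(path, n = 1L)
  ids <- NULL
  skip <- 0L
  if (startsWith(first, "#samples=")) {
    ids <- strsplit(sub("^#samples=", "", first), ",", fixed = TRUE)[[1L]]
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                          colClasses = c(composition = "character"),
                          stringsAsFactors = FALSE)
  attr(df, "sample_ids") <- ids
  class(df) <- c("edge_candidates", "data.frame")
  df
}
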