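#' Detect distributional outlier samples with a Kolmogorov-Smirnov test
#'
#' Each sample's empirical distribution of non-zero expression values
#' is compared against the pooled non-zero values of all other samples
#' (leave-one-out pooled reference). The statistic `D_N` is the
#' two-sample KS sup-norm distance; samples with `D_N > threshold` are
#' flagged. Zeros are excluded from both distributions because
#' zero-inflation would dominate the statistic; the GEM itself is not
#' modified.
#'
#' @param gem a [gem] with >= 2 samples.
#' @param threshold flagging cutoff on `D_N` (default 0.15).
#' @return an `outlier_report`: data.frame with columns `sample_id`,
#'   `D_N`, `flagged`, plus attributes `threshold` and `flagged`
#'   (character vector of flagged sample IDs).
#' @export
ks_outlier_detection <- function(gem, threshold = 0.15) {
  stopifnot(inherits(gem, "gem"))
  m <- gem$values
  if (ncol(m) < 2L) stop("KS outlier detection needs >= 2 samples")
  vals <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v[v != 0]
  })
  d <- vapply(seq_len(ncol(m)), function(j) {
    x <- vals[[j]]
    ref <- unlist(vals[-j], use.names = FALSE)
    if (length(x) == 0L || length(ref) == 0L) return(1)
    unname(suppressWarnings(stats::ks.test(x, ref)$statistic))
  }, numeric(1))
  rep <- data.frame(sample_id = colnames(m), D_N = d,
                    flagged = d > threshold, stringsAsFactors = FALSE)
  attr(rep, "threshold") <- threshold
  attr(rep, "flagged") <- rep$sample_id[rep$flagged]
  class(rep) <- c("outlier_report", "data.frame")
  rep
}

#' Log2 transform the non-zero values of a raw GEM
#'
#' Every value `v > 0` becomes `log2(v)`; zeros are preserved as exact
#' zeros (they are treated as missing downstream, not as expression
#' -Inf).
#'
#' @param gem a raw-scale [gem] (values >= 0).
#' @return a [gem] with transformed values (scale tag unchanged until
#'   quantile normalization completes the preprocessing contract).
#' @export
log2_transform_nonzero <- function(gem) {
  stopifnot(inherits(gem, "gem"))
  v <- gem$values
  if (any(v < 0)) stop("negative expression value; raw GEM required")
  nz <- v > 0
  v[nz] <- log2(v[nz])
  out <- gem
  out$values <- v
  out
}

#' Quantile normalize a GEM across samples
#'
#' Forces every sample (column) to share the same distribution: the
#' mean of the columns' sorted value vectors. Ties within a column
#' receive the mean of the reference values at their tied ranks.
#' Delegates to `limma::normalizeQuantiles(ties = TRUE)`. Exact zeros
#' are the pipeline's missing-data sentinel (log2 leaves them in
#' place): they are excluded from the rank computation and restored as
#' zeros, so downstream pairwise analysis can still recognize them.
#'
#' @param gem a [gem] with >= 2 samples.
#' @return a [gem]; applying the operation twice equals applying it
#'   once, and within-column rank order is preserved.
#' @export
quantile_normalize <- function(gem) {
  stopifnot(inherits(gem, "gem"))
  if (ncol(gem$values) < 2L) stop("quantile normalization needs >= 2 samples")
  m <- gem$values
  zeros <- m == 0
  if (any(zeros)) m[zeros] <- NA_real_
  v <- limma::normalizeQuantiles(m, ties = TRUE)
  if (any(zeros)) v[zeros] <- 0
  dimnames(v) <- dimnames(gem$values)
  out <- gem
  out$values <- v
  out
}

#' Preprocess a raw GEM: outlier removal, log2, quantile normalization
#'
#' Applies the three preprocessing steps in order: a single pass of KS
#' outlier removal (no re-iteration after removal), log2 transform of
#' non-zero values, then quantile normalization. The returned GEM is
#' tagged `log2_quantile`.
#'
#' @param gem a raw [gem].
#' @param ks_threshold outlier cutoff on `D_N` (default 0.15).
#' @return list with elements `gem` (preprocessed) and `outliers` (the
#'   [ks_outlier_detection] report on the input).
#' @export
preprocess_gem <- function(gem, ks_threshold = 0.15) {
  stopifnot(inherits(gem, "gem"))
  rep <- ks_outlier_detection(gem, threshold = ks_threshold)
  keep <- setdiff(colnames(gem$values), attr(rep, "flagged"))
  if (length(keep) < 2L)
    stop("fewer than 2 samples remain after outlier removal")
  g <- subset_gem(gem, samples = keep)
  g <- log2_transform_nonzero(g)
  g <- quantile_normalize(g)
  g$scale_tag <- "log2_quantile"
  list(gem = g, outliers = rep)
}

#' Write an outlier report as TSV
#' @param report an `outlier_report` from [ks_outlier_detection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
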