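#' Parameters for RMT threshold determination
#'
#' @param start first (highest) threshold scanned (default 0.99).
#' @param step scan decrement (default 0.001).
#' @param floor lowest threshold scanned (default 0.50).
#' @param min_eigenvalues smallest spectrum (distinct eigenvalues) on
#'   which the spacing distribution is evaluated (default 100).
#' @param nnsd_bins histogram bins for the spacing distribution
#'   (default 60).
#' @param nnsd_range_max upper end of the spacing histogram (default 3).
#' @param chi2_alpha significance level of the Poisson goodness-of-fit
#'   (default 0.001).
#' @param min_mean_expression clusters with mean expression below this
#'   are ignored by thresholding (default 0.1, the low-expression FPKM
#'   cut).
#' @param min_cluster_size clusters spanning fewer samples are ignored
#'   (default 30).
#' @return a `threshold_params` list.
#' @export
threshold_params <- function(start = 0.99, step = 0.001, floor = 0.50,
                             min_eigenvalues = 100L, nnsd_bins = 60L,
                             nnsd_range_max = 3.0, chi2_alpha = 0.001,
                             min_mean_expression = 0.1,
                             min_cluster_size = 30L) {
  stopifnot(floor < start, start <= 1, step > 0, min_eigenvalues >= 4,
            nnsd_bins >= 2, nnsd_range_max > 0,
            chi2_alpha > 0, chi2_alpha < 1)
  structure(list(start = start, step = step, floor = floor,
                 min_eigenvalues = as.integer(min_eigenvalues),
                 nnsd_bins = as.integer(nnsd_bins),
                 nnsd_range_max = nnsd_range_max,
                 chi2_alpha = chi2_alpha,
                 min_mean_expression = min_mean_expression,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "threshold_params")
}

#' Unfold a spectrum to unit mean spacing
#'
#' Collapses duplicate eigenvalues (within 1e-10), fits a cubic
#' smoothing spline (smoothness by generalized cross-validation) to the
#' empirical cumulative spectral density, maps the eigenvalues through
#' the fit, and returns the successive differences rescaled to mean 1.
#' For a modular (localized) matrix the unfolded spacings follow the
#' Poisson law `exp(-s)`; for a GOE-like random matrix they follow the
#' Wigner surmise.
#'
#' @param eigs numeric vector of eigenvalues (any order).
#' @param min_eigenvalues minimum number of distinct eigenvalues
#'   required (default 100).
#' @return numeric vector of non-negative spacings with mean 1.
#' @export
unfold_eigenvalues <- function(eigs, min_eigenvalues = 100L) {
  eigs <- sort(as.numeric(eigs))
  keep <- c(TRUE, diff(eigs) > 1e-10)
  eigs <- eigs[keep]
  n <- length(eigs)
  if (n < min_eigenvalues)
    stop("insufficient spectrum: ", n, " distinct eigenvalues < ",
         min_eigenvalues)
  cdf <- seq_len(n) / n
  fit <- stats::smooth.spline(eigs, cdf)
  mapped <- stats::predict(fit, eigs)$y
  s <- pmax(diff(mapped), 0)
  m <- mean(s)
  if (m <= 0) stop("degenerate spectrum: zero mean spacing")
  s / m
}

#' Chi-square goodness of fit of spacings to the Poisson law
#'
#' Histograms the spacings over `[0, range_max]` in equal-width bins
#' and compares observed counts with the counts expected under the
#' Poisson spacing density `exp(-s)` integrated per bin (scaled by the
#' total number of spacings). Large statistics indicate departure from
#' Poisson, i.e. the Wigner-Dyson regime of a random matrix.
#'
#' @param spacings unfolded spacings (>= 100).
#' @param bins number of histogram bins (default 60).
#' @param range_max histogram upper limit (default 3).
#' @return list with `chi2` (the Pearson statistic) and `df`
#'   (`bins - 1`).
#' @export
nnsd_chi_square <- function(spacings, bins = 60L, range_max = 3.0) {
  if (length(spacings) == 0L) stop("empty spacing vector")
  if (length(spacings) < 100L) stop("need >= 100 spacings")
  breaks <- seq(0, range_max, length.out = bins + 1L)
  inside <- spacings[spacings >= 0 & spacings <= range_max]
  obs <- tabulate(findInterval(inside, breaks, rightmost.closed = TRUE),
                  nbins = bins)
  expd <- length(spacings) *
    (exp(-breaks[-length(breaks)]) - exp(-breaks[-1L]))
  list(chi2 = sum((obs - expd)^2 / expd), df = bins - 1L)
}

# per-pair scalar similarity: max |spearman| over a pair's retained clusters
.pair_max_similarity <- function(candidates, params) {
  keep <- candidates$n_samples >= params$min_cluster_size &
    candidates$mean_expression >= params$min_mean_expression
  df <- candidates[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      w = numeric(), stringsAsFactors = FALSE))
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  w <- tapply(abs(df$spearman), key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[[`, "", 1L),
             gene_b = vapply(parts, `[[`, "", 2L),
             w = as.numeric(w), stringsAsFactors = FALSE)
}

#' Find the correlation significance threshold by random matrix theory
#'
#' Scans candidate thresholds downward from `start` to `floor`. At each
#' threshold `t` the gene-by-gene similarity matrix is built with entry
#' `(i,j)` equal to the pair's maximum absolute Spearman correlation
#' across retained clusters if it reaches `t`, else 0 (diagonal 1),
#' restricted to genes with at least one surviving edge. Whenever the
#' spectrum holds at least `min_eigenvalues` distinct eigenvalues, the
#' nearest-neighbour spacing distribution is tested against the Poisson
#' law; the returned threshold is the smallest `t` that still accepts
#' Poisson — the last point before the Poisson-to-GOE transition. If
#' the scan reaches `floor` without observing a transition (including
#' the case where the spectrum never grows large enough to test), the
#' floor is returned with `attr(, "warning_flag") = TRUE`.
#'
#' @param candidates an `edge_candidates` data.frame (see
#'   [build_similarity_matrix]).
#' @param params a [threshold_params] object.
#' @return the threshold (numeric scalar) with attributes
#'   `warning_flag` (TRUE when the floor was returned without a
#'   detected transition) and `trace` (data.frame of the scan:
#'   `t`, `n_genes`, `n_edges`, `chi2`, `df`, `decision`).
#' @export
find_rmt_threshold <- function(candidates, params = threshold_params()) {
  pairs <- .pair_max_similarity(candidates, params)
  if (nrow(pairs) == 0L || !any(pairs$w >= params$floor))
    stop("matrix never dense enough: no edges reach the scan floor")
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  crit <- stats::qchisq(1 - params$chi2_alpha, df = params$nnsd_bins - 1L)

  ts <- seq(params$start, params$floor, by = -params$step)
  last_accept <- NA_real_
  trace <- vector("list", length(ts))
  prev_edges <- -1L
  prev <- NULL
  for (idx in seq_along(ts)) {
    t <- ts[idx]
    sel <- pairs$w >= t
    n_edges <- sum(sel)
    if (n_edges == prev_edges && !is.null(prev)) {
      decision <- prev$decision
      chi2 <- prev$chi2; df <- prev$df; n_genes <- prev$n_genes
    } else {
      gsel <- sort(unique(c(ia[sel], ib[sel])))
      n_genes <- length(gsel)
      chi2 <- NA_real_; df <- NA_integer_
      decision <- "spectrum_too_small"
      if (n_genes >= params$min_eigenvalues) {
        A <- matrix(0, n_genes, n_genes)
        ri <- match(ia[sel], gsel); rj <- match(ib[sel], gsel)
        A[cbind(ri, rj)] <- pairs$w[sel]
        A[cbind(rj, ri)] <- pairs$w[sel]
        diag(A) <- 1
        ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
        sp <- tryCatch(
          unfold_eigenvalues(ev, params$min_eigenvalues),
          error = function(e) NULL)
        if (!is.null(sp) && length(sp) >= 100L) {
          gof <- nnsd_chi_square(sp, params$nnsd_bins,
                                 params$nnsd_range_max)
          chi2 <- gof$chi2; df <- gof$df
          decision <- if (chi2 <= crit) "poisson" else "goe"
        }
      }
      prev <- list(decision = decision, chi2 = chi2, df = df,
                   n_genes = n_genes)
      prev_edges <- n_edges
    }
    trace[[idx]] <- data.frame(t = t, n_genes = n_genes,
                               n_edges = n_edges, chi2 = chi2, df = df,
                               decision = decision,
                               stringsAsFactors = FALSE)
    if (decision == "poisson") last_accept <- t
    if (decision == "goe" && !is.na(last_accept)) {
      out <- last_accept
      attr(out, "warning_flag") <- FALSE
      attr(out, "trace") <- do.call(rbind, trace[seq_len(idx)])
      return(out)
    }
    if (decision == "goe" && is.na(last_accept)) {
      warning("spacing distribution already GOE-like at scan start; ",
              "returning start threshold")
      out <- params$start
      attr(out, "warning_flag") <- TRUE
      attr(out, "trace") <- do.call(rbind, trace[seq_len(idx)])
      return(out)
    }
  }
  out <- if (!is.na(last_accept)) last_accept else params$floor
  if (is.na(last_accept))
    warning("scan reached floor without a Poisson-to-GOE transition; ",
            "returning floor threshold")
  attr(out, "warning_flag") <- is.na(last_accept)
  attr(out, "trace") <- do.call(rbind, trace)
  out
}

#' Extract the co-expression network above a correlation threshold
#'
#' Keeps every edge candidate whose cluster passes the sample-count and
#' mean-expression filters and whose absolute Spearman correlation
#' reaches the threshold. Lowering the threshold never removes edges.
#'
#' @param candidates an `edge_candidates` data.frame.
#' @param threshold correlation cutoff in \[0, 1\] (0 keeps every
#'   filtered candidate).
#' @param params a [threshold_params] (supplies the cluster filters).
#' @param source_gem_id optional identifier of the GEM the candidates
#'   came from.
#' @return a `gcn` object: list with `edges` (the surviving
#'   `edge_candidates` rows), `threshold` and `source_gem_id`.
#' @export
threshold_network <- function(candidates, threshold,
                              params = threshold_params(),
                              source_gem_id = "") {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- candidates$n_samples >= params$min_cluster_size &
    candidates$mean_expression >= params$min_mean_expression &
    abs(candidates$spearman) >= threshold
  edges <- candidates[keep, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "sample_ids") <- attr(candidates, "sample_ids")
  class(edges) <- class(candidates)
  structure(list(edges = edges, threshold = as.numeric(threshold),
                 source_gem_id = source_gem_id),
            class = "gcn")
}

#' @export
print.gcn <- function(x, ...) {
  cat(sprintf("GCN: %d edges, %d genes, threshold %.4f\n",
              nrow(x$edges),
              length(unique(c(x$edges$gene_a, x$edges$gene_b))),
              x$threshold))
  invisible(x)
}
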