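#' Map gene IDs through an ID-mapping table
#'
#' @param genes character vector of source IDs.
#' @param id_map data.frame with columns `source_id`, `target_id`
#'   (many-to-many allowed; no empty IDs).
#' @return list with `mapped` (unique target IDs of all mappable
#'   sources) and `unmapped` (source IDs with no mapping).
#' @export
map_genes <- function(genes, id_map) {
  stopifnot(all(c("source_id", "target_id") %in% names(id_map)))
  if (any(!nzchar(id_map$source_id)) || any(!nzchar(id_map$target_id)))
    stop("empty IDs are not allowed in an ID map")
  hit <- genes %in% id_map$source_id
  mapped <- unique(id_map$target_id[id_map$source_id %in% genes])
  list(mapped = mapped, unmapped = genes[!hit])
}

#' Read a two-column ID map TSV
#' @param path TSV with columns `source_id`, `target_id` (header
#'   optional; first two columns used).
#' @return data.frame with columns `source_id`, `target_id`.
#' @export
read_id_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:2], c("source_id", "target_id"))
}

#' Genes shared by two modules after ID mapping
#'
#' Maps module A's genes into module B's namespace and intersects.
#'
#' @param module_a_genes,module_b_genes character vectors.
#' @param id_map data.frame (`source_id`, `target_id`); NULL for an
#'   identity map.
#' @return character vector of shared genes (in B's namespace).
#' @export
module_overlap <- function(module_a_genes, module_b_genes,
                           id_map = NULL) {
  a <- if (is.null(id_map)) module_a_genes
       else map_genes(module_a_genes, id_map)$mapped
  sort(intersect(a, module_b_genes))
}

#' Extract a mini-GEM: a module's genes in selected conditions
#'
#' @param gem a [gem].
#' @param genes transcript IDs to keep; IDs absent from the GEM are
#'   dropped and reported via the `missing_genes` attribute.
#' @param conditions optional condition labels to keep (all samples if
#'   omitted).
#' @return a [gem] restricted to the genes and conditions, values
#'   untouched; errors if nothing remains.
#' @export
extract_mini_gem <- function(gem, genes, conditions = NULL) {
  stopifnot(inherits(gem, "gem"))
  present <- intersect(genes, rownames(gem$values))
  missing <- setdiff(genes, present)
  if (length(present) == 0L) stop("no requested genes present in the GEM")
  samples <- names(gem$condition)
  if (!is.null(conditions))
    samples <- samples[gem$condition %in% conditions]
  if (length(samples) == 0L) stop("no samples in the requested conditions")
  out <- subset_gem(gem, transcripts = present, samples = samples)
  attr(out, "missing_genes") <- missing
  out
}

#' Edge rediscovery of a module in an alternate sample set
#'
#' A module edge is *rediscovered* when its unordered gene pair appears
#' among the mini-GEM's edge candidates (any mixture cluster); it is
#' *above threshold* when any of those clusters has
#' `|spearman| > reference_threshold`. `rediscovery_fraction` is
#' rediscovered / module edges and `above_threshold_fraction` is
#' above-threshold / rediscovered.
#'
#' @param module_edges data.frame (`gene_a`, `gene_b`) of the module's
#'   edges, already in the mini-GEM's ID namespace.
#' @param mini_candidates `edge_candidates` from
#'   [build_similarity_matrix] on the mini-GEM.
#' @param reference_threshold the reference network's RMT threshold.
#' @param universe_genes genes present in the mini-GEM (defaults to the
#'   genes seen among `mini_candidates`); a module edge is *mappable*
#'   when both endpoints are in this universe.
#' @return a `rediscovery_report` list: `n_module_edges`,
#'   `n_mappable_edges`, `n_rediscovered`, `n_above_threshold`,
#'   `rediscovery_fraction`, `above_threshold_fraction`,
#'   `reference_threshold`.
#' @export
edge_rediscovery <- function(module_edges, mini_candidates,
                             reference_threshold,
                             universe_genes = NULL) {
  n_module <- nrow(module_edges)
  if (is.null(universe_genes))
    universe_genes <- unique(c(mini_candidates$gene_a,
                               mini_candidates$gene_b))
  mkey <- .edge_key(module_edges$gene_a, module_edges$gene_b)
  mappable <- module_edges$gene_a %in% universe_genes &
    module_edges$gene_b %in% universe_genes
  ckey <- .edge_key(mini_candidates$gene_a, mini_candidates$gene_b)
  redisc <- mappable & (mkey %in% ckey)
  above <- vapply(seq_len(n_module), function(r) {
    if (!redisc[r]) return(FALSE)
    any(abs(mini_candidates$spearman[ckey == mkey[r]]) >
          reference_threshold)
  }, logical(1))
  rediscovery_report(n_module_edges = n_module,
                     n_mappable_edges = sum(mappable),
                     n_rediscovered = sum(redisc),
                     n_above_threshold = sum(above),
                     reference_threshold = reference_threshold)
}

#' Assemble a rediscovery report from its counts
#'
#' Checks the count ordering
#' `n_above_threshold <= n_rediscovered <= n_mappable_edges <=
#' n_module_edges` and derives the two fractions
#' (rediscovered / module edges; above-threshold / rediscovered).
#'
#' @param n_module_edges,n_mappable_edges,n_rediscovered,n_above_threshold
#'   non-negative integer counts.
#' @param reference_threshold the reference network's threshold.
#' @return a `rediscovery_report` list.
#' @export
rediscovery_report <- function(n_module_edges, n_mappable_edges,
                               n_rediscovered, n_above_threshold,
                               reference_threshold) {
  if (!(n_above_threshold <= n_rediscovered &&
        n_rediscovered <= n_mappable_edges &&
        n_mappable_edges <= n_module_edges))
    stop("inconsistent rediscovery counts")
  structure(list(
    n_module_edges = as.integer(n_module_edges),
    n_mappable_edges = as.integer(n_mappable_edges),
    n_rediscovered = as.integer(n_rediscovered),
    n_above_threshold = as.integer(n_above_threshold),
    rediscovery_fraction =
      if (n_module_edges > 0) n_rediscovered / n_module_edges else 0,
    above_threshold_fraction =
      if (n_rediscovered > 0) n_above_threshold / n_rediscovered else 0,
    reference_threshold = reference_threshold), class = "rediscovery_report")
}

#' @export
print.rediscovery_report <- function(x, ...) {
  cat(sprintf(
    "rediscovered %d/%d edges (%.2f%%); %d above threshold %.4f (%.2f%%)\n",
    x$n_rediscovered, x$n_module_edges, 100 * x$rediscovery_fraction,
    x$n_above_threshold, x$reference_threshold,
    100 * x$above_threshold_fraction))
  invisible(x)
}

#' Write a rediscovery report as key-value TSV
#' @param report a `rediscovery_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rediscovery_report <- function(report, path) {
  df <- data.frame(key = names(report),
                   value = vapply(report, function(v)
                     as.character(signif(as.numeric(v), 15)), ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# shared two-group t-test machinery for expression and methylation
.two_group_ttests <- function(values, condition, genes, cond_a, cond_b,
                              welch = FALSE) {
  genes <- intersect(genes, rownames(values))
  if (length(genes) == 0L) stop("none of the requested genes are present")
  ia <- which(condition == cond_a)
  ib <- which(condition == cond_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both conditions need >= 2 samples")
  one_test <- function(x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y))))
        return(c(t = 0, p = 1, degenerate = 1))
      return(c(t = Inf * sign(mean(x) - mean(y)), p = 0, degenerate = 1))
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    c(t = unname(tt$statistic), p = tt$p.value, degenerate = 0)
  }
  per_gene <- t(vapply(genes, function(g)
    one_test(values[g, ia], values[g, ib]), numeric(3)))
  per <- data.frame(gene = genes, t = per_gene[, "t"],
                    p = per_gene[, "p"],
                    direction = ifelse(
                      rowMeans(values[genes, ia, drop = FALSE]) >=
                        rowMeans(values[genes, ib, drop = FALSE]),
                      "up_in_a", "down_in_a"),
                    degenerate = per_gene[, "degenerate"] == 1,
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  pooled_raw <- one_test(as.numeric(values[genes, ia]),
                         as.numeric(values[genes, ib]))
  pooled <- list(t = unname(pooled_raw["t"]), p = unname(pooled_raw["p"]),
                 direction = if (mean(values[genes, ia]) >=
                                   mean(values[genes, ib]))
                   "up_in_a" else "down_in_a",
                 degenerate = pooled_raw["degenerate"] == 1)
  list(per_gene = per, pooled = pooled,
       cond_a = cond_a, cond_b = cond_b)
}

#' Differential expression t-tests between two conditions
#'
#' Classic two-sided pooled-variance (Student) two-sample t-test per
#' gene, plus a module-level test pooling all (gene, sample) values —
#' one p-value per comparison, as in the cross-network validation
#' workflow. Set `welch = TRUE` for the unequal-variance variant.
#'
#' @param gem a [gem].
#' @param genes genes to test (missing ones dropped).
#' @param cond_a,cond_b condition labels, each with >= 2 samples.
#' @param welch use Welch's t instead of pooled variance (default
#'   FALSE).
#' @return list with `per_gene` (data.frame `gene`, `t`, `p`,
#'   `direction`, `degenerate`) and `pooled` (module-level `t`, `p`,
#'   `direction`). Identical zero-variance groups give t = 0, p = 1
#'   with the `degenerate` flag set.
#' @export
differential_expression_ttest <- function(gem, genes, cond_a, cond_b,
                                          welch = FALSE) {
  stopifnot(inherits(gem, "gem"))
  .two_group_ttests(gem$values, gem$condition, genes, cond_a, cond_b,
                    welch)
}

#' Methylation beta-value t-tests between two conditions
#'
#' Same contract as [differential_expression_ttest] on a beta-value
#' matrix; `direction` reads `hypo_in_a` / `hyper_in_a` (condition A's
#' mean beta below / above condition B's).
#'
#' @param betas a `beta_matrix` (see [generate_methylation_betas]).
#' @param genes genes to test.
#' @param cond_a,cond_b condition labels.
#' @param welch use Welch's t (default FALSE).
#' @return as [differential_expression_ttest].
#' @export
methylation_ttest <- function(betas, genes, cond_a, cond_b,
                              welch = FALSE) {
  stopifnot(inherits(betas, "beta_matrix"))
  out <- .two_group_ttests(betas$values, betas$condition, genes,
                           cond_a, cond_b, welch)
  relabel <- function(d) ifelse(d == "up_in_a", "hyper_in_a", "hypo_in_a")
  out$per_gene$direction <- relabel(out$per_gene$direction)
  out$pooled$direction <- relabel(out$pooled$direction)
  out
}

#' Normalize one condition's samples by their global median
#'
#' Divides every value of the condition's samples by the global median
#' of that condition's submatrix, bringing cross-study conditions onto
#' a comparable scale; after normalization the condition's global
#' median is 1.
#'
#' @param gem a [gem].
#' @param condition condition label with >= 1 sample.
#' @return a [gem] with the condition's columns rescaled; the divisor
#'   is recorded in `attr(, "median_divisor")`.
#' @export
median_condition_normalize <- function(gem, condition) {
  stopifnot(inherits(gem, "gem"))
  cols <- names(gem$condition)[gem$condition == condition]
  if (length(cols) == 0L) stop("no samples in condition ", condition)
  med <- stats::median(gem$values[, cols])
  if (med == 0) stop("global median of condition ", condition, " is zero")
  v <- gem$values
  v[, cols] <- v[, cols] / med
  out <- gem(v, gem$condition, scale_tag = gem$scale_tag)
  attr(out, "median_divisor") <- med
  out
}
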