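#' Samples supporting a module: the > 95%-of-edges rule
#'
#' A sample supports a module if it is in-cluster (code `'1'` in the
#' composition string) for strictly more than `fraction` of the
#' module's edges. When a pair carries several retained clusters in the
#' GCN, a sample counts as in-cluster for the edge if any cluster of
#' that pair includes it.
#'
#' @param module a `link_community_module`.
#' @param gcn the `gcn` the module was extracted from (supplies the
#'   per-edge sample masks).
#' @param fraction strict inclusion fraction (default 0.95).
#' @return character vector of supporting sample IDs.
#' @export
module_sample_set <- function(module, gcn, fraction = 0.95) {
  e <- gcn$edges
  ids <- attr(e, "sample_ids")
  if (is.null(ids)) stop("GCN edges carry no sample_ids attribute")
  key_gcn <- .edge_key(e$gene_a, e$gene_b)
  n_edges <- nrow(module$edges)
  counts <- integer(length(ids))
  for (r in seq_len(n_edges)) {
    k <- .edge_key(module$edges$gene_a[r], module$edges$gene_b[r])
    rows <- which(key_gcn == k)
    if (length(rows) == 0L)
      stop("module edge missing from GCN: ", k)
    inmask <- rep(FALSE, length(ids))
    for (rr in rows)
      inmask <- inmask | (parse_composition_string(e$composition[rr]) == 1L)
    counts <- counts + inmask
  }
  ids[counts > fraction * n_edges]
}

#' One-sided Fisher enrichment p-value of a 2x2 table
#'
#' Over-representation (upper-tail hypergeometric) probability of
#' observing at least `a` successes, for the table
#' `rbind(c(a, b), c(c, d))` with `a` = in-set and in-class counts.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_enrichment <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  a <- table[1L, 1L]; b <- table[1L, 2L]
  cc <- table[2L, 1L]; d <- table[2L, 2L]
  # P(X >= a), X ~ Hypergeometric(white = a+cc, black = b+d, drawn = a+b)
  stats::phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
}

#' Condition-label enrichment of a module's sample set
#'
#' For every condition in the GEM, builds the 2x2 table of
#' (module-sample membership) x (condition membership) over all GEM
#' samples and tests over-representation with a one-sided Fisher exact
#' test. Significance at raw p < `alpha` (no multiple-testing
#' correction); a Benjamini-Hochberg column is reported alongside for
#' transparency but does not drive the flag.
#'
#' @param module a `link_community_module`.
#' @param gcn its source `gcn`.
#' @param gem the GEM (supplies the condition labels).
#' @param fraction the module-sample rule's fraction (default 0.95).
#' @param alpha significance cutoff on the raw p (default 0.001).
#' @return data.frame with columns `module_id`, `label`, `a`, `b`,
#'   `c`, `d`, `p_value`, `p_adjust`, `significant`.
#' @export
condition_enrichment <- function(module, gcn, gem, fraction = 0.95,
                                 alpha = 0.001) {
  samples <- module_sample_set(module, gcn, fraction)
  all_samples <- names(gem$condition)
  if (length(samples) == 0L)
    warning("module ", module$module_id, " has an empty sample set")
  conds <- sort(unique(gem$condition))
  rows <- lapply(conds, function(cond) {
    in_cond <- all_samples[gem$condition == cond]
    a <- length(intersect(samples, in_cond))
    b <- length(samples) - a
    cc <- length(in_cond) - a
    d <- length(all_samples) - a - b - cc
    p <- if (length(samples) == 0L) 1
         else fisher_exact_enrichment(rbind(c(a, b), c(cc, d)))
    data.frame(module_id = module$module_id, label = cond,
               a = a, b = b, c = cc, d = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out
}

#' Read a term -> genes annotation map (two-column TSV or GMT)
#'
#' Two-column TSV: columns `term`, `gene` (one gene per row, header
#' optional). GMT: `term <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path annotation file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return named list term -> character vector of genes.
#' @export
read_annotation_map <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
    names(out) <- vapply(parts, `[[`, "", 1L)
    return(out)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Functional term enrichment of a module's gene set
#'
#' Per-term one-sided Fisher over-representation test of the module's
#' genes against a background gene universe.
#'
#' @param module_genes character vector, a subset of `background`.
#' @param annotation named list term -> gene vector (see
#'   [read_annotation_map]).
#' @param background the gene universe.
#' @param alpha significance cutoff on the raw p (default 0.001).
#' @return data.frame with columns `label`, `a`, `b`, `c`, `d`,
#'   `p_value`, `p_adjust`, `significant`; terms with no genes in the
#'   background are skipped with a warning.
#' @export
term_enrichment <- function(module_genes, annotation, background,
                            alpha = 0.001) {
  if (!all(module_genes %in% background))
    stop("module genes must be a subset of the background universe")
  rows <- list()
  for (term in names(annotation)) {
    genes <- intersect(annotation[[term]], background)
    if (length(genes) == 0L) {
      warning("term ", term, " has no genes in the background; skipped")
      next
    }
    a <- length(intersect(module_genes, genes))
    b <- length(module_genes) - a
    cc <- length(genes) - a
    d <- length(background) - a - b - cc
    p <- fisher_exact_enrichment(rbind(c(a, b), c(cc, d)))
    rows[[term]] <- data.frame(label = term, a = a, b = b, c = cc,
                               d = d, p_value = p,
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(label = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), p_value = numeric(),
                      p_adjust = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out
}
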