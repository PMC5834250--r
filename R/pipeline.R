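#' Configuration for a discovery run
#'
#' Bundles inputs and stage parameters for [run_discovery]. Supply
#' either an in-memory [gem] or the paths of its TSV files.
#'
#' @param gem a [gem] object, or NULL to read from `gem_path`.
#' @param gem_path,annotation_path GEM TSV and sample-annotation TSV.
#' @param pairwise a [pairwise_params].
#' @param threshold a [threshold_params].
#' @param ks_threshold KS outlier cutoff (default 0.15).
#' @param fraction module-sample rule fraction (default 0.95).
#' @param min_module_edges minimum module size in edges (default 3).
#' @param enrichment_alpha significance cutoff (default 0.001).
#' @param annotation_map optional named list term -> genes for term
#'   enrichment.
#' @param out_dir optional directory; when given, every stage artifact
#'   is written there with a manifest recording parameters, seed and
#'   config hash.
#' @param seed global seed recorded in the manifest and carried into
#'   the pairwise parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gem = NULL, gem_path = NULL,
                            annotation_path = NULL,
                            pairwise = pairwise_params(),
                            threshold = threshold_params(),
                            ks_threshold = 0.15, fraction = 0.95,
                            min_module_edges = 3L,
                            enrichment_alpha = 0.001,
                            annotation_map = NULL, out_dir = NULL,
                            seed = 1L) {
  if (is.null(gem) && (is.null(gem_path) || is.null(annotation_path)))
    stop("config error: supply a gem or gem_path + annotation_path")
  pairwise$seed <- as.integer(seed)
  structure(list(gem = gem, gem_path = gem_path,
                 annotation_path = annotation_path, pairwise = pairwise,
                 threshold = threshold, ks_threshold = ks_threshold,
                 fraction = fraction,
                 min_module_edges = as.integer(min_module_edges),
                 enrichment_alpha = enrichment_alpha,
                 annotation_map = annotation_map, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  skim <- config[setdiff(names(config),
                         c("gem", "annotation_map", "out_dir"))]
  txt <- paste(deparse(skim), collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full module-discovery pipeline on one GEM
#'
#' preprocess (KS outliers, log2, quantile) -> pairwise mixture
#' similarity -> RMT threshold -> network extraction -> link community
#' modules -> condition (and optional term) enrichment. When
#' `config$out_dir` is set, every artifact is written as TSV together
#' with `manifest.tsv` recording the parameters, seed and config hash.
#'
#' @param config a [pipeline_config].
#' @return list with `gem` (preprocessed), `outliers`, `candidates`,
#'   `threshold` (with scan trace attribute), `gcn`, `modules`,
#'   `condition_enrichment` (one data.frame over all modules) and
#'   `term_enrichment` (NULL without an annotation map).
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  g <- config$gem
  if (is.null(g))
    g <- .stage("read_gem",
                read_gem(config$gem_path, config$annotation_path))
  pre <- .stage("preprocess", preprocess_gem(g, config$ks_threshold))
  cand <- .stage("similarity",
                 build_similarity_matrix(pre$gem, config$pairwise))
  thr <- .stage("threshold",
                suppressWarnings(
                  find_rmt_threshold(cand, config$threshold)))
  gcn <- .stage("network",
                threshold_network(cand, as.numeric(thr), config$threshold,
                                  source_gem_id = .config_hash(config)))
  modules <- .stage("modules",
                    extract_modules(gcn, config$min_module_edges))
  cond_enr <- .stage("enrich", {
    tabs <- lapply(modules, condition_enrichment, gcn = gcn,
                   gem = pre$gem, fraction = config$fraction,
                   alpha = config$enrichment_alpha)
    if (length(tabs)) do.call(rbind, tabs) else NULL
  })
  term_enr <- NULL
  if (!is.null(config$annotation_map)) {
    background <- rownames(pre$gem$values)
    term_enr <- .stage("term_enrich", {
      tabs <- lapply(modules, function(mo) {
        df <- term_enrichment(mo$genes, config$annotation_map,
                              background, config$enrichment_alpha)
        if (nrow(df)) cbind(module_id = mo$module_id, df) else NULL
      })
      tabs <- Filter(Negate(is.null), tabs)
      if (length(tabs)) do.call(rbind, tabs) else NULL
    })
  }
  result <- list(gem = pre$gem, outliers = pre$outliers,
                 candidates = cand, threshold = thr, gcn = gcn,
                 modules = modules, condition_enrichment = cond_enr,
                 term_enrichment = term_enr)
  if (!is.null(config$out_dir)) .write_discovery(result, config)
  result
}

.write_discovery <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  hash <- .config_hash(config)
  write_gem(result$gem, p("gem_preprocessed.tsv"), p("annotation.tsv"))
  write_outlier_report(result$outliers, p("outliers.tsv"))
  write_edge_candidates(result$candidates, p("edge_candidates.tsv"))
  trace <- attr(result$threshold, "trace")
  utils::write.table(trace, p("threshold_trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  thr_line <- data.frame(
    threshold = as.numeric(result$threshold),
    warning_flag = isTRUE(attr(result$threshold, "warning_flag")),
    n_edges = nrow(result$gcn$edges),
    n_genes = length(unique(c(result$gcn$edges$gene_a,
                              result$gcn$edges$gene_b))))
  utils::write.table(thr_line, p("threshold.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edge_candidates(result$gcn$edges, p("gcn_edges.tsv"))
  write_modules(result$modules, p("modules.tsv"),
                p("module_summary.tsv"))
  if (!is.null(result$condition_enrichment))
    utils::write.table(result$condition_enrichment,
                       p("condition_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$term_enrichment))
    utils::write.table(result$term_enrichment,
                       p("term_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- data.frame(
    key = c("config_hash", "seed", "ks_threshold", "fraction",
            "min_module_edges", "enrichment_alpha", "max_components",
            "min_cluster_size", "em_tol", "em_max_iter",
            "threshold_start", "threshold_step", "threshold_floor",
            "min_eigenvalues", "nnsd_bins", "nnsd_range_max",
            "chi2_alpha", "min_mean_expression"),
    value = as.character(c(
      hash, config$seed, config$ks_threshold, config$fraction,
      config$min_module_edges, config$enrichment_alpha,
      config$pairwise$max_components, config$pairwise$min_cluster_size,
      config$pairwise$em_tol, config$pairwise$em_max_iter,
      config$threshold$start, config$threshold$step,
      config$threshold$floor, config$threshold$min_eigenvalues,
      config$threshold$nnsd_bins, config$threshold$nnsd_range_max,
      config$threshold$chi2_alpha,
      config$threshold$min_mean_expression)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Cross-network validation of discovered modules
#'
#' For every condition-enriched module of network A: (i) rediscovers
#' its edges within network A's own GEM restricted to the samples of
#' the conditions it is *not* enriched for, and (ii) maps its genes
#' into network B's namespace, extracts the matching mini-GEM from B,
#' and rediscovers the mapped edges there against B's threshold. Also
#' reports gene overlaps between enriched modules of A and all modules
#' of B, and, when requested, differential expression and methylation
#' t-tests for each enriched module's genes.
#'
#' @param discovery_a,discovery_b results of [run_discovery].
#' @param id_map optional data.frame (`source_id`, `target_id`) mapping
#'   A's gene IDs into B's namespace; NULL for identity.
#' @param betas optional `beta_matrix` for methylation t-tests.
#' @param de_conditions optional character vector of length 2: the
#'   conditions compared by the expression t-tests (defaults to the
#'   module's enriched condition vs all other samples pooled under the
#'   label `"other"`).
#' @param methylation_conditions optional character vector of length 2
#'   for the beta-value t-tests.
#' @param pairwise_b [pairwise_params] used for the mini-GEM similarity
#'   builds (defaults to `pairwise_params()`).
#' @return list with one entry per enriched module of A: `module_id`,
#'   `enriched_condition`, `overlap` (best-matching module of B and
#'   shared genes), `rediscovery_inactive` and `rediscovery_cross`
#'   (`rediscovery_report`s), `de`, `methylation`.
#' @export
run_crossvalidation <- function(discovery_a, discovery_b, id_map = NULL,
                                betas = NULL, de_conditions = NULL,
                                methylation_conditions = NULL,
                                pairwise_b = pairwise_params()) {
  if (is.null(discovery_a$modules) || is.null(discovery_b$modules))
    stop("discovery outputs missing modules; run run_discovery first")
  enr <- discovery_a$condition_enrichment
  if (is.null(enr) || !any(enr$significant)) {
    warning("network A has no condition-enriched module; nothing to validate")
    return(list())
  }
  if (!is.null(id_map) && nrow(id_map) == 0L) {
    warning("empty ID map: overlaps will be empty")
  }
  enr_sig <- enr[enr$significant, , drop = FALSE]
  out <- list()
  for (mid in unique(enr_sig$module_id)) {
    mod <- Filter(function(mo) mo$module_id == mid,
                  discovery_a$modules)[[1L]]
    cond <- enr_sig$label[enr_sig$module_id == mid][1L]
    gem_a <- discovery_a$gem
    inactive <- setdiff(unique(gem_a$condition), cond)

    # (i) same network, unenriched conditions only
    redisc_inactive <- NULL
    if (length(inactive)) {
      mini_a <- extract_mini_gem(gem_a, mod$genes, conditions = inactive)
      cand_a <- build_similarity_matrix(mini_a, pairwise_b)
      redisc_inactive <- edge_rediscovery(
        mod$edges, cand_a, discovery_a$gcn$threshold,
        universe_genes = rownames(mini_a$values))
    }

    # (ii) mapped into network B
    genes_b <- if (is.null(id_map)) mod$genes
               else map_genes(mod$genes, id_map)$mapped
    edges_b <- mod$edges
    if (!is.null(id_map)) {
      # one-to-one rows only; many-to-many pairs are not edge-resolvable
      a1 <- vapply(mod$edges$gene_a, function(g) {
        t <- unique(id_map$target_id[id_map$source_id == g])
        if (length(t) == 1L) t else NA_character_
      }, "")
      b1 <- vapply(mod$edges$gene_b, function(g) {
        t <- unique(id_map$target_id[id_map$source_id == g])
        if (length(t) == 1L) t else NA_character_
      }, "")
      keep <- !is.na(a1) & !is.na(b1)
      edges_b <- data.frame(gene_a = pmin(a1[keep], b1[keep]),
                            gene_b = pmax(a1[keep], b1[keep]),
                            stringsAsFactors = FALSE)
    }
    redisc_cross <- NULL
    overlap <- NULL
    gem_b <- discovery_b$gem
    present_b <- intersect(genes_b, rownames(gem_b$values))
    if (length(present_b) >= 2L) {
      mini_b <- extract_mini_gem(gem_b, present_b)
      cand_b <- build_similarity_matrix(mini_b, pairwise_b)
      redisc_cross <- edge_rediscovery(
        edges_b, cand_b, discovery_b$gcn$threshold,
        universe_genes = rownames(mini_b$values))
    }
    if (length(discovery_b$modules)) {
      shared <- lapply(discovery_b$modules, function(mb)
        module_overlap(mod$genes, mb$genes, id_map))
      best <- which.max(vapply(shared, length, 0L))
      overlap <- list(module_b = discovery_b$modules[[best]]$module_id,
                      shared_genes = shared[[best]])
    }

    de <- NULL
    if (!is.null(de_conditions)) {
      de <- differential_expression_ttest(
        gem_a, mod$genes, de_conditions[1L], de_conditions[2L])
    } else if (length(inactive)) {
      g2 <- gem_a
      g2$condition[g2$condition != cond] <- "other"
      de <- differential_expression_ttest(g2, mod$genes, cond, "other")
    }
    meth <- NULL
    if (!is.null(betas)) {
      mc <- if (!is.null(methylation_conditions)) methylation_conditions
            else unique(betas$condition)[1:2]
      genes_m <- intersect(mod$genes, rownames(betas$values))
      if (length(genes_m))
        meth <- methylation_ttest(betas, genes_m, mc[1L], mc[2L])
    }
    out[[mid]] <- list(module_id = mid, enriched_condition = cond,
                       overlap = overlap,
                       rediscovery_inactive = redisc_inactive,
                       rediscovery_cross = redisc_cross,
                       de = de, methylation = meth)
  }
  out
}
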