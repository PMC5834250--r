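# a tiny GCN whose composition strings are chosen by hand
hand_gcn <- function(compositions, sample_ids) {
  n <- length(compositions)
  genes <- sprintf("g%03d", seq_len(n + 1))
  e <- data.frame(gene_a = genes[seq_len(n)], gene_b = genes[n + 1],
                  cluster_index = 0L,
                  n_samples = nchar(compositions[1]),
                  spearman = 0.95, mean_expression = 5,
                  composition = compositions, stringsAsFactors = FALSE)
  swap <- e$gene_a > e$gene_b
  tmp <- e$gene_a[swap]; e$gene_a[swap] <- e$gene_b[swap]; e$gene_b[swap] <- tmp
  attr(e, "sample_ids") <- sample_ids
  class(e) <- c("edge_candidates", "data.frame")
  structure(list(edges = e, threshold = 0.9, source_gem_id = "hand"),
            class = "gcn")
}

hand_module <- function(gcn) {
  e <- gcn$edges
  ed <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                   stringsAsFactors = FALSE)
  structure(list(module_id = "M0001", edges = ed,
                 genes = sort(unique(c(ed$gene_a, ed$gene_b))),
                 n_edges = nrow(ed), n_genes = length(unique(unlist(ed)))),
            class = "link_community_module")
}

test_that("module sample rule requires strictly more than the fraction of edges", {
  ids <- sprintf("S%d", 1:4)
  # sample 1 in 3/3 edges, sample 2 in 2/3, sample 3 in 0/3, sample 4 excluded
  gcn <- hand_gcn(c("1109", "1009", "1109"), ids)
  mod <- hand_module(gcn)
  expect_identical(module_sample_set(mod, gcn), "S1")
  # exactly 95% of 100 edges is excluded by the strict inequality
  comps <- c(rep("19", 95), rep("09", 5))
  gcn100 <- hand_gcn(comps, c("S1", "S2"))
  mod100 <- hand_module(gcn100)
  expect_length(module_sample_set(mod100, gcn100, fraction = 0.95), 0)
  comps96 <- c(rep("19", 96), rep("09", 4))
  gcn96 <- hand_gcn(comps96, c("S1", "S2"))
  expect_identical(module_sample_set(hand_module(gcn96), gcn96), "S1")
  # raising the fraction never grows the sample set
  s80 <- module_sample_set(mod, gcn, fraction = 0.5)
  s95 <- module_sample_set(mod, gcn, fraction = 0.95)
  expect_true(all(s95 %in% s80))
})

test_that("Fisher enrichment p equals the hypergeometric tail sum", {
  expect_equal(fisher_exact_enrichment(rbind(c(10, 0), c(0, 10))),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_enrichment(rbind(c(0, 10), c(10, 0))), 1.0)
  set.seed(5)
  for (i in 1:200) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    cc <- sample(0:25, 1); d <- sample(0:25, 1)
    if (a + b == 0 || a + cc == 0) next
    expect_equal(fisher_exact_enrichment(rbind(c(a, b), c(cc, d))),
                 hyper_tail_p(a, b, cc, d), tolerance = 1e-12)
  }
  # and agrees with the one-sided stats::fisher.test
  tab <- rbind(c(7, 3), c(2, 18))
  expect_equal(fisher_exact_enrichment(tab),
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("condition enrichment flags the planted condition only", {
  g <- make_planted_gem(seed = 2)
  res <- preprocess_gem(g)
  cand <- build_similarity_matrix(res$gem)
  thr <- suppressWarnings(as.numeric(find_rmt_threshold(cand)))
  gcn <- threshold_network(cand, thr)
  mods <- extract_modules(gcn)
  target <- which.max(vapply(mods, function(m)
    length(intersect(m$genes, planted_gene_ids())), 1L))
  enr <- condition_enrichment(mods[[target]], gcn, res$gem)
  expect_lt(enr$p_value[enr$label == "A"], 0.001)
  expect_true(all(enr$p_value[enr$label != "A"] >= 0.001))
  expect_identical(enr$significant, enr$p_value < 0.001)

  # sample ordering must not matter
  perm <- sample(ncol(res$gem$values))
  gem2 <- subset_gem(res$gem, samples = colnames(res$gem$values)[perm])
  enr2 <- condition_enrichment(mods[[target]], gcn, gem2)
  expect_equal(enr2$p_value, enr$p_value, tolerance = 1e-12)
})

test_that("a module supported by every sample cannot be enriched", {
  ids <- sprintf("S%d", 1:6)
  gcn <- hand_gcn(rep("111111", 3), ids)
  mod <- hand_module(gcn)
  m <- matrix(runif(4 * 6, 1, 2), 4,
              dimnames = list(mod$genes, ids))
  g <- gem(m, stats::setNames(rep(c("A", "B"), each = 3), ids))
  enr <- condition_enrichment(mod, gcn, g)
  expect_true(all(enr$p_value == 1))
})

test_that("term enrichment detects exact gene-set matches and degenerate cases", {
  background <- sprintf("g%03d", 1:100)
  mod_genes <- background[1:10]
  ann <- list(hit = background[1:10], miss = background[51:60],
              empty = character(0))
  expect_warning(res <- term_enrichment(mod_genes, ann, background),
                 "empty")
  expect_lt(res$p_value[res$label == "hit"], 0.001)
  expect_equal(res$p_value[res$label == "miss"], 1)
  # module equal to the whole background cannot be enriched
  res_all <- suppressWarnings(
    term_enrichment(background, ann, background))
  expect_true(all(res_all$p_value == 1))
  expect_error(term_enrichment(c("nope"), ann, background), "subset")
})

test_that("annotation maps read from TSV and GMT agree", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("term\tgene", "T1\tg1", "T1\tg2", "T2\tg3"), tsv)
  m1 <- read_annotation_map(tsv)
  expect_identical(m1$T1, c("g1", "g2"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2", "T2\tdesc\tg3"), gmt)
  m2 <- read_annotation_map(gmt, format = "gmt")
  expect_identical(m2, m1)
})
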