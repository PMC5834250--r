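edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = pmin(m[, 1], m[, 2]), gene_b = pmax(m[, 1], m[, 2]),
             stringsAsFactors = FALSE)
}

make_gcn <- function(edges) {
  e <- edges
  e$cluster_index <- 0L
  e$n_samples <- 40L
  e$spearman <- 0.95
  e$mean_expression <- 5
  e$composition <- strrep("1", 10)
  attr(e, "sample_ids") <- sprintf("S%02d", 1:10)
  class(e) <- c("edge_candidates", "data.frame")
  structure(list(edges = e, threshold = 0.9, source_gem_id = "test"),
            class = "gcn")
}

test_that("edge similarity is the Jaccard of inclusive neighbourhoods", {
  tri <- edge_df("a", "b", "a", "c", "b", "c")
  adj <- graph_adjacency(tri)
  expect_equal(edge_similarity(c("a", "c"), c("b", "c"), adj), 1.0)
  withp <- edge_df("a", "b", "a", "c", "b", "c", "c", "d")
  adjp <- graph_adjacency(withp)
  expect_equal(edge_similarity(c("a", "c"), c("d", "c"), adjp), 0.25)
  expect_error(edge_similarity(c("a", "c"), c("a", "c"), adj), "exactly")
  expect_error(edge_similarity(c("a", "b"), c("c", "d"), adjp), "exactly")
})

test_that("partition density matches the closed form on canonical graphs", {
  tri <- edge_df("a", "b", "a", "c", "b", "c")
  expect_equal(partition_density(list(tri), tri), 1.0)
  singletons <- lapply(seq_len(3), function(i) tri[i, , drop = FALSE])
  expect_equal(partition_density(singletons, tri), 0)
  cyc <- edge_df("a", "b", "b", "c", "c", "d", "d", "a")
  expect_equal(partition_density(list(cyc), cyc), 1 / 3)
  expect_error(partition_density(list(tri[1:2, ]), tri), "cover")
  expect_error(partition_density(list(tri, tri[1, , drop = FALSE]), tri),
               "more than once")
})

test_that("module extraction recovers canonical structures", {
  tri <- make_gcn(edge_df("a", "b", "a", "c", "b", "c"))
  mods <- extract_modules(tri)
  expect_length(mods, 1)
  expect_equal(mods[[1]]$n_edges, 3)
  expect_setequal(mods[[1]]$genes, c("a", "b", "c"))

  two_tri <- make_gcn(edge_df("a", "b", "a", "c", "b", "c",
                              "d", "e", "d", "f", "e", "f",
                              "c", "d"))
  mods2 <- extract_modules(two_tri)
  expect_length(mods2, 2)
  expect_setequal(mods2[[1]]$genes, c("a", "b", "c"))
  expect_setequal(mods2[[2]]$genes, c("d", "e", "f"))
  expect_true(all(vapply(mods2, function(m) m$n_edges, 1L) == 3))

  expect_length(extract_modules(make_gcn(edge_df("a", "b"))), 0)
})

test_that("the chosen cut attains the exhaustive-enumeration optimum on K5 subgraphs", {
  # On every connected edge subset of K5 with <= 6 edges the
  # single-linkage cut family contains the globally optimal
  # edge-connected partition, so the cut must attain it. (On sparser
  # 6- and 7-node graphs the global optimum can fall outside the
  # dendrogram family; the family-optimality property below covers
  # those.)
  k5 <- t(combn(letters[1:5], 2))
  cases <- list()
  for (m in 1:6) {
    sets <- combn(nrow(k5), m)
    for (j in seq_len(ncol(sets))) {
      e <- data.frame(gene_a = k5[sets[, j], 1], gene_b = k5[sets[, j], 2],
                      stringsAsFactors = FALSE)
      if (edges_connected(e, seq_len(nrow(e)))) cases[[length(cases) + 1]] <- e
    }
  }
  expect_gt(length(cases), 300)
  for (e in cases) {
    mods <- extract_modules(make_gcn(e), min_module_edges = 1L)
    got <- partition_density(lapply(mods, `[[`, "edges"), e)
    expect_equal(got, oracle_max_density(e), tolerance = 1e-12)
  }
})

test_that("the chosen cut is optimal within the single-linkage family", {
  # independent re-enumeration of every dendrogram cut on random
  # 6-edge subgraphs of K7
  k7 <- t(combn(letters[1:7], 2))
  set.seed(99)
  n_cases <- 0
  for (i in 1:60) {
    idx <- sample(nrow(k7), 6)
    e <- data.frame(gene_a = k7[idx, 1], gene_b = k7[idx, 2],
                    stringsAsFactors = FALSE)
    if (!edges_connected(e, seq_len(nrow(e)))) next
    n_cases <- n_cases + 1
    mods <- extract_modules(make_gcn(e), min_module_edges = 1L)
    got <- partition_density(lapply(mods, `[[`, "edges"), e)
    expect_equal(got, oracle_family_max(e), tolerance = 1e-12)
  }
  expect_gt(n_cases, 30)
})

test_that("modules partition the network's edges and IDs are order-stable", {
  g <- make_log2_gem(seed = 10, n_genes = 40, n_module = 12)
  cand <- build_similarity_matrix(g)
  thr <- suppressWarnings(as.numeric(find_rmt_threshold(cand)))
  gcn <- threshold_network(cand, thr)
  mods <- extract_modules(gcn, min_module_edges = 1L)
  all_edges <- unique(paste(pmin(gcn$edges$gene_a, gcn$edges$gene_b),
                            pmax(gcn$edges$gene_a, gcn$edges$gene_b)))
  got <- unlist(lapply(mods, function(m)
    paste(m$edges$gene_a, m$edges$gene_b)))
  expect_setequal(got, all_edges)
  expect_identical(anyDuplicated(got), 0L)

  gcn2 <- gcn
  gcn2$edges <- gcn$edges[rev(seq_len(nrow(gcn$edges))), , drop = FALSE]
  attr(gcn2$edges, "sample_ids") <- attr(gcn$edges, "sample_ids")
  class(gcn2$edges) <- class(gcn$edges)
  mods2 <- extract_modules(gcn2, min_module_edges = 1L)
  expect_identical(lapply(mods, `[[`, "genes"),
                   lapply(mods2, `[[`, "genes"))
  expect_identical(vapply(mods, `[[`, "", "module_id"),
                   vapply(mods2, `[[`, "", "module_id"))
})
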