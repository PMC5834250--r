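test_that("Fisher-z power analysis reproduces the classic sample sizes", {
  expect_identical(pearson_min_sample_size(0.05, 0.2, 0.5), 30L)
  expect_identical(pearson_min_sample_size(0.05, 0.2, 0.8), 10L)
  expect_identical(pearson_min_sample_size(0.05, 0.2, 0.3), 85L)
  expect_error(pearson_min_sample_size(0.05, 0.2, 0), "infinite")
  # monotone in effect size, alpha and beta
  r <- seq(0.1, 0.9, by = 0.1)
  n_r <- vapply(r, function(x) pearson_min_sample_size(0.05, 0.2, x), 1L)
  expect_true(all(diff(n_r) <= 0))
  expect_gte(pearson_min_sample_size(0.01, 0.2, 0.5),
             pearson_min_sample_size(0.05, 0.2, 0.5))
  expect_gte(pearson_min_sample_size(0.05, 0.1, 0.5),
             pearson_min_sample_size(0.05, 0.2, 0.5))
})

test_that("Spearman correlation follows the rank formula and handles ties", {
  expect_equal(spearman_correlation(1:3, 1:3), 1)
  expect_equal(spearman_correlation(1:3, 3:1), -1)
  expect_equal(spearman_correlation(1:4, c(1, 3, 2, 4)), 0.8)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(25); y <- rnorm(25)
    expect_equal(spearman_correlation(x, y),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(spearman_correlation(exp(x), y^3 + 2 * y),
                 spearman_correlation(x, y), tolerance = 1e-12)
  }
  xt <- c(1, 1, 2, 3, 3, 4); yt <- c(2, 1, 1, 3, 4, 4)
  expect_equal(spearman_correlation(xt, yt),
               cor(xt, yt, method = "spearman"), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

test_that("pairwise GMM separates blobs, keeps unimodal data whole, and agrees with mclust", {
  skip_if_not_installed("mclust")
  suppressWarnings(suppressMessages(library(mclust)))
  set.seed(42)
  x <- c(rnorm(40, 0), rnorm(40, 10)) + 5
  y <- c(rnorm(40, 0), rnorm(40, 10)) + 5
  masks <- pairwise_gmm_cluster(x, y)
  expect_length(masks, 2)
  sizes <- vapply(masks, function(m) sum(m == 1), 1L)
  expect_true(all(abs(sizes - 40) <= 2))
  mfit <- mclust::Mclust(cbind(x, y), G = 1:5, modelNames = "VVV",
                         verbose = FALSE)
  expect_equal(mfit$G, 2)
  # same bipartition (up to component labels)
  ours <- masks[[1]] == 1
  theirs <- mfit$classification == mfit$classification[1]
  expect_true(mean(ours == theirs) > 0.95 || mean(ours != theirs) > 0.95)

  x1 <- rnorm(60, 5); y1 <- rnorm(60, 5)
  expect_length(pairwise_gmm_cluster(x1, y1), 1)
  m1 <- mclust::Mclust(cbind(x1, y1), G = 1:5, modelNames = "VVV",
                       verbose = FALSE)
  expect_equal(m1$G, 1)
})

test_that("pairwise GMM masks partition the included samples", {
  expect_length(pairwise_gmm_cluster(rnorm(20), rnorm(20)), 0)
  set.seed(7)
  x <- c(rnorm(50, 0), rnorm(45, 8), rnorm(40, 16))
  y <- c(rnorm(50, 0), rnorm(45, 8), rnorm(40, 16))
  x[c(3, 17)] <- 0   # excluded sentinels
  masks <- pairwise_gmm_cluster(x, y)
  expect_gte(length(masks), 2)
  codes <- do.call(rbind, masks)
  expect_true(all(codes[, c(3, 17)] == 9L))
  incl <- which(x != 0 & y != 0)
  in_counts <- colSums(codes[, incl, drop = FALSE] == 1L)
  expect_true(all(in_counts <= 1))   # disjoint masks
  expect_true(all(vapply(masks, function(m) sum(m == 1), 1L) >= 30))
})

test_that("composition strings round-trip the ternary sample mask", {
  expect_identical(sample_composition_string(c(1L, 0L, 9L)), "109")
  expect_identical(sample_composition_string(rep(1L, 5)), "11111")
  m <- c(1L, 1L, 0L, 9L, 0L, 1L)
  expect_identical(parse_composition_string(sample_composition_string(m)), m)
  expect_error(sample_composition_string(c(1L, 2L)), "codes")
  expect_error(parse_composition_string("10x"), "invalid")
})

test_that("similarity build enumerates every pair and recovers planted structure", {
  g3 <- generate_random_gem(3, 40, seed = 2)
  v <- g3$values
  nz <- v > 0; v[nz] <- log2(v[nz])
  cand3 <- build_similarity_matrix(gem(v, g3$condition,
                                       scale_tag = "log2_quantile"))
  expect_lte(length(unique(paste(cand3$gene_a, cand3$gene_b))), 3)
  expect_true(all(cand3$gene_a < cand3$gene_b))

  g <- make_log2_gem(seed = 3, n_genes = 30, n_module = 8)
  cand <- build_similarity_matrix(g)
  act <- g$condition == "A"
  planted <- planted_gene_ids(8)
  mp <- cand$gene_a %in% planted & cand$gene_b %in% planted
  strong <- cand[mp & abs(cand$spearman) >= 0.8, , drop = FALSE]
  # every planted pair yields a high-correlation cluster covering the
  # active samples
  expect_equal(length(unique(paste(strong$gene_a, strong$gene_b))),
               choose(8, 2))
  for (r in seq_len(nrow(strong))) {
    mask <- parse_composition_string(strong$composition[r])
    expect_gte(sum(mask == 1 & act) / sum(act), 0.9)
  }
  expect_true(all(cand$n_samples >= 30))
})

test_that("a structureless GEM yields no strong edges", {
  g <- generate_random_gem(40, 60, seed = 11)
  v <- g$values; nz <- v > 0; v[nz] <- log2(v[nz])
  cand <- build_similarity_matrix(gem(v, g$condition,
                                      scale_tag = "log2_quantile"))
  expect_lt(max(abs(cand$spearman)), 0.9)
})

test_that("edge-candidate TSV round-trips with sample order intact", {
  g <- make_log2_gem(seed = 5, n_genes = 12, n_module = 5)
  cand <- build_similarity_matrix(g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_candidates(cand, path)
  back <- read_edge_candidates(path)
  expect_identical(attr(back, "sample_ids"), attr(cand, "sample_ids"))
  expect_equal(back$spearman, cand$spearman, tolerance = 1e-12)
  expect_identical(back$composition, cand$composition)
  expect_identical(back$gene_a, cand$gene_a)
})
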