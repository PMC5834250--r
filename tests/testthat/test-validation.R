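test_that("gene ID mapping handles empty, identity and partial maps", {
  genes <- sprintf("tx%02d", 1:54)
  empty <- data.frame(source_id = character(), target_id = character())
  res <- map_genes(genes, empty)
  expect_length(res$mapped, 0)
  expect_identical(res$unmapped, genes)
  ident <- data.frame(source_id = genes, target_id = genes)
  resi <- map_genes(genes, ident)
  expect_setequal(resi$mapped, genes)
  expect_length(resi$unmapped, 0)
  # 54 inputs with 49 mappable: 49 mapped, 5 unmapped
  partial <- data.frame(source_id = genes[1:49],
                        target_id = sprintf("ENST%02d", 1:49))
  resp <- map_genes(genes, partial)
  expect_length(resp$mapped, 49)
  expect_identical(resp$unmapped, genes[50:54])
  expect_error(map_genes(genes, data.frame(source_id = "", target_id = "x")),
               "empty")
})

test_that("module overlap intersects after mapping", {
  expect_length(module_overlap(c("a", "b"), c("c", "d")), 0)
  expect_setequal(module_overlap(c("a", "b"), c("a", "b")), c("a", "b"))
  im <- data.frame(source_id = c("a", "b"), target_id = c("A", "B"))
  expect_identical(module_overlap(c("a", "b"), c("A", "Z"), im), "A")
})

test_that("mini-GEM extraction subsets genes and conditions", {
  p <- gem_sim_params(80, list(condition_spec("normal", 138),
                               condition_spec("tumor", 38)), seed = 3)
  g <- generate_multicondition_gem(p)
  genes <- sprintf("G%04d", 1:63)
  mini <- extract_mini_gem(g, genes, conditions = "normal")
  expect_equal(dim(mini), c(63L, 138L))
  expect_true(all(mini$condition == "normal"))
  full <- extract_mini_gem(g, genes)
  expect_equal(ncol(full), 176L)
  withmiss <- extract_mini_gem(g, c(genes, "absent1"))
  expect_identical(attr(withmiss, "missing_genes"), "absent1")
  expect_error(extract_mini_gem(g, "absent1"), "no requested genes")
})

test_that("edge rediscovery against the source GEM itself is complete", {
  g <- make_log2_gem(seed = 5, n_genes = 25, n_module = 8)
  cand <- build_similarity_matrix(g)
  thr <- suppressWarnings(as.numeric(find_rmt_threshold(cand)))
  gcn <- threshold_network(cand, thr)
  mods <- extract_modules(gcn)
  mod <- mods[[1]]
  mini <- extract_mini_gem(g, mod$genes)
  mini_cand <- build_similarity_matrix(mini)
  rep <- edge_rediscovery(mod$edges, mini_cand, thr,
                          universe_genes = rownames(mini$values))
  expect_equal(rep$rediscovery_fraction, 1.0)
})

test_that("rediscovery count inequalities hold for random reports", {
  set.seed(12)
  for (i in 1:50) {
    n_mod <- sample(1:400, 1)
    n_map <- sample(0:n_mod, 1)
    n_red <- sample(0:n_map, 1)
    n_abv <- sample(0:n_red, 1)
    rep <- rediscovery_report(n_mod, n_map, n_red, n_abv, 0.86)
    expect_equal(rep$rediscovery_fraction, n_red / n_mod)
    expect_equal(rep$above_threshold_fraction,
                 if (n_red > 0) n_abv / n_red else 0)
  }
  expect_error(rediscovery_report(10, 5, 7, 0, 0.8), "inconsistent")
  expect_error(rediscovery_report(10, 10, 5, 6, 0.8), "inconsistent")
})

test_that("two-sample t-tests match the pooled-variance formula", {
  x <- c(5.1, 4.8, 5.6, 5.0); y <- c(3.9, 4.4, 4.1, 4.2)
  m <- rbind(gA = c(x, y), gB = rep(1, 8))
  colnames(m) <- sprintf("s%d", 1:8)
  g <- gem(m, stats::setNames(rep(c("t", "n"), each = 4), colnames(m)))
  res <- differential_expression_ttest(g, c("gA", "gB"), "t", "n")
  sp <- sqrt(((3) * var(x) + (3) * var(y)) / 6)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 4 + 1 / 4))
  row <- res$per_gene[res$per_gene$gene == "gA", ]
  expect_equal(row$t, t_hand, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(t_hand), df = 6), tolerance = 1e-12)
  expect_identical(row$direction, "up_in_a")
  # identical zero-variance groups are degenerate with t = 0
  rowB <- res$per_gene[res$per_gene$gene == "gB", ]
  expect_equal(rowB$t, 0)
  expect_equal(rowB$p, 1)
  expect_true(rowB$degenerate)
  # label swap flips t but not p
  res2 <- differential_expression_ttest(g, c("gA", "gB"), "n", "t")
  expect_equal(res2$per_gene$t[1], -row$t, tolerance = 1e-12)
  expect_equal(res2$per_gene$p[1], row$p, tolerance = 1e-12)
})

test_that("shifted genes reach significance at n = 50 per group", {
  set.seed(9)
  m <- rbind(matrix(rnorm(5 * 100), 5), matrix(rnorm(5 * 100), 5))
  m[1:5, 1:50] <- m[1:5, 1:50] + 2
  dimnames(m) <- list(sprintf("g%d", 1:10), sprintf("s%d", 1:100))
  g <- gem(m + 20, stats::setNames(rep(c("a", "b"), each = 50),
                                   colnames(m)))
  res <- differential_expression_ttest(g, sprintf("g%d", 1:5), "a", "b")
  expect_true(all(res$per_gene$p < 0.001))
  expect_lt(res$pooled$p, 1e-6)
  expect_identical(res$pooled$direction, "up_in_a")
})

test_that("methylation t-tests report hypo/hyper direction", {
  conds <- list(condition_spec("LGG", 200), condition_spec("GBM", 200))
  b <- generate_methylation_betas(sprintf("g%02d", 1:22), conds, "GBM",
                                  mean_hypo = 0.3, mean_other = 0.6,
                                  seed = 4)
  res <- methylation_ttest(b, sprintf("g%02d", 1:22), "GBM", "LGG")
  expect_true(all(res$per_gene$direction == "hypo_in_a"))
  expect_true(all(res$per_gene$p < 0.001))
  expect_lt(res$pooled$p, 1e-6)
  b2 <- b; b2$condition[] <- rep(c("x", "y"), 200)
  same <- methylation_ttest(
    structure(list(values = cbind(b$values, b$values),
                   condition = stats::setNames(
                     rep(c("x", "y"), each = 400),
                     sprintf("c%d", 1:800))),
              class = "beta_matrix"),
    sprintf("g%02d", 1:22), "x", "y")
  expect_true(all(abs(same$per_gene$t) < 1e-8))
})

test_that("median normalization rescales one condition to unit median", {
  m <- matrix(c(4, 8, 2, 6, 1, 3), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  g <- gem(m, c(s1 = "A", s2 = "A", s3 = "B"))
  out <- median_condition_normalize(g, "A")
  med <- median(c(4, 8, 2, 6))
  expect_equal(attr(out, "median_divisor"), med)
  expect_equal(out$values[, 1:2], m[, 1:2] / med)
  expect_equal(out$values[, 3], m[, 3])
  expect_equal(median(out$values[, 1:2]), 1.0)
  gz <- gem(matrix(0, 1, 2, dimnames = list("g", c("s1", "s2"))),
            c(s1 = "A", s2 = "A"))
  expect_error(median_condition_normalize(gz, "A"), "zero")
})

test_that("rediscovery reports serialize as key-value TSV", {
  rep <- rediscovery_report(154, 154, 70, 0, 0.8801)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rediscovery_report(rep, path)
  df <- read.delim(path)
  expect_equal(df$value[df$key == "rediscovery_fraction"], 70 / 154,
               tolerance = 1e-12)
})
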