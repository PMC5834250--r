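# Independent oracles and fixture builders shared across the suite.

# brute-force two-sample KS statistic: max ECDF gap over the pooled support
brute_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# brute-force one-sided Fisher p: hypergeometric tail by direct summation
hyper_tail_p <- function(a, b, c, d) {
  k_max <- min(a + b, a + c)
  sum(vapply(a:k_max, function(k)
    stats::dhyper(k, a + c, b + d, a + b), 0))
}

# all set partitions of 1..n (restricted-growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_block) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (b in seq_len(next_block))
      rec(c(assign, b), max(next_block, b + 1L))
  }
  rec(integer(0), 1L)
  out
}

# is an edge subset (rows of `edges`) connected as a subgraph?
edges_connected <- function(edges, idx) {
  if (length(idx) <= 1L) return(TRUE)
  sub <- edges[idx, , drop = FALSE]
  nodes <- unique(c(sub$gene_a, sub$gene_b))
  seen <- nodes[1L]
  repeat {
    grow <- unique(c(sub$gene_b[sub$gene_a %in% seen],
                     sub$gene_a[sub$gene_b %in% seen]))
    new <- setdiff(grow, seen)
    if (!length(new)) break
    seen <- c(seen, new)
  }
  length(seen) == length(nodes)
}

# independent partition-density formula (used only by the oracle)
oracle_density <- function(edges, assign) {
  M <- nrow(edges)
  d <- 0
  for (b in unique(assign)) {
    idx <- which(assign == b)
    m_c <- length(idx)
    n_c <- length(unique(c(edges$gene_a[idx], edges$gene_b[idx])))
    if (n_c > 2L) d <- d + m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }
  2 / M * d
}

# exhaustive max partition density over edge-connected partitions
oracle_max_density <- function(edges) {
  best <- 0
  for (assign in all_partitions(nrow(edges))) {
    ok <- all(vapply(unique(assign), function(b)
      edges_connected(edges, which(assign == b)), TRUE))
    if (ok) best <- max(best, oracle_density(edges, assign))
  }
  best
}

# independent re-implementation of the single-linkage cut family:
# max partition density over components of the edge-similarity graph
# thresholded at every height (plus the all-singletons partition)
oracle_family_max <- function(edges) {
  m <- nrow(edges)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  nbr <- lapply(nodes, function(v)
    union(v, unique(c(edges$gene_b[edges$gene_a == v],
                      edges$gene_a[edges$gene_b == v]))))
  names(nbr) <- nodes
  pairs <- list()
  for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
    sh <- intersect(unlist(edges[i, 1:2]), unlist(edges[j, 1:2]))
    if (length(sh) != 1L) next
    u <- setdiff(unlist(edges[i, 1:2]), sh)
    w <- setdiff(unlist(edges[j, 1:2]), sh)
    s <- length(intersect(nbr[[u]], nbr[[w]])) /
      length(union(nbr[[u]], nbr[[w]]))
    pairs[[length(pairs) + 1L]] <- c(i, j, s)
  }
  best <- 0   # all singletons
  if (!length(pairs)) return(best)
  pm <- do.call(rbind, pairs)
  for (h in unique(pm[, 3])) {
    # components of the edge graph linked at similarity >= h
    comp <- seq_len(m)
    repeat {
      changed <- FALSE
      for (r in which(pm[, 3] >= h)) {
        a <- comp[pm[r, 1]]; b <- comp[pm[r, 2]]
        if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
      }
      if (!changed) break
    }
    best <- max(best, oracle_density(edges, comp))
  }
  best
}

# inverse-CDF sampler of the Wigner surmise (pi/2) s exp(-pi s^2 / 4)
rwigner <- function(n) sqrt(-4 / pi * log(1 - stats::runif(n)))

# the suite's standard planted-module GEM: 150 genes, 3 conditions,
# 10-gene module active in condition A (small enough to keep tests
# fast, large enough that the module is a minor fraction of each
# sample's distribution, as in real data)
make_planted_gem <- function(seed = 1L, n_genes = 150L, n_module = 10L,
                             target_correlation = 0.9) {
  params <- gem_sim_params(
    n_genes,
    list(condition_spec("A", 80), condition_spec("B", 80),
         condition_spec("C", 80)),
    planted = list(planted_module_spec(
      seq_len(n_module), "A", target_correlation)),
    seed = seed)
  generate_multicondition_gem(params)
}

planted_gene_ids <- function(n_module = 10L) sprintf("G%04d", seq_len(n_module))

# a small GEM already on the log2 scale (bypasses preprocessing), for
# unit tests of the pairwise stage in isolation
make_log2_gem <- function(seed = 1L, n_genes = 30L, n_module = 8L) {
  g <- make_planted_gem(seed, n_genes, n_module)
  v <- g$values
  nz <- v > 0
  v[nz] <- log2(v[nz])
  gem(v, g$condition, scale_tag = "log2_quantile")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
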