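# Link communities: communities of edges (not nodes). Adjacent edges
# are compared by the Jaccard similarity of the inclusive neighbourhoods
# of their non-shared endpoints; single-linkage agglomeration over edges
# is cut at the height maximizing partition density.

.edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# unique node-pair edges of a gcn (cluster-level rows collapsed)
.gcn_edge_pairs <- function(gcn) {
  e <- gcn$edges
  if (nrow(e) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  unique(data.frame(gene_a = pmin(e$gene_a, e$gene_b),
                    gene_b = pmax(e$gene_a, e$gene_b),
                    stringsAsFactors = FALSE))
}

#' Similarity of two adjacent edges
#'
#' For edges sharing exactly one endpoint, the similarity is the
#' Jaccard index of the inclusive neighbourhoods `n+(v) = {v} union
#' neighbours(v)` of the two non-shared endpoints.
#'
#' @param e1,e2 character vectors of length 2 (the edges' endpoints).
#' @param adjacency named list mapping node -> character vector of its
#'   neighbours (see [graph_adjacency]).
#' @return similarity in \[0, 1\].
#' @export
edge_similarity <- function(e1, e2, adjacency) {
  shared <- intersect(e1, e2)
  if (length(shared) != 1L)
    stop("edge similarity is defined only for edges sharing exactly ",
         "one endpoint (shared: ", length(shared), ")")
  u <- setdiff(e1, shared)
  v <- setdiff(e2, shared)
  nu <- union(u, adjacency[[u]])
  nv <- union(v, adjacency[[v]])
  length(intersect(nu, nv)) / length(union(nu, nv))
}

#' Adjacency list of an edge table
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return named list node -> character vector of neighbours.
#' @export
graph_adjacency <- function(edges) {
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  adj <- c(split(edges$gene_b, edges$gene_a),
           split(edges$gene_a, edges$gene_b))
  out <- lapply(nodes, function(v)
    unique(unlist(adj[names(adj) == v], use.names = FALSE)))
  names(out) <- nodes
  out
}

#' Partition density of an edge partition
#'
#' `D = (2/M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1))` over
#' communities `c` with `m_c` edges and `n_c` nodes; communities with
#' `n_c = 2` (single edges, trees of one link) contribute 0. `M` is the
#' total number of edges. The partition must cover every edge of the
#' graph exactly once.
#'
#' @param partition list of communities, each a data.frame with
#'   columns `gene_a`, `gene_b`.
#' @param graph data.frame of all edges (`gene_a`, `gene_b`).
#' @return the partition density; 1 when every community is a clique,
#'   0 for the all-singletons partition.
#' @export
partition_density <- function(partition, graph) {
  all_keys <- .edge_key(graph$gene_a, graph$gene_b)
  got <- unlist(lapply(partition, function(p)
    .edge_key(p$gene_a, p$gene_b)), use.names = FALSE)
  if (anyDuplicated(got))
    stop("edge covered more than once: ", got[duplicated(got)][1L])
  if (!setequal(got, all_keys) || length(got) != length(all_keys))
    stop("partition must cover every graph edge exactly once")
  M <- length(all_keys)
  contrib <- vapply(partition, function(p) {
    m_c <- nrow(p)
    n_c <- length(unique(c(p$gene_a, p$gene_b)))
    if (n_c <= 2L) return(0)
    m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }, numeric(1))
  2 / M * sum(contrib)
}

# all adjacent-edge-pair similarities of an edge table
# returns data.frame(i, j, sim) with i < j indexing rows of `edges`
.edge_pair_similarities <- function(edges) {
  m <- nrow(edges)
  adj <- graph_adjacency(edges)
  keyrow <- stats::setNames(seq_len(m), .edge_key(edges$gene_a, edges$gene_b))
  # inclusive neighbourhoods, precomputed
  incl <- lapply(names(adj), function(v) union(v, adj[[v]]))
  names(incl) <- names(adj)
  incident <- split(c(seq_len(m), seq_len(m)),
                    c(edges$gene_a, edges$gene_b))
  ii <- integer(0); jj <- integer(0); ss <- numeric(0)
  for (v in names(incident)) {
    es <- sort(unique(incident[[v]]))
    if (length(es) < 2L) next
    cmb <- utils::combn(es, 2L)
    for (q in seq_len(ncol(cmb))) {
      a <- cmb[1L, q]; b <- cmb[2L, q]
      u <- setdiff(c(edges$gene_a[a], edges$gene_b[a]), v)
      w <- setdiff(c(edges$gene_a[b], edges$gene_b[b]), v)
      if (length(u) != 1L || length(w) != 1L) next
      nu <- incl[[u]]; nw <- incl[[w]]
      s <- length(intersect(nu, nw)) / length(union(nu, nw))
      ii <- c(ii, a); jj <- c(jj, b); ss <- c(ss, s)
    }
  }
  df <- data.frame(i = ii, j = jj, sim = ss)
  # a pair of edges can share a node at two... no: sharing 2 endpoints
  # means identical edge; (i,j) pairs are unique per shared node, but
  # two edges share at most one node, so no duplicates arise
  df
}

#' Extract link community modules from a co-expression network
#'
#' Deduplicates the GCN's edges to node pairs, computes all
#' adjacent-edge similarities, agglomerates edges by single linkage
#' (equivalently: connected components of the edge-similarity graph
#' thresholded at each dendrogram height), and cuts at the height
#' maximizing partition density — preferring the highest-similarity
#' height on plateaus, which yields the smallest, tightest modules.
#' Communities with fewer than `min_module_edges` edges are discarded;
#' survivors are named `M0001`, `M0002`, ... in order of decreasing
#' edge count (ties broken by the lexicographically smallest gene).
#'
#' @param gcn a `gcn` object (see [threshold_network]).
#' @param min_module_edges minimum edges per reported module
#'   (default 3, the smallest community with nonzero density).
#' @return list of `link_community_module` objects, each a list with
#'   `module_id`, `edges` (data.frame `gene_a`, `gene_b`), `genes`,
#'   `n_edges`, `n_genes`. Empty list for an empty GCN.
#' @export
extract_modules <- function(gcn, min_module_edges = 3L) {
  edges <- .gcn_edge_pairs(gcn)
  if (nrow(edges) == 0L) return(list())
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  m <- nrow(edges)
  sims <- .edge_pair_similarities(edges)
  heights <- sort(unique(sims$sim), decreasing = TRUE)

  best_density <- 0          # singleton partition scores 0
  best_comp <- seq_len(m)    # each edge its own community
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_a <- edges$gene_a; node_b <- edges$gene_b
  for (h in heights) {
    # union all edge pairs at exactly this height (higher heights are
    # already merged, so components = single-linkage clusters at cut h)
    at_h <- which(abs(sims$sim - h) < 1e-15)
    for (q in at_h) {
      ri <- find(sims$i[q]); rj <- find(sims$j[q])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
    comp <- vapply(seq_len(m), find, integer(1))
    # partition density from component membership
    msize <- table(comp)
    dsum <- 0
    for (cid in names(msize)) {
      idx <- which(comp == as.integer(cid))
      m_c <- length(idx)
      n_c <- length(unique(c(node_a[idx], node_b[idx])))
      if (n_c > 2L)
        dsum <- dsum + m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
    }
    d <- 2 / m * dsum
    if (d > best_density + 1e-12) {
      best_density <- d
      best_comp <- comp
    }
  }

  groups <- split(seq_len(m), best_comp)
  groups <- Filter(function(idx) length(idx) >= min_module_edges, groups)
  if (length(groups) == 0L) return(list())
  ord_key <- lapply(groups, function(idx) {
    genes <- sort(unique(c(node_a[idx], node_b[idx])))
    list(n = length(idx), first_gene = genes[1L])
  })
  o <- order(-vapply(ord_key, `[[`, 0, "n"),
             vapply(ord_key, `[[`, "", "first_gene"))
  groups <- groups[o]
  lapply(seq_along(groups), function(r) {
    idx <- groups[[r]]
    ed <- edges[idx, , drop = FALSE]
    rownames(ed) <- NULL
    genes <- sort(unique(c(ed$gene_a, ed$gene_b)))
    structure(list(module_id = sprintf("M%04d", r), edges = ed,
                   genes = genes, n_edges = nrow(ed),
                   n_genes = length(genes)),
              class = "link_community_module")
  })
}

#' @export
print.link_community_module <- function(x, ...) {
  cat(sprintf("%s: %d edges over %d genes\n", x$module_id, x$n_edges,
              x$n_genes))
  invisible(x)
}

#' Write link community modules as TSV
#'
#' Edge file: one row per (module, edge) with columns `module_id`,
#' `gene_a`, `gene_b`. Summary file: `module_id`, `n_edges`, `n_genes`.
#'
#' @param modules list of modules from [extract_modules].
#' @param path edge TSV path.
#' @param summary_path optional summary TSV path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path, summary_path = NULL) {
  rows <- do.call(rbind, lapply(modules, function(mo)
    data.frame(module_id = mo$module_id, mo$edges,
               stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(module_id = character(), gene_a = character(),
                       gene_b = character(), stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summary_path)) {
    sm <- do.call(rbind, lapply(modules, function(mo)
      data.frame(module_id = mo$module_id, n_edges = mo$n_edges,
                 n_genes = mo$n_genes, stringsAsFactors = FALSE)))
    if (is.null(sm))
      sm <- data.frame(module_id = character(), n_edges = integer(),
                       n_genes = integer())
    utils::write.table(sm, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
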