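# Shared fixtures and independent brute-force oracles.

# small network from "A-B"-style edge strings
net_from_strings <- function(edges, nodes = NULL) {
  parts <- strsplit(edges, "-", fixed = TRUE)
  gene_network(data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                          gene_b = vapply(parts, `[[`, "", 2L)),
               nodes = nodes)
}

path_network <- function(labels) {
  net_from_strings(paste(labels[-length(labels)], labels[-1L], sep = "-"))
}

# adjacency list (named by node) from a gene_network
adj_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$gene_a[i]; b <- net$edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# breadth-first connected components over an explicit vertex subset
oracle_components <- function(vertices, adj) {
  seen <- character()
  comps <- list()
  for (v in vertices) {
    if (v %in% seen) next
    queue <- v
    comp <- character()
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      if (u %in% comp) next
      comp <- c(comp, u)
      nb <- intersect(adj[[u]], vertices)
      queue <- c(queue, setdiff(nb, comp))
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

# all-pairs BFS distance between two nodes (Inf when unreachable)
oracle_bfs_dist <- function(adj, from, to) {
  if (from == to) return(0)
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  unname(dist[to])
}

# DPI oracle: enumerate all triangles, mark weakest-edge removals against
# the original edge set, remove simultaneously
oracle_dpi <- function(mi_edges, tolerance = 0) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mi_map <- stats::setNames(mi_edges$mi, key(mi_edges$gene_a, mi_edges$gene_b))
  nodes <- sort(unique(c(mi_edges$gene_a, mi_edges$gene_b)))
  drop <- character()
  if (length(nodes) >= 3L) {
    for (tri in utils::combn(nodes, 3L, simplify = FALSE)) {
      ks <- c(key(tri[1L], tri[2L]), key(tri[1L], tri[3L]),
              key(tri[2L], tri[3L]))
      if (!all(ks %in% names(mi_map))) next
      m <- mi_map[ks]
      weakest <- which(m == min(m))
      if (length(weakest) == 1L &&
          m[weakest] < (1 - tolerance) * min(m[-weakest])) {
        drop <- c(drop, ks[weakest])
      }
    }
  }
  keep <- !(key(mi_edges$gene_a, mi_edges$gene_b) %in% drop)
  mi_edges[keep, , drop = FALSE]
}

# score of one active-state under the annealing objective, independent of
# the C++ implementation
oracle_state_score <- function(active, adj, z, cal, n_modules) {
  if (length(active) == 0L) return(0)
  comps <- oracle_components(active, adj)
  sas <- vapply(comps, function(g) {
    k <- length(g)
    if (cal$sigma[k] <= 0) return(0)
    (sum(z[g]) / sqrt(k) - cal$mu[k]) / cal$sigma[k]
  }, numeric(1L))
  sum(sort(sas, decreasing = TRUE)[seq_len(min(n_modules, length(sas)))])
}

# exhaustive optimum over all active states of a small network
oracle_sa_optimum <- function(net, gene_p, n_modules) {
  adj <- adj_list(net)
  z <- stats::setNames(netsig:::node_zscores(net, gene_p), net$nodes)
  cal <- netsig:::exact_calibration(z)
  nodes <- net$nodes
  best <- -Inf
  best_states <- list()
  for (mask in 0:(2^length(nodes) - 1L)) {
    active <- nodes[bitwAnd(bitwShiftR(mask, seq_along(nodes) - 1L), 1L) == 1L]
    sc <- oracle_state_score(active, adj, z, cal, n_modules)
    if (sc > best + 1e-12) {
      best <- sc
      best_states <- list(active)
    } else if (abs(sc - best) <= 1e-12) {
      best_states[[length(best_states) + 1L]] <- active
    }
  }
  list(score = best, states = best_states, z = z, cal = cal, adj = adj)
}

# random expression fixture
random_expression <- function(n_genes, n_case, n_ctrl, seed, mu = 100,
                              phi = 0.1) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_genes * (n_case + n_ctrl),
                                  mu = mu, size = 1 / phi),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)), NULL))
  colnames(counts) <- c(sprintf("CA%02d", seq_len(n_case)),
                        sprintf("CO%02d", seq_len(n_ctrl)))
  expression_matrix(counts, rep(c("case", "control"), c(n_case, n_ctrl)))
}
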