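test_that("edge canonicalization collapses duplicates and drops self-loops", {
  expect_message(
    net <- gene_network(data.frame(gene_a = c("a", "b", "a", "a"),
                                   gene_b = c("b", "a", "a", "b"))),
    "self-loop")
  expect_equal(net$nodes, c("A", "B"))
  expect_equal(n_edges(net), 1L)
  expect_equal(net$n_self_loops_dropped, 1L)
})

test_that("edge-list write/read round-trips the canonical form", {
  cfg <- sim_config(seed = 3, n_genes = 60, module_size = 8, n_seeds = 3)
  net <- simulate_interactome(cfg)$network
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(back$nodes, sort(unique(c(net$edges$gene_a, net$edges$gene_b))))
  expect_equal(back$edges$gene_a, net$edges$gene_a)
  expect_equal(back$edges$gene_b, net$edges$gene_b)
  expect_equal(back$edges$source, net$edges$source)
})

test_that("malformed edge-list rows raise a parse error naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C\tD", "E"), path)
  expect_error(read_edge_list(path), "line 3", class = "netsig_parse_error")
  writeLines(character(), path)
  expect_warning(empty <- read_edge_list(path), "empty")
  expect_equal(n_nodes(empty), 0L)
  expect_equal(n_edges(empty), 0L)
})

test_that("merge takes the union and tags shared edges with both sources", {
  phys <- net_from_strings("A-B")
  coex <- gene_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")),
                       source_tag = "coexpression")
  m <- merge_networks(phys, coex)
  expect_equal(n_nodes(m), 3L)
  expect_equal(n_edges(m), 2L)
  ab <- m$edges[m$edges$gene_a == "A" & m$edges$gene_b == "B", ]
  expect_equal(ab$source, "both")

  disj <- merge_networks(net_from_strings("A-B"),
                         gene_network(data.frame(gene_a = "X", gene_b = "Y"),
                                      source_tag = "coexpression"))
  expect_equal(n_edges(disj), 2L)
})

test_that("merge is commutative and idempotent on edge sets", {
  set.seed(11)
  e1 <- data.frame(gene_a = sample(LETTERS[1:8], 12, TRUE),
                   gene_b = sample(LETTERS[1:8], 12, TRUE))
  e1 <- e1[e1$gene_a != e1$gene_b, ]
  e2 <- data.frame(gene_a = sample(LETTERS[4:12], 12, TRUE),
                   gene_b = sample(LETTERS[4:12], 12, TRUE))
  e2 <- e2[e2$gene_a != e2$gene_b, ]
  a <- gene_network(e1)
  b <- gene_network(e2, source_tag = "coexpression")
  ab <- merge_networks(a, b)
  ba <- merge_networks(b, a)
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  expect_setequal(key(ab), key(ba))
  expect_setequal(key(merge_networks(a, a)), key(a))
})

test_that("power-law fit recovers a known exponent and guards degeneracy", {
  # inverse-CDF draws from a discrete power law, alpha = 2.5, xmin = 2
  set.seed(42)
  u <- runif(10000)
  degs <- floor((2 - 0.5) * (1 - u)^(-1 / 1.5) + 0.5)
  degs <- degs[degs >= 2]
  fit <- power_law_fit(degs, xmin = 2)
  expect_gt(fit$alpha, 2.4)
  expect_lt(fit$alpha, 2.6)

  expect_error(power_law_fit(c(2, 2, 2, 2), xmin = 2),
               class = "netsig_degenerate_input")
  # star graph: all leaves have degree 1
  star <- net_from_strings(paste0("H-L", 1:6))
  expect_error(power_law_fit(igraph::degree(as_igraph(star))[-1], xmin = 1),
               class = "netsig_degenerate_input")
  expect_error(power_law_fit(c(5), xmin = 2),
               class = "netsig_insufficient_data")
})

test_that("largest connected component follows the induced-subgraph rule", {
  net <- path_network(c("a", "b", "c", "d"))
  expect_equal(largest_connected_component(net, c("a", "b", "d")),
               c("A", "B"))
  # all isolated: lexicographically smallest singleton
  expect_equal(largest_connected_component(net, c("d", "b")), "B")
  expect_equal(largest_connected_component(net, character()), character())
})

test_that("largest connected component matches a brute-force BFS oracle", {
  for (s in 1:25) {
    set.seed(s)
    g <- igraph::sample_gnp(20, 0.2)
    el <- igraph::as_edgelist(g)
    labs <- sprintf("N%02d", 1:20)
    net <- gene_network(data.frame(gene_a = labs[el[, 1]],
                                   gene_b = labs[el[, 2]]), nodes = labs)
    genes <- sample(labs, 8)
    comps <- oracle_components(sort(genes), adj_list(net))
    sizes <- lengths(comps)
    expected <- comps[sizes == max(sizes)]
    expected <- expected[order(vapply(expected, `[[`, "", 1L))][[1L]]
    expect_equal(largest_connected_component(net, genes), expected)
  }
})

test_that("LCC size is monotone under gene-set growth", {
  cfg <- sim_config(seed = 5, n_genes = 80, module_size = 10, n_seeds = 3)
  net <- simulate_interactome(cfg)$network
  set.seed(9)
  genes <- sample(net$nodes, 10)
  s1 <- length(largest_connected_component(net, genes))
  for (extra in list(5, 15, 30)) {
    bigger <- union(genes, sample(net$nodes, extra))
    expect_gte(length(largest_connected_component(net, bigger)), s1)
  }
})

test_that("interactome coverage is a percentage of the reference count", {
  expect_equal(interactome_coverage(455302, 650000), 100 * 455302 / 650000)
  expect_equal(round(interactome_coverage(455302)), 70)
})
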