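test_that("p-to-z conversion matches normal quantiles and clamps extremes", {
  expect_equal(gene_zscore(0.5), 0)
  expect_equal(gene_zscore(0.05), 1.6449, tolerance = 1e-4)
  expect_warning(z <- gene_zscore(1e-300), "clamped")
  expect_equal(z, qnorm(1 - 1e-12), tolerance = 1e-6)
  expect_equal(round(z, 3), 7.034)
})

test_that("the aggregate score is sum over root-k", {
  expect_equal(subnetwork_score(c(1.6449, 1.6449)), 2 * 1.6449 / sqrt(2),
               tolerance = 1e-9)
  expect_equal(round(subnetwork_score(c(1.6449, 1.6449)), 4), 2.3262)
  expect_equal(subnetwork_score(0), 0)
})

test_that("Monte-Carlo calibration matches normal theory under uniform p", {
  # edges are irrelevant to calibration; a large node set keeps the
  # population mean of the z-scores near zero
  labs <- sprintf("G%04d", 1:5000)
  net <- gene_network(nodes = labs)
  set.seed(99)
  gene_p <- setNames(runif(5000), labs)
  set.seed(100)
  cal <- calibrate_score(net, gene_p, k = 10, n_samples = 5000)
  expect_lt(abs(cal$mu_k), 0.1)
  expect_gt(cal$sigma_k, 0.85)
  expect_lt(cal$sigma_k, 1.15)
  # and agrees with the exact finite-population moments
  z <- netsig:::node_zscores(net, gene_p)
  exact <- netsig:::exact_calibration(z)
  expect_lt(abs(cal$mu_k - exact$mu[10]), 0.05)
  expect_lt(abs(cal$sigma_k - exact$sigma[10]), 0.05)
})

test_that("degenerate calibration is reported", {
  net <- net_from_strings(c("A-B", "B-C"))
  gene_p <- setNames(rep(0.5, 3), net$nodes)
  expect_error(calibrate_score(net, gene_p, k = 3, n_samples = 100),
               class = "netsig_degenerate_calibration")
})

test_that("annealing reaches the exhaustive optimum on small graphs", {
  for (s in 1:10) {
    set.seed(s)
    n <- 9
    g <- igraph::sample_gnp(n, 0.35)
    labs <- sprintf("N%d", seq_len(n))
    el <- igraph::as_edgelist(g)
    net <- gene_network(data.frame(gene_a = labs[el[, 1]],
                                   gene_b = labs[el[, 2]]), nodes = labs)
    gene_p <- setNames(ifelse(runif(n) < 0.3, 10^-runif(n, 3, 8),
                              runif(n, 0.5, 1)), labs)
    oracle <- oracle_sa_optimum(net, gene_p, n_modules = 3)
    am <- suppressWarnings(
      jactivemodules_run(net, gene_p, iterations = 2e4, n_modules = 3,
                         seed = s + 100))
    expect_equal(attr(am, "best_score"), oracle$score, tolerance = 1e-9)
  }
})

test_that("a planted stretch of strong p-values is found on a path graph", {
  labs <- sprintf("P%02d", 1:10)
  net <- path_network(labs)
  gene_p <- setNames(rep(0.99, 10), labs)
  gene_p[c("P04", "P05", "P06")] <- 1e-6
  oracle <- oracle_sa_optimum(net, gene_p, n_modules = 5)
  am <- jactivemodules_run(net, gene_p, iterations = 1e4, seed = 5)
  expect_equal(attr(am, "best_score"), oracle$score, tolerance = 1e-9)
  # every reported hotspot lies inside the planted low-p stretch
  expect_true(all(unlist(lapply(am, `[[`, "genes")) %in%
                    c("P04", "P05", "P06")))
})

test_that("equal p-values give calibrated scores of exactly zero", {
  cfg <- sim_config(seed = 16, n_genes = 60, module_size = 8, n_seeds = 3)
  net <- simulate_interactome(cfg)$network
  gene_p <- setNames(rep(0.3, 60), net$nodes)
  am <- jactivemodules_run(net, gene_p, iterations = 2000, seed = 1)
  expect_true(all(vapply(am, `[[`, numeric(1L), "sA") == 0))
})

test_that("the search is deterministic given its seed", {
  cfg <- sim_config(seed = 17, n_genes = 80, module_size = 10, n_seeds = 3)
  net <- simulate_interactome(cfg)$network
  set.seed(3)
  gene_p <- setNames(runif(80)^3, net$nodes)
  a <- jactivemodules_run(net, gene_p, iterations = 5000, seed = 42)
  b <- jactivemodules_run(net, gene_p, iterations = 5000, seed = 42)
  expect_identical(a, b)
})

test_that("reported module scores are internally consistent", {
  cfg <- sim_config(seed = 18, n_genes = 100, module_size = 12, n_seeds = 4)
  net <- simulate_interactome(cfg)$network
  set.seed(4)
  gene_p <- setNames(runif(100)^2, net$nodes)
  am <- jactivemodules_run(net, gene_p, iterations = 5000, seed = 9)
  z <- setNames(netsig:::node_zscores(net, gene_p), net$nodes)
  cal <- netsig:::exact_calibration(z)
  for (m in am) {
    za <- subnetwork_score(z[m$genes])
    expect_equal(m$zA, unname(za), tolerance = 1e-9)
    sa <- if (cal$sigma[m$k] > 0) (za - cal$mu[m$k]) / cal$sigma[m$k] else 0
    expect_equal(m$sA, unname(sa), tolerance = 1e-9)
  }
})

test_that("the two-pass search refines within the first-pass genes", {
  cfg <- sim_config(seed = 19, n_genes = 150, module_size = 20, n_seeds = 5)
  study <- simulate_study(cfg)
  st <- nb_wald_test(study$expr)
  gene_p <- setNames(st$p, st$gene)
  rs <- recursive_search(study$network, gene_p, iterations = 5000, seed = 2)
  expect_true(all(rs$hsn2_genes %in% rs$hsn1_genes))

  expect_warning(empty <- jactivemodules_run(study$network, numeric()),
                 "no gene-level p-values")
  expect_length(empty, 0L)
})

test_that("signature combination intersects discovery with DE support", {
  # worked overlap arithmetic
  deg <- sprintf("g%03d", 1:420)
  diamond <- sprintf("g%03d", 1:39)
  hsn2 <- sprintf("g%03d", 20:420)
  sig <- combine_signatures(diamond, hsn2, deg)
  expect_equal(nrow(sig), 420L)
  expect_equal(sum(sig$provenance == "both"), 20L)
  expect_equal(sum(sig$provenance == "diamond"), 19L)
  expect_equal(sum(sig$provenance == "jactivemodules"), 381L)

  expect_equal(nrow(combine_signatures(diamond, hsn2, character())), 0L)
  one <- combine_signatures("g", "g", "g")
  expect_equal(one$gene, "G")
  expect_equal(one$provenance, "both")
})
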