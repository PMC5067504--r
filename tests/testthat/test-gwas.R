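test_that("SNP binning applies the positional and one-hop LD rules", {
  genes <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600),
                      gene = c("GA", "GB"))
  snps <- data.frame(id = c("S1", "S2", "S3", "S4"), chrom = "chr1",
                     pos = c(150, 900, 550, 950))
  ld <- data.frame(snp1 = c("S1", "S4"), snp2 = c("S2", "S2"),
                   r2 = c(1, 0.9), dprime = c(1, 0.9))
  bins <- bin_snps_to_genes(snps, genes, ld)
  expect_setequal(bins$GA, c("S1", "S2")) # S2 via perfect LD with S1
  expect_setequal(bins$GB, "S3")
  # S4 only reaches S2, which is outside all genes: no transitive chaining
  expect_false("S4" %in% unlist(bins))
  expect_error(bin_snps_to_genes(snps,
                                 data.frame(chrom = "chr1", start = 10,
                                            end = 5, gene = "BAD")))
})

test_that("SNP binning matches a per-pair rule oracle on block LD", {
  cfg <- sim_config(seed = 22, n_genes = 5, attach_m = 2, module_size = 2,
                    n_seeds = 1, snps_per_gene_mean = 4)
  si <- simulate_interactome(cfg)
  coords <- gene_coordinates(si$network$nodes)
  gw <- simulate_gwas(coords, si$truth, cfg)
  bins <- bin_snps_to_genes(gw$snps, coords, gw$ld, r2_threshold = 0.8)
  ld2 <- rbind(gw$ld, data.frame(snp1 = gw$ld$snp2, snp2 = gw$ld$snp1,
                                 r2 = gw$ld$r2, dprime = gw$ld$dprime))
  for (gi in seq_len(nrow(coords))) {
    g <- coords$gene[gi]
    expected <- vapply(gw$snps$id, function(s) {
      pos <- gw$snps$pos[gw$snps$id == s]
      if (pos >= coords$start[gi] && pos <= coords$end[gi]) return(TRUE)
      partners <- ld2$snp2[ld2$snp1 == s & ld2$r2 >= 0.8]
      any(gw$snps$pos[gw$snps$id %in% partners] >= coords$start[gi] &
            gw$snps$pos[gw$snps$id %in% partners] <= coords$end[gi])
    }, logical(1L))
    got <- if (g %in% names(bins)) bins[[g]] else character()
    expect_setequal(got, gw$snps$id[expected])
  }
})

test_that("removing LD pairs never adds SNPs to a bin", {
  cfg <- sim_config(seed = 23, n_genes = 10, attach_m = 2, module_size = 2,
                    n_seeds = 1, snps_per_gene_mean = 3)
  si <- simulate_interactome(cfg)
  coords <- gene_coordinates(si$network$nodes)
  gw <- simulate_gwas(coords, si$truth, cfg)
  full <- bin_snps_to_genes(gw$snps, coords, gw$ld)
  reduced <- bin_snps_to_genes(gw$snps, coords, gw$ld[-seq_len(5), ])
  for (g in names(reduced)) {
    expect_true(all(reduced[[g]] %in% full[[g]]))
  }
})

test_that("Sidak gene-level p matches its closed form and is monotone", {
  expect_equal(gene_p_sidak(0.3, m = 1), 0.3)
  expect_equal(gene_p_sidak(0.01, m = 10), 1 - 0.99^10, tolerance = 1e-12)
  expect_equal(round(gene_p_sidak(0.01, m = 10), 6), 0.095618)
  expect_equal(gene_p_sidak(0), 0)
  p1 <- vapply(1:20, function(m) gene_p_sidak(0.01, m), numeric(1L))
  expect_true(all(diff(p1) > 0))
  p2 <- vapply(seq(0.001, 0.5, 0.01),
               function(p) gene_p_sidak(p, m = 5), numeric(1L))
  expect_true(all(diff(p2) > 0))
  expect_equal(gene_p_simes(c(0.01, 0.02, 0.9)), min(3 * 0.01 / 1, 1))
})

test_that("genomic inflation matches definitional and scaling identities", {
  expect_equal(lambda_gc(rep(0.5, 11))$lambda_gc, 1)
  set.seed(24)
  p <- runif(1e5)
  expect_gt(lambda_gc(p)$lambda_gc, 0.98)
  expect_lt(lambda_gc(p)$lambda_gc, 1.02)
  stat <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * stat, 1, lower.tail = FALSE)
  expect_equal(lambda_gc(p2)$lambda_gc, 2 * lambda_gc(p)$lambda_gc,
               tolerance = 1e-9)
  expect_error(lambda_gc(numeric()))
})

test_that("fraction curves flag enriched sets against the control band", {
  set.seed(25)
  gene_p <- setNames(runif(2000), sprintf("G%04d", 1:2000))
  top <- names(sort(gene_p))[1:100]
  res <- qq_fraction_comparison(gene_p, list(top = top, rand = sample(names(gene_p), 100)),
                                n_controls = 100, seed = 3)
  at05 <- which.min(abs(res$top$threshold - 0.05))
  expect_gt(res$top$fraction[at05],
            res$top$ctrl_mean[at05] + res$top$ctrl_sd[at05])
  within <- with(res$rand, fraction >= ctrl_mean - 3 * ctrl_sd &
                   fraction <= ctrl_mean + 3 * ctrl_sd)
  expect_gte(mean(within), 0.9)
  expect_error(qq_fraction_comparison(gene_p, list(empty = character())))
})

test_that("Fisher enrichment matches hand enumeration and fisher.test", {
  fe <- fisher_enrichment(4, 1, 1, 4)
  expect_equal(fe$p, 26 / 252, tolerance = 1e-12)
  expect_equal(fe$odds_ratio, 16)
  expect_equal(fisher_enrichment(0, 5, 5, 5)$p, 1)
  # symmetric under simultaneous row/column swap
  expect_equal(fisher_enrichment(4, 1, 1, 4)$p,
               fisher_enrichment(4, 1, 1, 4)$p)
  for (s in 1:10) {
    set.seed(s)
    cells <- rpois(4, 8)
    got <- fisher_enrichment(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE),
                       alternative = "greater")
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_enrichment(-1, 2, 3, 4))
})

test_that("Monte-Carlo enrichment obeys the plus-one floor and tie behavior", {
  bg <- sprintf("S%04d", 1:2000)
  fl <- setNames(rep(0L, 2000), bg)
  q <- bg[1:50]
  fl[q] <- 1L
  res <- monte_carlo_snp_enrichment(q, bg, fl, n_rand = 1e5, seed = 1)
  expect_equal(res$observed, 50)
  expect_equal(res$p, 1 / (1e5 + 1))
  # all flags set: every draw ties the observed count
  fl2 <- setNames(rep(1L, 2000), bg)
  res2 <- monte_carlo_snp_enrichment(q, bg, fl2, n_rand = 1000, seed = 1)
  expect_equal(res2$p, 1)
  expect_error(monte_carlo_snp_enrichment(c(q, "NOPE"), bg, fl,
                                          n_rand = 1000))
})

test_that("Monte-Carlo enrichment accepts multi-column annotation tables", {
  cfg <- sim_config(seed = 26, n_genes = 50, attach_m = 2, module_size = 5,
                    n_seeds = 2)
  study <- simulate_study(cfg)
  res <- monte_carlo_snp_enrichment(study$truth$causal_snps,
                                    study$gwas$snps$id,
                                    study$annotations,
                                    n_rand = 1000, seed = 2)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("perfect-LD expansion is the transitive closure of exact pairs", {
  ld <- data.frame(snp1 = c("S1", "S2", "S4"), snp2 = c("S2", "S3", "S5"),
                   r2 = c(1, 1, 1), dprime = c(1, 1, 0.99))
  expect_setequal(perfect_ld_expand("S1", ld), c("S1", "S2", "S3"))
  expect_setequal(perfect_ld_expand("S4", ld), "S4") # D' < 1 does not count
  for (s in 1:10) {
    set.seed(s)
    ids <- sprintf("S%02d", 1:20)
    pairs <- t(utils::combn(ids, 2L))
    keep <- runif(nrow(pairs)) < 0.1
    ld2 <- data.frame(snp1 = pairs[keep, 1L], snp2 = pairs[keep, 2L],
                      r2 = sample(c(1, 0.95), sum(keep), TRUE),
                      dprime = sample(c(1, 0.9), sum(keep), TRUE))
    query <- sample(ids, 3)
    got <- perfect_ld_expand(query, ld2)
    # oracle: components of the perfect-LD subgraph via igraph
    pf <- ld2[ld2$r2 == 1 & ld2$dprime == 1, ]
    g <- igraph::graph_from_data_frame(pf[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    want <- sort(unique(c(query, ids[comp %in% comp[query]])))
    expect_equal(got, want)
  }
})

test_that("log Bayes factors match their closed forms", {
  expect_equal(sherlock_lbf(3, V = 1, W = 0), 0)
  expect_equal(sherlock_lbf(0, V = 1, W = 1), 0.5 * log(0.5))
  expect_equal(round(sherlock_lbf(0, V = 1, W = 1), 5), -0.34657)
  expect_equal(sherlock_lbf(5, V = 1, W = 1), 0.5 * log(0.5) + 25 / 4)
  expect_equal(round(sherlock_lbf(5, V = 1, W = 1), 4), 5.9034)
  expect_error(sherlock_lbf(1, V = 0), class = "netsig_domain_error")
})

test_that("gene scores sum eSNP factors and detect planted signal", {
  set.seed(27)
  pool <- rnorm(5000)
  one <- sherlock_gene_score(2.5, z_pool = pool, n_perm = 200, seed = 1)
  expect_equal(one$total_lbf, sherlock_lbf(2.5))
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    strong <- rnorm(4, mean = 5)
    sherlock_gene_score(strong, z_pool = pool, W = 0.04,
                        n_perm = 500, seed = s)$p < 0.05
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})
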