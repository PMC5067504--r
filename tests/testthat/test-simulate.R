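test_that("preferential attachment yields the forced edge count and a connected module", {
  cfg <- sim_config(seed = 1, n_genes = 200, attach_m = 3, module_size = 20,
                    module_wiring_prob = 0)
  res <- simulate_interactome(cfg)
  expect_equal(n_nodes(res$network), 200L)
  expect_equal(n_edges(res$network), 3L * 197L)
  expect_length(res$truth$module_genes, 20L)
  expect_equal(largest_connected_component(res$network,
                                           res$truth$module_genes),
               res$truth$module_genes)
  expect_true(all(res$truth$seed_genes %in% res$truth$module_genes))
  expect_true(all(res$truth$module_genes %in% res$truth$effect_genes))
})

test_that("the interactome generator is deterministic given the seed", {
  cfg <- sim_config(seed = 7, n_genes = 120, module_size = 12, n_seeds = 4)
  a <- simulate_interactome(cfg)
  b <- simulate_interactome(cfg)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$truth, b$truth)
})

test_that("generated interactomes have a power-law degree exponent in range", {
  alphas <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 2000, attach_m = 3,
                      module_size = 20, module_wiring_prob = 0)
    # fit the tail above the attachment minimum (every new node enters with
    # degree attach_m = 3)
    power_law_fit(simulate_interactome(cfg)$network, xmin = 5)$alpha
  }, numeric(1L))
  expect_true(all(alphas >= 2.2 & alphas <= 3.8))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(module_size = 50, n_genes = 40),
               class = "netsig_invalid_config")
  expect_error(sim_config(n_seeds = 40, module_size = 30),
               class = "netsig_invalid_config")
  expect_error(sim_config(dispersion = 0), class = "netsig_invalid_config")
  expect_error(sim_config(neighbor_effect_prob = 1.5))
})

test_that("expression counts are nonnegative integers with planted fold changes", {
  cfg <- sim_config(seed = 2, n_genes = 300, module_size = 25, n_seeds = 5,
                    lfc_effect = 2, coexpr_strength = 0)
  si <- simulate_interactome(cfg)
  ex <- simulate_expression(si$network, si$truth, cfg)
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == floor(ex$counts)))
  expect_equal(dim(ex$counts), c(300L, 20L))
  st <- nb_wald_test(ex)
  med <- median(st$log2fc[st$gene %in% si$truth$module_genes])
  expect_lt(abs(med - 2), 0.5)
})

test_that("null expression yields few BH-significant calls", {
  rates <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 500, module_size = 10, n_seeds = 2,
                      lfc_effect = 0, neighbor_effect_prob = 0,
                      coexpr_strength = 0)
    si <- simulate_interactome(cfg)
    ex <- simulate_expression(si$network, si$truth, cfg)
    st <- dge_stats(nb_wald_test(ex))
    mean(st$padj < 0.05)
  }, numeric(1L))
  expect_true(all(rates <= 0.07))
})

test_that("GWAS generator produces valid p-values, causal placement, and LD blocks", {
  cfg <- sim_config(seed = 4, n_genes = 150, module_size = 15, n_seeds = 5)
  si <- simulate_interactome(cfg)
  coords <- gene_coordinates(si$network$nodes)
  gw <- simulate_gwas(coords, si$truth, cfg)
  expect_true(all(gw$snps$p > 0 & gw$snps$p <= 1))
  # ground-truth consistency: every causal SNP lies inside a module gene
  causal <- gw$snps[gw$snps$causal, ]
  for (i in seq_len(nrow(causal))) {
    gi <- coords[coords$gene == causal$gene[i], ]
    expect_true(causal$pos[i] >= gi$start && causal$pos[i] <= gi$end)
    expect_true(causal$gene[i] %in% si$truth$module_genes)
  }
  # LD pairs stay within blocks of consecutive SNPs and include perfect LD
  expect_true(all(gw$ld$r2 >= 0 & gw$ld$r2 <= 1))
  expect_true(any(gw$ld$r2 == 1 & gw$ld$dprime == 1))
  idx <- match(gw$ld$snp1, gw$snps$id)
  jdx <- match(gw$ld$snp2, gw$snps$id)
  expect_true(all((idx - 1) %/% cfg$ld_block_size ==
                    (jdx - 1) %/% cfg$ld_block_size))
})

test_that("null GWAS shows no genomic inflation; strong signal reaches significance", {
  lambdas <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 400, module_size = 10, n_seeds = 2,
                      gwas_ncp = 0)
    si <- simulate_interactome(cfg)
    gw <- simulate_gwas(gene_coordinates(si$network$nodes), si$truth, cfg)
    lambda_gc(gw$snps$p)$lambda_gc
  }, numeric(1L))
  expect_true(all(lambdas >= 0.9 & lambdas <= 1.1))

  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_genes = 200, module_size = 20, n_seeds = 5,
                      gwas_ncp = 6)
    si <- simulate_interactome(cfg)
    gw <- simulate_gwas(gene_coordinates(si$network$nodes), si$truth, cfg)
    any(gw$snps$causal & gw$snps$p < GENOME_WIDE_SIG)
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("annotation flags are binary and eQTLs prefer module genes", {
  cfg <- sim_config(seed = 6, n_genes = 200, module_size = 20, n_seeds = 5)
  si <- simulate_interactome(cfg)
  gw <- simulate_gwas(gene_coordinates(si$network$nodes), si$truth, cfg)
  ann <- simulate_annotations(gw, si$truth, cfg)
  flags <- as.matrix(ann$annotations[, -1L])
  expect_true(all(flags %in% c(0L, 1L)))
  mod_rate <- mean(si$truth$module_genes %in% ann$eqtl$gene)
  other <- setdiff(si$network$nodes, si$truth$module_genes)
  other_rate <- mean(other %in% ann$eqtl$gene)
  expect_gt(mod_rate, other_rate)
})

test_that("comorbidity generator emits RR metadata and overlapping symptom vectors", {
  cfg <- sim_config(seed = 8, n_genes = 150, module_size = 20, n_seeds = 5,
                    shared_gene_rate = 0.5)
  si <- simulate_interactome(cfg)
  como <- simulate_comorbidity(si$network$nodes, si$truth, cfg)
  expect_length(como$diseases, cfg$n_comorbid_diseases)
  for (d in como$diseases) {
    expect_gt(d$rr, 0)
    expect_gt(length(d$genes), 0L)
  }
  expect_true("FOCAL" %in% como$symptoms$disease)
})

test_that("a complete study is bit-reproducible on disk", {
  cfg <- sim_config(seed = 9, n_genes = 100, module_size = 10, n_seeds = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("GMT round trip preserves gene sets and relative-risk metadata", {
  cfg <- sim_config(seed = 10, n_genes = 80, module_size = 10, n_seeds = 3)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_gmt(file.path(dir, "comorbid.gmt"))
  expect_length(back, cfg$n_comorbid_diseases)
  orig <- study$comorbidity$diseases[[1L]]
  expect_equal(back[[1L]]$genes, orig$genes)
  expect_equal(back[[1L]]$rr, orig$rr, tolerance = 1e-4)
  expect_equal(back[[1L]]$rr_ci_low, orig$rr_ci_low, tolerance = 1e-4)
})
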