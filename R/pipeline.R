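#' Run the full signature-discovery analysis on a synthetic study
#'
#' Executes every stage in order: study simulation, mutual-information
#' co-expression network, merge with the physical interactome,
#' differential expression, DIAMOnD seed expansion, two-pass active-module
#' search, combination into DE-supported signatures, module topology
#' statistics, GWAS integration (LD binning, gene-level p, genomic
#' inflation, control-set comparison, Fisher and Monte-Carlo enrichment,
#' Bayes-factor gene scores), and comorbidity/symptom analysis. All
#' randomness derives from the master seed in `config`, so two runs with
#' the same configuration produce identical outputs.
#'
#' The `"test"` profile scales the annealing iterations, Monte-Carlo draws
#' and permutation counts down (1e4 / 1e3 / 200) for fast runs on small
#' networks; `"production"` uses 1e6 / 1e6 / 1e4. The report records the
#' profile and every threshold actually applied.
#'
#' @param config a [sim_config] describing the synthetic study.
#' @param out_dir optional directory; when given, the study inputs, the
#'   signature table and the JSON run report are written there.
#' @param profile `"test"` (default) or `"production"`.
#' @param mi_threshold MI threshold in nats (default 1.0).
#' @param alpha,lfc_threshold differential-expression cutoffs
#'   (defaults 0.05 and 0.75).
#' @param diamond_iter DIAMOnD iterations (default 200).
#' @param r2_threshold LD binning threshold (default 0.8).
#' @param n_controls control gene sets for the fraction comparison
#'   (default 100).
#' @param rr_min,ci_low_min comorbidity relative-risk filter
#'   (defaults 1.5 and 1.0).
#' @return an object of class `netsig_run`: a list with the intermediate
#'   objects (`study`, `coexpr_network`, `merged_network`, `stats`,
#'   `diamond`, `active`, `signatures`, `topology`, `gwas`, `comorbidity`)
#'   and a machine-readable `report`.
#' @export
run_all <- function(config = sim_config(), out_dir = NULL,
                    profile = c("test", "production"),
                    mi_threshold = 1.0, alpha = 0.05, lfc_threshold = 0.75,
                    diamond_iter = 200L, r2_threshold = 0.8,
                    n_controls = 100L, rr_min = 1.5, ci_low_min = 1.0) {
  stopifnot(inherits(config, "sim_config"))
  profile <- match.arg(profile)
  sa_iter <- if (profile == "test") 1e4 else 1e6
  mc_rand <- if (profile == "test") 1e3 else 1e6
  n_perm <- if (profile == "test") 200L else 10000L
  topo_rand <- if (profile == "test") 500L else 10000L

  stages <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  study <- clock("simulate", simulate_study(config))

  coexpr <- clock("coexpression",
                  build_mi_network(study$expr, threshold = mi_threshold))
  merged <- clock("merge", merge_networks(study$network, coexpr))

  stats <- clock("dge", dge_stats(nb_wald_test(study$expr),
                                  alpha = alpha,
                                  lfc_threshold = lfc_threshold))
  deg <- select_deg(stats, alpha = alpha, lfc_threshold = lfc_threshold)

  diamond <- clock("diamond",
                   diamond_run(merged, study$truth$seed_genes,
                               n_iter = diamond_iter))
  gene_p <- stats::setNames(stats$p, stats$gene)
  active <- clock("active_modules",
                  recursive_search(merged, gene_p,
                                   iterations = sa_iter,
                                   seed = stage_seed(config$seed, "discovery")))
  signatures <- combine_signatures(diamond$gene, active$hsn2_genes, deg)

  # precision counts a signature as a true discovery when the generator
  # planted an expression effect on it (module genes and affected
  # neighbors); recall asks how much of the module proper was found
  truth_mod <- study$truth$module_genes
  truth_eff <- study$truth$effect_genes
  precision <- if (nrow(signatures) > 0)
    length(intersect(signatures$gene, truth_eff)) / nrow(signatures) else NA_real_
  precision_module <- if (nrow(signatures) > 0)
    length(intersect(signatures$gene, truth_mod)) / nrow(signatures) else NA_real_
  recall <- length(intersect(signatures$gene, truth_mod)) / length(truth_mod)

  topology <- clock("topology",
                    module_size_zscore(merged, signatures$gene,
                                       n_rand = topo_rand,
                                       seed = stage_seed(config$seed,
                                                         "topology")))

  gwas <- clock("gwas_integration", {
    snps <- study$gwas$snps
    snp_p <- stats::setNames(snps$p, snps$id)
    bins <- bin_snps_to_genes(snps, study$gene_coords, study$gwas$ld,
                              r2_threshold = r2_threshold)
    gp <- gene_level_p(bins, snp_p)
    lam <- lambda_gc(snps$p)
    qq <- if (any(signatures$gene %in% names(gp))) {
      qq_fraction_comparison(gp, list(signatures = signatures$gene),
                             n_controls = n_controls,
                             seed = stage_seed(config$seed, "controls"))
    } else NULL
    low <- names(gp)[gp < 0.05]
    sig_in <- intersect(signatures$gene, names(gp))
    a <- length(intersect(sig_in, low))
    fis <- fisher_enrichment(a, length(sig_in) - a,
                             length(low) - a,
                             length(gp) - length(sig_in) - length(low) + a)
    query <- unique(unlist(bins[names(bins) %in% signatures$gene]))
    query <- perfect_ld_expand(query, study$gwas$ld)
    query <- intersect(query, snps$id)
    mc <- if (length(query) > 0) {
      monte_carlo_snp_enrichment(query, snps$id, study$annotations,
                                 n_rand = mc_rand,
                                 seed = stage_seed(config$seed, "enrichment"))
    } else NULL
    zmap <- stats::setNames(snps$z, snps$id)
    eq <- study$eqtl[study$eqtl$gene %in% signatures$gene, , drop = FALSE]
    sherlock <- lapply(split(eq$snp, eq$gene), function(ids) {
      sherlock_gene_score(zmap[ids], z_pool = snps$z, n_perm = n_perm,
                          seed = stage_seed(config$seed, "enrichment"))
    })
    sherlock_sig <- sum(vapply(sherlock, `[[`, numeric(1L), "p") < 0.05)
    list(bins = bins, gene_p = gp, lambda_gc = lam$lambda_gc, qq = qq,
         fisher_low_p = fis, mc_enrichment = mc, sherlock = sherlock,
         n_sherlock_significant = sherlock_sig,
         n_genome_wide = sum(snps$p < GENOME_WIDE_SIG))
  })

  comorbidity <- clock("comorbidity", {
    kept <- filter_comorbid(study$comorbidity$diseases, rr_min, ci_low_min)
    enr <- lapply(kept, function(d) {
      c(list(name = d$name, rr = d$rr),
        comorbid_gene_enrichment(signatures$gene, d, merged$nodes))
    })
    sim <- tfidf_similarity(study$comorbidity$symptoms)
    focal_sim <- if ("FOCAL" %in% rownames(sim)) {
      s <- sim["FOCAL", colnames(sim) != "FOCAL"]
      stats::setNames(as.numeric(s), colnames(sim)[colnames(sim) != "FOCAL"])
    } else NULL
    list(n_filtered = length(kept), enrichment = enr,
         n_enriched = sum(vapply(enr, `[[`, numeric(1L), "p") < 0.05),
         focal_similarity = focal_sim)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("netsig")),
    profile = profile,
    seed = config$seed,
    config = unclass(config),
    thresholds = list(mi_threshold = mi_threshold, alpha = alpha,
                      lfc_threshold = lfc_threshold,
                      r2_threshold = r2_threshold,
                      genome_wide_sig = GENOME_WIDE_SIG,
                      rr_min = rr_min, ci_low_min = ci_low_min,
                      sa_iterations = sa_iter, mc_n_rand = mc_rand,
                      n_controls = n_controls,
                      scaled_down = profile == "test"),
    stage_seconds = stages,
    network = list(n_nodes_physical = n_nodes(study$network),
                   n_edges_physical = n_edges(study$network),
                   n_nodes_coexpr = n_nodes(coexpr),
                   n_edges_coexpr = n_edges(coexpr),
                   n_nodes_merged = n_nodes(merged),
                   n_edges_merged = n_edges(merged)),
    dge = attr(deg, "summary"),
    n_deg = length(deg),
    n_diamond = nrow(diamond),
    n_hsn2 = length(active$hsn2_genes),
    n_signatures = nrow(signatures),
    signature_precision = precision,
    signature_precision_module = precision_module,
    signature_recall = recall,
    topology = unclass(topology),
    lambda_gc = gwas$lambda_gc,
    fisher_low_p = gwas$fisher_low_p$p,
    mc_enrichment_p = if (!is.null(gwas$mc_enrichment))
      gwas$mc_enrichment$p else NA_real_,
    n_sherlock_significant = gwas$n_sherlock_significant,
    comorbid_enriched = comorbidity$n_enriched)

  run <- structure(list(study = study, coexpr_network = coexpr,
                        merged_network = merged, stats = stats, deg = deg,
                        diamond = diamond, active = active,
                        signatures = signatures, topology = topology,
                        gwas = gwas, comorbidity = comorbidity,
                        report = report),
                   class = "netsig_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_study(study, file.path(out_dir, "inputs"))
    utils::write.table(signatures, file.path(out_dir, "signatures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diamond, file.path(out_dir, "diamond.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  run
}

#' @export
print.netsig_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("netsig run (seed %d, %s profile)\n", r$seed, r$profile))
  cat(sprintf("  merged network: %d nodes, %d edges\n",
              r$network$n_nodes_merged, r$network$n_edges_merged))
  cat(sprintf("  DE genes: %d; DIAMOnD: %d; HSN2: %d; signatures: %d\n",
              r$n_deg, r$n_diamond, r$n_hsn2, r$n_signatures))
  cat(sprintf("  planted-module precision %.2f, recall %.2f\n",
              r$signature_precision, r$signature_recall))
  cat(sprintf("  module S = %d (z = %.1f), lambda_gc = %.3f\n",
              r$topology$S,
              if (is.na(r$topology$z)) NA else r$topology$z,
              r$lambda_gc))
  invisible(x)
}
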