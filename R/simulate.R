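#' Configuration for a synthetic disease-module study
#'
#' Bundles every tunable of the synthetic-study generator. The defaults
#' describe the study conditions used throughout the package's tests: a
#' 1,000-gene scale-free interactome with a planted 30-gene disease module,
#' a 10 vs 10 case-control expression cohort, GWAS summary statistics with
#' association signal concentrated in module genes, and annotation, eQTL and
#' comorbidity layers enriched at the module.
#'
#' @param seed master RNG seed; every stage derives an independent substream
#'   from it (see [stage_seed]).
#' @param n_genes number of genes (network nodes).
#' @param attach_m preferential-attachment edges added per new node.
#' @param module_size size M of the planted connected disease module.
#' @param module_wiring_prob probability of adding an extra edge between each
#'   non-adjacent pair of module genes, giving the module the local edge
#'   density the disease-module hypothesis posits.
#' @param n_seeds number of "known disease genes" sampled from the module.
#' @param n_cases,n_controls sample counts per group.
#' @param base_mean scale of the log-normal distribution of per-gene
#'   negative-binomial means.
#' @param dispersion negative-binomial dispersion phi (var = mu + phi mu^2).
#' @param lfc_effect log2 fold change planted on effect genes in cases.
#' @param neighbor_effect_prob probability that a first neighbor of the
#'   module also receives the expression effect.
#' @param coexpr_strength loading of the latent factor shared by module
#'   genes, inducing positive co-expression recoverable by mutual
#'   information.
#' @param snps_per_gene_mean Poisson mean of SNP counts per gene body (the
#'   same mean is used for each inter-gene gap).
#' @param ld_block_size number of consecutive SNPs per LD block.
#' @param gwas_ncp non-centrality added to the z-scores of causal SNPs
#'   (SNPs falling inside module genes).
#' @param annot_enrichment odds multiplier for regulatory-annotation flags at
#'   causal SNPs.
#' @param n_comorbid_diseases number of comorbid-disease gene sets.
#' @param shared_gene_rate fraction rho of each comorbid set drawn from
#'   module/effect genes.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       attach_m = 3L,
                       module_size = 30L,
                       module_wiring_prob = 0.15,
                       n_seeds = 10L,
                       n_cases = 10L,
                       n_controls = 10L,
                       base_mean = 100,
                       dispersion = 0.1,
                       lfc_effect = 2,
                       neighbor_effect_prob = 0.1,
                       coexpr_strength = 0.5,
                       snps_per_gene_mean = 3,
                       ld_block_size = 5L,
                       gwas_ncp = 6,
                       annot_enrichment = 10,
                       n_comorbid_diseases = 20L,
                       shared_gene_rate = 0.5) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              attach_m = as.integer(attach_m),
              module_size = as.integer(module_size),
              module_wiring_prob = module_wiring_prob,
              n_seeds = as.integer(n_seeds),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              base_mean = base_mean, dispersion = dispersion,
              lfc_effect = lfc_effect,
              neighbor_effect_prob = neighbor_effect_prob,
              coexpr_strength = coexpr_strength,
              snps_per_gene_mean = snps_per_gene_mean,
              ld_block_size = as.integer(ld_block_size),
              gwas_ncp = gwas_ncp, annot_enrichment = annot_enrichment,
              n_comorbid_diseases = as.integer(n_comorbid_diseases),
              shared_gene_rate = shared_gene_rate)
  for (f in c("n_genes", "attach_m", "module_size", "n_seeds", "n_cases",
              "n_controls", "ld_block_size", "n_comorbid_diseases")) {
    assert_count(cfg[[f]], f)
  }
  assert_that(cfg$module_size <= cfg$n_genes,
              "'module_size' must not exceed 'n_genes'",
              class = "netsig_invalid_config")
  assert_that(cfg$n_seeds <= cfg$module_size,
              "'n_seeds' must not exceed 'module_size'",
              class = "netsig_invalid_config")
  assert_that(cfg$attach_m < cfg$n_genes,
              "'attach_m' must be smaller than 'n_genes'",
              class = "netsig_invalid_config")
  assert_that(cfg$dispersion > 0, "'dispersion' must be > 0",
              class = "netsig_invalid_config")
  assert_that(cfg$base_mean > 0, "'base_mean' must be > 0",
              class = "netsig_invalid_config")
  assert_that(cfg$snps_per_gene_mean > 0, "'snps_per_gene_mean' must be > 0",
              class = "netsig_invalid_config")
  assert_that(cfg$annot_enrichment > 0, "'annot_enrichment' must be > 0",
              class = "netsig_invalid_config")
  for (f in c("module_wiring_prob", "neighbor_effect_prob",
              "shared_gene_rate")) {
    assert_prob(cfg[[f]], f)
  }
  structure(cfg, class = "sim_config")
}

sim_gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate a scale-free interactome with a planted disease module
#'
#' Builds an undirected simple graph by preferential attachment: `attach_m`
#' initially isolated nodes, then each new node attaches to `attach_m`
#' distinct existing nodes with probability proportional to degree + 1, for
#' `attach_m * (n_genes - attach_m)` edges in total. A connected disease
#' module of `module_size` genes is selected by a random walk from a random
#' start, then densified by adding intra-module edges with probability
#' `module_wiring_prob` per non-adjacent pair. Seed genes are sampled
#' uniformly from the module, and planted expression effects (log2 fold
#' changes) are assigned to all module genes plus each first neighbor with
#' probability `neighbor_effect_prob`.
#'
#' @param config a [sim_config].
#' @return a list with elements `network` (a [gene_network], source tag
#'   `"physical"`) and `truth` (class `ground_truth`: `module_genes`,
#'   `seed_genes`, `effect_genes`, `per_gene_lfc`, and later `causal_snps`).
#' @export
simulate_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "interactome"))
  n <- config$n_genes
  m <- config$attach_m
  genes <- sim_gene_names(n)

  deg <- integer(n)
  from <- integer(m * (n - m))
  to <- integer(m * (n - m))
  k <- 0L
  for (v in seq.int(m + 1L, n)) {
    existing <- seq_len(v - 1L)
    targets <- sample(existing, m, prob = deg[existing] + 1)
    idx <- k + seq_len(m)
    from[idx] <- v
    to[idx] <- targets
    deg[v] <- deg[v] + m
    deg[targets] <- deg[targets] + 1L
    k <- k + m
  }

  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer()
  for (e in seq_along(from)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }

  module <- plant_module_walk(adj, config$module_size)

  extra_a <- integer(); extra_b <- integer()
  if (config$module_wiring_prob > 0 && length(module) > 1L) {
    pairs <- utils::combn(sort(module), 2L)
    have <- paste(pmin(from, to), pmax(from, to))
    cand <- !(paste(pairs[1L, ], pairs[2L, ]) %in% have)
    add <- cand & stats::runif(ncol(pairs)) < config$module_wiring_prob
    extra_a <- pairs[1L, add]
    extra_b <- pairs[2L, add]
  }

  edges <- data.frame(gene_a = genes[c(from, extra_a)],
                      gene_b = genes[c(to, extra_b)],
                      stringsAsFactors = FALSE)
  network <- gene_network(edges, nodes = genes, source_tag = "physical")

  module_genes <- sort(genes[module])
  seed_genes <- sort(sample(module_genes, config$n_seeds))

  nbrs <- unique(unlist(adj[module]))
  nbrs <- setdiff(nbrs, module)
  eff_nbr <- nbrs[stats::runif(length(nbrs)) < config$neighbor_effect_prob]
  effect_genes <- sort(c(module_genes, genes[eff_nbr]))
  lfc <- stats::setNames(rep(config$lfc_effect, length(effect_genes)),
                         effect_genes)

  truth <- structure(list(module_genes = module_genes,
                          seed_genes = seed_genes,
                          effect_genes = effect_genes,
                          per_gene_lfc = lfc,
                          causal_snps = character()),
                     class = "ground_truth")
  list(network = network, truth = truth)
}

# Random walk collecting `size` distinct vertices; bounded steps per start,
# bounded restarts.
plant_module_walk <- function(adj, size, max_steps = NULL, max_retries = 25L) {
  n <- length(adj)
  if (is.null(max_steps)) max_steps <- 200L * size
  for (try in seq_len(max_retries)) {
    cur <- sample.int(n, 1L)
    seen <- cur
    for (s in seq_len(max_steps)) {
      if (length(seen) >= size) return(seen)
      nb <- adj[[cur]]
      if (length(nb) == 0L) break
      cur <- nb[sample.int(length(nb), 1L)]
      if (!cur %in% seen) seen <- c(seen, cur)
    }
    if (length(seen) >= size) return(seen)
  }
  stop_netsig("random walk failed to collect a connected module; the graph may be too fragmented",
              "netsig_simulation_error")
}

#' Simulate two-group negative-binomial expression counts
#'
#' Control samples draw from NB(mu_g, phi) with gene means log-normal around
#' `base_mean`; case samples multiply the mean of each effect gene by
#' `2^lfc`. Module genes additionally share a per-sample latent factor
#' (mean-preserving log-normal modulation with loading `coexpr_strength`),
#' inducing the positive co-expression that lets a mutual-information network
#' recover module edges.
#'
#' @param network a [gene_network] (its node set defines the genes).
#' @param truth a `ground_truth` from [simulate_interactome].
#' @param config a [sim_config].
#' @return an [expression_matrix].
#' @export
simulate_expression <- function(network, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(all(truth$module_genes %in% network$nodes),
              "ground-truth genes must be network nodes")
  assert_that(config$dispersion > 0, "'dispersion' must be > 0",
              class = "netsig_invalid_config")
  set.seed(stage_seed(config$seed, "expression"))
  genes <- network$nodes
  ng <- length(genes)
  n_case <- config$n_cases
  n_ctrl <- config$n_controls
  ns <- n_case + n_ctrl
  groups <- factor(rep(c("case", "control"), c(n_case, n_ctrl)),
                   levels = c("case", "control"))

  mu <- stats::rlnorm(ng, meanlog = log(config$base_mean), sdlog = 1)
  lfc <- rep(0, ng)
  idx <- match(names(truth$per_gene_lfc), genes)
  lfc[idx[!is.na(idx)]] <- truth$per_gene_lfc[!is.na(idx)]

  mean_mat <- matrix(mu, nrow = ng, ncol = ns)
  mean_mat[, groups == "case"] <- mean_mat[, groups == "case"] * 2^lfc

  if (config$coexpr_strength > 0 && length(truth$module_genes) > 0L) {
    f <- stats::rnorm(ns)
    b <- config$coexpr_strength
    mod_idx <- match(truth$module_genes, genes)
    mod_f <- exp(b * f - b^2 / 2) # unit-mean modulation
    mean_mat[mod_idx, ] <- sweep(mean_mat[mod_idx, , drop = FALSE], 2L,
                                 mod_f, `*`)
  }

  counts <- matrix(stats::rnbinom(ng * ns, mu = mean_mat,
                                  size = 1 / config$dispersion),
                   nrow = ng, ncol = ns,
                   dimnames = list(genes,
                                   c(sprintf("CASE%02d", seq_len(n_case)),
                                     sprintf("CTRL%02d", seq_len(n_ctrl)))))
  expression_matrix(counts, groups)
}

#' Expression matrix container
#'
#' @param counts nonnegative numeric matrix, genes in rows (rownames are the
#'   gene symbols), samples in columns.
#' @param groups factor of length `ncol(counts)` with levels
#'   `c("case", "control")`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, groups) {
  assert_that(is.matrix(counts) && !is.null(rownames(counts)),
              "'counts' must be a matrix with gene-symbol rownames")
  assert_that(!anyDuplicated(rownames(counts)),
              "duplicate gene symbols in 'counts'")
  assert_that(ncol(counts) >= 2L, "need at least 2 samples")
  assert_that(all(counts >= 0), "'counts' must be nonnegative")
  groups <- factor(groups, levels = c("case", "control"))
  assert_that(length(groups) == ncol(counts) && !anyNA(groups),
              "'groups' must label every sample as case or control")
  structure(list(counts = counts, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' Lay genes out on a synthetic chromosome
#'
#' Deterministic layout: one chromosome, 1-based inclusive intervals of
#' `gene_length` bp separated by `gap` bp.
#'
#' @param genes character vector of gene symbols.
#' @param gene_length gene body length in bp.
#' @param gap inter-gene gap in bp.
#' @return data frame with columns `chrom`, `start`, `end`, `gene`.
#' @export
gene_coordinates <- function(genes, gene_length = 1000L, gap = 2000L) {
  genes <- normalize_symbols(genes)
  n <- length(genes)
  start <- (seq_len(n) - 1L) * (gene_length + gap) + 1L
  data.frame(chrom = "chr1", start = start, end = start + gene_length - 1L,
             gene = genes, stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics with block LD
#'
#' Places SNPs within gene bodies and inter-gene gaps (Poisson counts),
#' draws per-SNP z from N(0,1), adds `gwas_ncp` to the z of causal SNPs
#' (those inside module genes), and converts to two-sided p-values. LD pairs
#' are emitted within blocks of `ld_block_size` consecutive SNPs with high
#' r-squared (a fraction of pairs at exactly r2 = 1, D' = 1) and omitted
#' (r2 = 0) across blocks.
#'
#' @param gene_coords data frame from [gene_coordinates].
#' @param truth a `ground_truth`; its `module_genes` define causal SNPs.
#' @param config a [sim_config].
#' @return a list with `snps` (data frame `id`, `chrom`, `pos`, `p`, `z`,
#'   `causal`), `ld` (data frame `snp1`, `snp2`, `r2`, `dprime`, ids
#'   canonically sorted within each pair), and `causal_snps` (character).
#' @export
simulate_gwas <- function(gene_coords, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(all(gene_coords$start <= gene_coords$end),
              "gene intervals must have start <= end")
  set.seed(stage_seed(config$seed, "gwas"))
  lambda <- config$snps_per_gene_mean
  ng <- nrow(gene_coords)

  n_in <- stats::rpois(ng, lambda)
  pos_in <- unlist(lapply(seq_len(ng), function(i) {
    if (n_in[i] == 0L) return(integer())
    sort(sample.int(gene_coords$end[i] - gene_coords$start[i] + 1L,
                    n_in[i], replace = TRUE) + gene_coords$start[i] - 1L)
  }))
  gene_of <- rep(gene_coords$gene, n_in)

  gaps <- cbind(gene_coords$end[-ng] + 1L, gene_coords$start[-1L] - 1L)
  n_out <- stats::rpois(nrow(gaps), lambda)
  pos_out <- unlist(lapply(seq_len(nrow(gaps)), function(i) {
    if (n_out[i] == 0L) return(integer())
    sort(sample.int(gaps[i, 2L] - gaps[i, 1L] + 1L, n_out[i],
                    replace = TRUE) + gaps[i, 1L] - 1L)
  }))

  pos <- c(pos_in, pos_out)
  gene_of <- c(gene_of, rep(NA_character_, length(pos_out)))
  o <- order(pos)
  pos <- pos[o]
  gene_of <- gene_of[o]
  nsnp <- length(pos)
  assert_that(nsnp >= 2L, "simulated GWAS produced fewer than 2 SNPs",
              class = "netsig_simulation_error")
  ids <- sprintf("RS%06d", seq_len(nsnp))

  causal <- !is.na(gene_of) & gene_of %in% truth$module_genes
  z <- stats::rnorm(nsnp)
  z[causal] <- z[causal] + config$gwas_ncp
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin) # keep p in (0,1]

  snps <- data.frame(id = ids, chrom = "chr1", pos = pos, p = p, z = z,
                     causal = causal, gene = gene_of,
                     stringsAsFactors = FALSE)

  block <- (seq_len(nsnp) - 1L) %/% config$ld_block_size
  ld_list <- lapply(split(seq_len(nsnp), block), function(ix) {
    if (length(ix) < 2L) return(NULL)
    pr <- utils::combn(ix, 2L)
    npair <- ncol(pr)
    perfect <- stats::runif(npair) < 0.15
    r2 <- ifelse(perfect, 1, stats::runif(npair, 0.6, 0.999))
    dp <- ifelse(perfect, 1, pmin(1, sqrt(r2) + stats::runif(npair, 0, 0.1)))
    data.frame(snp1 = ids[pr[1L, ]], snp2 = ids[pr[2L, ]],
               r2 = r2, dprime = dp, stringsAsFactors = FALSE)
  })
  ld <- do.call(rbind, ld_list)
  if (is.null(ld)) {
    ld <- data.frame(snp1 = character(), snp2 = character(),
                     r2 = numeric(), dprime = numeric())
  }
  rownames(ld) <- NULL

  list(snps = snps, ld = ld, causal_snps = ids[causal])
}

#' Simulate regulatory annotations and eQTL records
#'
#' Emits one binary flag per SNP per cell type, with the odds of a flag
#' multiplied by `annot_enrichment` at causal SNPs, and an eQTL table
#' (SNP, target gene, z, V) preferentially targeting module genes.
#'
#' @param gwas output of [simulate_gwas].
#' @param truth a `ground_truth`.
#' @param config a [sim_config].
#' @param cell_types annotation column names.
#' @param base_rate baseline flag probability for non-causal SNPs.
#' @return list with `annotations` (data frame `id` + one 0/1 column per
#'   cell type) and `eqtl` (data frame `snp`, `gene`, `z`, `V`).
#' @export
simulate_annotations <- function(gwas, truth, config,
                                 cell_types = c("islet", "liver", "muscle",
                                                "adipose", "lcl"),
                                 base_rate = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(gwas$snps) > 0L, "'gwas' must contain SNPs")
  assert_that(config$annot_enrichment > 0,
              "'annot_enrichment' must be > 0",
              class = "netsig_invalid_config")
  set.seed(stage_seed(config$seed, "annotations"))
  snps <- gwas$snps
  pflag <- ifelse(snps$causal,
                  stats::plogis(stats::qlogis(base_rate) +
                                  log(config$annot_enrichment)),
                  base_rate)
  ann <- data.frame(id = snps$id, stringsAsFactors = FALSE)
  for (ct in cell_types) {
    ann[[ct]] <- as.integer(stats::runif(nrow(snps)) < pflag)
  }

  gene_hits <- snps$gene
  in_gene <- !is.na(gene_hits)
  is_module <- in_gene & gene_hits %in% truth$module_genes
  p_esnp <- ifelse(is_module, 0.8, ifelse(in_gene, 0.2, 0))
  take <- stats::runif(nrow(snps)) < p_esnp
  eqtl <- data.frame(snp = snps$id[take], gene = gene_hits[take],
                     z = stats::rnorm(sum(take),
                                      mean = ifelse(is_module[take], 4, 0)),
                     V = 1, stringsAsFactors = FALSE)
  list(annotations = ann, eqtl = eqtl)
}

#' Simulate comorbid-disease gene sets and symptom corpora
#'
#' Each comorbid disease draws a fraction `shared_gene_rate` of its members
#' from the module/effect genes and the rest uniformly from the remaining
#' genes, carries a relative-risk value with a lower confidence bound, and a
#' bag-of-terms symptom vector overlapping the focal disease's vector
#' proportionally to `shared_gene_rate`.
#'
#' @param genes full gene universe (character).
#' @param truth a `ground_truth`.
#' @param config a [sim_config].
#' @param vocab_size number of distinct symptom terms.
#' @return list with `diseases` (list of `comorbid_disease` records:
#'   `name`, `genes`, `rr`, `rr_ci_low`) and `symptoms` (data frame
#'   `disease`, `term`, `count`; the focal disease is named `"FOCAL"`).
#' @export
simulate_comorbidity <- function(genes, truth, config, vocab_size = 60L) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(length(genes) > 0L, "'genes' must be nonempty")
  set.seed(stage_seed(config$seed, "comorbidity"))
  genes <- normalize_symbols(genes)
  pool_mod <- intersect(union(truth$module_genes, truth$effect_genes), genes)
  pool_rest <- setdiff(genes, pool_mod)
  rho <- config$shared_gene_rate
  vocab <- sprintf("SYM%03d", seq_len(vocab_size))
  focal_terms <- sample(vocab, 15L)

  diseases <- vector("list", config$n_comorbid_diseases)
  sym_rows <- list(data.frame(disease = "FOCAL",
                              term = focal_terms,
                              count = stats::rpois(length(focal_terms), 2) + 1L,
                              stringsAsFactors = FALSE))
  for (d in seq_len(config$n_comorbid_diseases)) {
    size <- sample(10:30, 1L)
    n_shared <- stats::rbinom(1L, size, rho)
    n_shared <- min(n_shared, length(pool_mod))
    gset <- c(sample(pool_mod, n_shared),
              sample(pool_rest, size - n_shared))
    rr <- exp(stats::rnorm(1L, mean = 0.5, sd = 0.4))
    width <- stats::runif(1L, 0.1, 0.6)
    diseases[[d]] <- structure(list(name = sprintf("DIS%03d", d),
                                    genes = sort(unique(gset)),
                                    rr = rr,
                                    rr_ci_low = max(rr - width, 0.01)),
                               class = "comorbid_disease")
    n_terms <- 12L
    from_focal <- stats::runif(n_terms) < rho
    terms <- ifelse(from_focal,
                    sample(focal_terms, n_terms, replace = TRUE),
                    sample(vocab, n_terms, replace = TRUE))
    tt <- table(terms)
    sym_rows[[d + 1L]] <- data.frame(disease = sprintf("DIS%03d", d),
                                     term = names(tt),
                                     count = as.integer(tt),
                                     stringsAsFactors = FALSE)
  }
  symptoms <- do.call(rbind, sym_rows)
  rownames(symptoms) <- NULL
  list(diseases = diseases, symptoms = symptoms)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage from one configuration: interactome with a
#' planted module, expression counts, gene coordinates, GWAS summary
#' statistics with block LD, regulatory annotations and eQTLs, and
#' comorbidity inputs. Each stage uses an independent RNG substream derived
#' from the master seed.
#'
#' @param config a [sim_config].
#' @return a list of class `sim_study` with elements `config`, `network`,
#'   `truth`, `expr`, `gene_coords`, `gwas`, `annotations`, `eqtl`,
#'   `comorbidity`.
#' @export
simulate_study <- function(config = sim_config()) {
  net <- simulate_interactome(config)
  truth <- net$truth
  expr <- simulate_expression(net$network, truth, config)
  coords <- gene_coordinates(net$network$nodes)
  gwas <- simulate_gwas(coords, truth, config)
  truth$causal_snps <- gwas$causal_snps
  ann <- simulate_annotations(gwas, truth, config)
  como <- simulate_comorbidity(net$network$nodes, truth, config)
  structure(list(config = config, network = net$network, truth = truth,
                 expr = expr, gene_coords = coords, gwas = gwas,
                 annotations = ann$annotations, eqtl = ann$eqtl,
                 comorbidity = como),
            class = "sim_study")
}

#' Write a synthetic study to a directory of plain-text files
#'
#' Emits the standard formats consumed by the analysis layers: edge-list
#' TSV, counts TSV, GWAS TSV, LD TSV, BED-like gene table (1-based
#' inclusive), annotation and eQTL TSVs, a GMT of comorbid gene sets with
#' relative risks in the description field, a symptom-term TSV, and the
#' ground truth as JSON.
#'
#' @param study a `sim_study` from [simulate_study].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name, ...) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, ...)
  }
  write_edge_list(study$network, file.path(dir, "network.tsv"))
  counts <- data.frame(gene = rownames(study$expr$counts),
                       study$expr$counts, check.names = FALSE)
  tsv(counts, "counts.tsv")
  writeLines(paste(colnames(study$expr$counts),
                   as.character(study$expr$groups), sep = "\t"),
             file.path(dir, "samples.tsv"))
  tsv(study$gwas$snps[, c("id", "chrom", "pos", "p")], "gwas.tsv")
  tsv(study$gwas$ld, "ld.tsv")
  tsv(study$gene_coords, "genes.tsv")
  tsv(study$annotations, "annotations.tsv")
  tsv(study$eqtl, "eqtl.tsv")
  write_gmt(lapply(study$comorbidity$diseases, function(d) {
    list(name = d$name,
         description = sprintf("RR=%.4f;CI_low=%.4f", d$rr, d$rr_ci_low),
         genes = d$genes)
  }), file.path(dir, "comorbid.gmt"))
  tsv(study$comorbidity$symptoms, "symptoms.tsv")
  truth <- study$truth
  jsonlite::write_json(list(module_genes = truth$module_genes,
                            seed_genes = truth$seed_genes,
                            effect_genes = truth$effect_genes,
                            per_gene_lfc = as.list(truth$per_gene_lfc),
                            causal_snps = truth$causal_snps),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
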