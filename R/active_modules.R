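#' Convert a p-value to an upper-tail z-score
#'
#' `z = qnorm(1 - p)`; p-values are clamped to `[1e-12, 1 - 1e-12]` with a
#' warning so that extreme inputs stay finite.
#'
#' @param p numeric vector of p-values.
#' @return z-scores.
#' @export
gene_zscore <- function(p) {
  assert_that(is.numeric(p) && !anyNA(p) && all(p >= 0) && all(p <= 1),
              "'p' must contain probabilities in [0,1]")
  lo <- 1e-12
  if (any(p < lo | p > 1 - lo)) {
    warning("p-values clamped to [1e-12, 1 - 1e-12]")
    p <- pmin(pmax(p, lo), 1 - lo)
  }
  stats::qnorm(1 - p)
}

#' Aggregate subnetwork z-score
#'
#' `zA = sum(z) / sqrt(k)` for a set of `k` member z-scores.
#'
#' @param zs numeric vector of member z-scores.
#' @return the aggregate score.
#' @export
subnetwork_score <- function(zs) {
  assert_that(length(zs) >= 1L, "need at least one z-score")
  sum(zs) / sqrt(length(zs))
}

#' Monte-Carlo calibration of the subnetwork score
#'
#' Estimates the null mean and standard deviation of `zA` over uniformly
#' sampled `k`-gene sets, so that a candidate subnetwork can be reported on
#' the calibrated scale `sA = (zA - mu_k) / sigma_k`.
#'
#' @param network a [gene_network].
#' @param gene_p named vector of per-gene p-values; network genes absent
#'   from it score `p = 1`.
#' @param k subnetwork size to calibrate.
#' @param n_samples number of random sets (default 2000, minimum 100).
#' @return list with `mu_k`, `sigma_k`.
#' @export
calibrate_score <- function(network, gene_p, k, n_samples = 2000L) {
  stopifnot(inherits(network, "gene_network"))
  assert_count(k, "k")
  assert_count(n_samples, "n_samples", min = 100L)
  z <- node_zscores(network, gene_p)
  assert_that(k <= length(z), "'k' exceeds the number of network genes")
  za <- vapply(seq_len(n_samples), function(i) {
    subnetwork_score(z[sample.int(length(z), k)])
  }, numeric(1L))
  sigma <- stats::sd(za)
  if (!is.finite(sigma) || sigma == 0) {
    stop_netsig("degenerate calibration: sigma_k = 0",
                "netsig_degenerate_calibration")
  }
  list(mu_k = mean(za), sigma_k = sigma)
}

# Exact finite-population calibration moments for every k in 1..N.
# For uniform k-subsets drawn without replacement from z_1..z_N:
#   E[zA]  = sqrt(k) * mean(z)
#   SD[zA] = sqrt(sigma2 * (N - k) / (N - 1)),  sigma2 = population variance.
# These are the exact values the Monte-Carlo calibrator estimates.
exact_calibration <- function(z) {
  N <- length(z)
  zbar <- mean(z)
  sigma2 <- mean((z - zbar)^2)
  k <- seq_len(N)
  list(mu = sqrt(k) * zbar,
       sigma = sqrt(sigma2 * (N - k) / max(N - 1, 1)))
}

node_zscores <- function(network, gene_p) {
  p <- rep(1, length(network$nodes))
  names(p) <- network$nodes
  gp <- gene_p[names(gene_p) %in% network$nodes]
  p[names(gp)] <- gp
  suppressWarnings(gene_zscore(p))
}

#' Active-subnetwork search by simulated annealing
#'
#' Re-implementation of the classic active-modules search: each network node
#' is active or inactive (initialized active with probability 0.5); one
#' uniformly random node is toggled per iteration; the state score is the
#' sum of the `n_modules` highest calibrated component scores
#' `sA = (zA - mu_k) / sigma_k` over connected components of the active
#' set; improving moves are always accepted and worsening moves with
#' probability `exp(delta / T)` under geometric cooling from `start_temp`
#' to `end_temp`. Calibration moments are the exact finite-population values
#' (see the package vignette). The best-seen state is decomposed into
#' components, ranked by `sA`, and greedily filtered so that reported
#' modules have pairwise Jaccard overlap at most `overlap_threshold`.
#'
#' @param network a [gene_network].
#' @param gene_p named per-gene p-values; genes without a value get `p = 1`.
#' @param start_temp,end_temp annealing temperature schedule
#'   (defaults 1.0 and 0.01).
#' @param iterations number of annealing steps (default 1e6; use ~1e4 for
#'   small networks and tests).
#' @param n_modules number of modules to report (default 5).
#' @param overlap_threshold maximum pairwise Jaccard index between reported
#'   modules (default 0.1).
#' @param seed RNG seed for the search.
#' @return list of class `active_modules`: per module a list with `genes`,
#'   `k`, `zA`, `sA`, `mu_k`, `sigma_k`; attribute `best_score` carries the
#'   optimized state score.
#' @export
jactivemodules_run <- function(network, gene_p,
                               start_temp = 1.0, end_temp = 0.01,
                               iterations = 1e6, n_modules = 5L,
                               overlap_threshold = 0.1, seed = 1L) {
  stopifnot(inherits(network, "gene_network"))
  assert_that(iterations >= 1, "'iterations' must be >= 1",
              class = "netsig_invalid_config")
  assert_count(n_modules, "n_modules")
  if (length(gene_p) == 0L) {
    warning("no gene-level p-values supplied: returning no modules")
    return(structure(list(), class = "active_modules", best_score = 0))
  }
  extra <- setdiff(names(gene_p), network$nodes)
  if (length(extra) > 0L) {
    warning(sprintf("%d scored gene(s) absent from the network were ignored",
                    length(extra)))
  }
  nodes <- network$nodes
  N <- length(nodes)
  z <- node_zscores(network, gene_p)
  cal <- exact_calibration(z)
  csr <- build_csr(network)
  set.seed(seed)
  res <- sa_search_cpp(csr$ptr, csr$idx, z, c(0, cal$mu), c(0, cal$sigma),
                       as.integer(n_modules), start_temp, end_temp,
                       as.integer(iterations))
  active_genes <- nodes[res$active]
  mods <- active_components(network, active_genes, z, cal)
  mods <- greedy_overlap_filter(mods, n_modules, overlap_threshold)
  structure(mods, class = "active_modules", best_score = res$score)
}

# decompose an active gene set into components and score each
active_components <- function(network, active_genes, z, cal) {
  if (length(active_genes) == 0L) return(list())
  ed <- network$edges
  keep <- ed$gene_a %in% active_genes & ed$gene_b %in% active_genes
  comp <- induced_components(active_genes, ed$gene_a[keep], ed$gene_b[keep])
  zmap <- stats::setNames(z, network$nodes)
  mods <- lapply(split(active_genes, comp), function(g) {
    k <- length(g)
    za <- subnetwork_score(zmap[g])
    sa <- if (cal$sigma[k] > 0) (za - cal$mu[k]) / cal$sigma[k] else 0
    list(genes = sort(unname(g)), k = k, zA = unname(za), sA = sa,
         mu_k = cal$mu[k], sigma_k = cal$sigma[k])
  })
  mods[order(-vapply(mods, `[[`, numeric(1L), "sA"))]
}

greedy_overlap_filter <- function(mods, n_modules, overlap_threshold) {
  chosen <- list()
  for (m in mods) {
    if (length(chosen) >= n_modules) break
    ok <- all(vapply(chosen, function(c0) {
      jaccard(m$genes, c0$genes) <= overlap_threshold
    }, logical(1L)))
    if (ok) chosen[[length(chosen) + 1L]] <- m
  }
  chosen
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

build_csr <- function(network) {
  nodes <- network$nodes
  N <- length(nodes)
  ai <- match(network$edges$gene_a, nodes)
  bi <- match(network$edges$gene_b, nodes)
  from <- c(ai, bi); to <- c(bi, ai)
  o <- order(from)
  from <- from[o]; to <- to[o]
  ptr <- integer(N + 1L)
  cnt <- tabulate(from, nbins = N)
  ptr[-1L] <- cumsum(cnt)
  list(ptr = as.integer(ptr), idx = as.integer(to - 1L))
}

#' @export
print.active_modules <- function(x, ...) {
  cat(sprintf("active_modules: %d module(s), best state score %.3f\n",
              length(x), attr(x, "best_score")))
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] k = %d, sA = %.3f\n", i, x[[i]]$k, x[[i]]$sA))
  }
  invisible(x)
}

#' Recursive two-pass active-subnetwork search
#'
#' Runs the annealing search twice: first on the full network (HSN1), then
#' on the subgraph induced by the union of HSN1 genes, whose result (HSN2)
#' is a refinement contained in HSN1.
#'
#' @inheritParams jactivemodules_run
#' @return list with elements `hsn1`, `hsn2` (both `active_modules`) and
#'   `hsn1_genes`, `hsn2_genes` (character unions).
#' @export
recursive_search <- function(network, gene_p,
                             start_temp = 1.0, end_temp = 0.01,
                             iterations = 1e6, n_modules = 5L,
                             overlap_threshold = 0.1, seed = 1L) {
  hsn1 <- jactivemodules_run(network, gene_p, start_temp, end_temp,
                             iterations, n_modules, overlap_threshold, seed)
  g1 <- sort(unique(unlist(lapply(hsn1, `[[`, "genes"))))
  if (length(g1) == 0L) {
    warning("first-pass search returned no modules; HSN2 is empty")
    return(list(hsn1 = hsn1, hsn2 = structure(list(),
                                              class = "active_modules",
                                              best_score = 0),
                hsn1_genes = character(), hsn2_genes = character()))
  }
  sub <- subnetwork(network, g1)
  hsn2 <- jactivemodules_run(sub, gene_p[names(gene_p) %in% g1],
                             start_temp, end_temp, iterations, n_modules,
                             overlap_threshold, seed + 1L)
  list(hsn1 = hsn1, hsn2 = hsn2, hsn1_genes = g1,
       hsn2_genes = sort(unique(unlist(lapply(hsn2, `[[`, "genes")))))
}

#' Induced subgraph on a gene set
#'
#' @param network a [gene_network].
#' @param genes gene symbols to keep.
#' @return the induced [gene_network].
#' @export
subnetwork <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  genes <- intersect(normalize_symbols(genes), network$nodes)
  ed <- network$edges
  keep <- ed$gene_a %in% genes & ed$gene_b %in% genes
  gene_network(ed[keep, , drop = FALSE], nodes = genes)
}

#' Combine discovery methods into a DE-supported signature set
#'
#' Signature genes are those found by either discovery route (DIAMOnD
#' expansion or the second-pass active subnetwork HSN2) that additionally
#' pass the differential-expression filter:
#' `signatures = (diamond U hsn2) n deg`. Per-gene provenance records which
#' route(s) found each signature.
#'
#' @param diamond genes added by [diamond_run].
#' @param hsn2 genes in the second-pass active modules.
#' @param deg differentially expressed genes (from [select_deg]).
#' @return data frame of class `signature_set` with columns `gene`,
#'   `provenance` (`"diamond"`, `"jactivemodules"`, or `"both"`).
#' @export
combine_signatures <- function(diamond, hsn2, deg) {
  diamond <- unique(normalize_symbols(diamond))
  hsn2 <- unique(normalize_symbols(hsn2))
  deg <- unique(normalize_symbols(deg))
  d <- intersect(diamond, deg)
  j <- intersect(hsn2, deg)
  genes <- sort(union(d, j))
  prov <- ifelse(genes %in% d & genes %in% j, "both",
                 ifelse(genes %in% d, "diamond", "jactivemodules"))
  structure(data.frame(gene = genes, provenance = prov,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("signature_set", "data.frame"))
}
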