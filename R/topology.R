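#' One-sided upper-tail normal p-value
#'
#' @param z a finite z-score.
#' @return `1 - pnorm(z)`.
#' @export
p_from_z <- function(z) {
  assert_that(is.numeric(z) && all(is.finite(z)), "'z' must be finite")
  stats::pnorm(z, lower.tail = FALSE)
}

#' Module size z-score against random gene sets
#'
#' Measures whether a disease gene set clusters in the network more than
#' expected by chance: the observed largest-connected-component size `S` is
#' compared with its distribution over `n_rand` random gene sets of the
#' same size (`S_rand`), yielding `z = (S - mean(S_rand)) / sd(S_rand)`, a
#' one-sided normal p, and an empirical p with the plus-one convention
#' `(#\{S_rand >= S\} + 1) / (n_rand + 1)`.
#'
#' @param network a [gene_network].
#' @param disease_genes character vector; symbols absent from the network
#'   are dropped before computing `Nd` (both counts are reported).
#' @param n_rand number of random sets (default 1000, minimum 100).
#' @param seed RNG seed.
#' @param sample_mode `"uniform"` samples random sets uniformly from all
#'   network nodes; `"degree_binned"` matches the degree-decile profile of
#'   the disease genes.
#' @return list of class `module_topology`: `S`, `Nd`, `n_input`,
#'   `relative_size`, `null_mean`, `null_sd`, `z`, `p_normal`,
#'   `p_empirical`, `n_rand`, `ds`.
#' @export
module_size_zscore <- function(network, disease_genes, n_rand = 1000L,
                               seed = 1L,
                               sample_mode = c("uniform", "degree_binned")) {
  stopifnot(inherits(network, "gene_network"))
  sample_mode <- match.arg(sample_mode)
  assert_count(n_rand, "n_rand", min = 100L)
  disease_genes <- unique(normalize_symbols(disease_genes))
  n_input <- length(disease_genes)
  present <- intersect(disease_genes, network$nodes)
  assert_that(length(present) > 0L,
              "no disease gene is present in the network")
  Nd <- length(present)
  S <- length(largest_connected_component(network, present))

  set.seed(seed)
  nodes <- network$nodes
  if (sample_mode == "degree_binned") {
    deg <- igraph::degree(as_igraph(network))
    brk <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
    bin <- cut(deg, breaks = brk, include.lowest = TRUE, labels = FALSE)
    target_bins <- bin[match(present, nodes)]
    by_bin <- split(seq_along(nodes), bin)
    draw <- function() {
      nodes[unlist(lapply(target_bins, function(b) {
        pool <- by_bin[[as.character(b)]]
        pool[sample.int(length(pool), 1L)]
      }))]
    }
  } else {
    draw <- function() nodes[sample.int(length(nodes), Nd)]
  }
  s_rand <- vapply(seq_len(n_rand), function(i) {
    length(largest_connected_component(network, draw()))
  }, numeric(1L))

  null_mean <- mean(s_rand)
  null_sd <- stats::sd(s_rand)
  degenerate <- !is.finite(null_sd) || null_sd == 0
  z <- if (degenerate) NA_real_ else (S - null_mean) / null_sd
  ds <- tryCatch(separation_ds(network, present), error = function(e) NA_real_)
  structure(list(S = S, Nd = Nd, n_input = n_input,
                 relative_size = S / Nd,
                 null_mean = null_mean, null_sd = null_sd,
                 z = z,
                 p_normal = if (degenerate) NA_real_ else p_from_z(z),
                 p_empirical = (sum(s_rand >= S) + 1) / (n_rand + 1),
                 n_rand = n_rand, ds = ds),
            class = "module_topology")
}

#' @export
print.module_topology <- function(x, ...) {
  cat(sprintf("module topology: S = %d of Nd = %d (%.1f%%)\n",
              x$S, x$Nd, 100 * x$relative_size))
  cat(sprintf("  null S_rand: %.2f +/- %.2f; z = %s, p_normal = %s, p_emp = %.3g\n",
              x$null_mean, x$null_sd,
              if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
              if (is.na(x$p_normal)) "NA" else sprintf("%.3g", x$p_normal),
              x$p_empirical))
  invisible(x)
}

#' Network separation of a disease gene set
#'
#' Mean, over all disease genes, of the shortest-path distance to the
#' nearest other disease gene. Genes unreachable from every other disease
#' gene are excluded with a message.
#'
#' @param network a [gene_network].
#' @param disease_genes character vector (at least two present in the
#'   network).
#' @return the separation statistic `d_s`.
#' @export
separation_ds <- function(network, disease_genes) {
  stopifnot(inherits(network, "gene_network"))
  present <- intersect(unique(normalize_symbols(disease_genes)),
                       network$nodes)
  if (length(present) < 2L) {
    stop_netsig("need at least 2 disease genes in the network",
                "netsig_undefined_statistic")
  }
  g <- as_igraph(network)
  d <- igraph::distances(g, v = present, to = present)
  diag(d) <- Inf
  nearest <- apply(d, 1L, min)
  unreachable <- !is.finite(nearest)
  if (any(unreachable)) {
    message(sprintf("%d disease gene(s) unreachable from any other were excluded",
                    sum(unreachable)))
  }
  if (sum(!unreachable) < 2L) {
    stop_netsig("fewer than 2 mutually reachable disease genes",
                "netsig_undefined_statistic")
  }
  mean(nearest[!unreachable])
}

#' Glass' Delta effect size
#'
#' Mean difference between treatment and control scaled by the control
#' group's standard deviation (denominator `n - 1`).
#'
#' @param treatment,control numeric samples.
#' @return the effect size.
#' @export
glass_delta <- function(treatment, control) {
  s <- stats::sd(control)
  if (!is.finite(s) || s == 0) {
    stop_netsig("control standard deviation is zero",
                "netsig_undefined_statistic")
  }
  (mean(treatment) - mean(control)) / s
}
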