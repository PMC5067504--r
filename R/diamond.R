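#' DIAMOnD connectivity p-value
#'
#' Probability that a gene of degree `k` has `ks` or more links to a seed
#' set of size `s`, out of `N` network genes, under the hypergeometric null:
#' \deqn{p = \sum_{i=k_s}^{\min(k, s)} \frac{\binom{s}{i}\binom{N-s}{k-i}}
#'   {\binom{N}{k}}}
#' Computed in log space via [stats::phyper]. This score penalizes hubs: a
#' large `k` inflates the chance of seed links arising by accident.
#'
#' @param N total number of network genes.
#' @param s current seed/expanded set size (`s < N`).
#' @param k gene degree (`k <= N - 1`).
#' @param ks links from the gene to the current set (`0 <= ks <= min(k, s)`).
#' @return the upper-tail hypergeometric p-value (vectorized over `k`, `ks`).
#' @export
diamond_connectivity_p <- function(N, s, k, ks) {
  assert_that(all(ks >= 0) && all(ks <= pmin(k, s)),
              "'ks' must satisfy 0 <= ks <= min(k, s)",
              class = "netsig_domain_error")
  assert_that(s >= 0 && s < N, "'s' must satisfy 0 <= s < N",
              class = "netsig_domain_error")
  assert_that(all(k >= 0) && all(k <= N - 1), "'k' must satisfy 0 <= k <= N - 1",
              class = "netsig_domain_error")
  exp(stats::phyper(ks - 1, s, N - s, k, lower.tail = FALSE, log.p = TRUE))
}

#' Iterative disease-module expansion (DIAMOnD)
#'
#' Starting from the seed genes, repeatedly adds the non-member gene whose
#' links to the current set are most hypergeometrically significant
#' ([diamond_connectivity_p]); the added gene joins the set and the next
#' iteration re-scores the frontier. Ties are broken by larger `ks`, then by
#' lexicographic gene symbol. Stops after `n_iter` additions or when no
#' remaining gene touches the set.
#'
#' @param network a [gene_network].
#' @param seeds seed gene symbols; members absent from the network are
#'   dropped with a warning.
#' @param n_iter number of genes to add (default 200).
#' @return data frame with one row per added gene, in addition order:
#'   `gene`, `rank`, `degree`, `ks` (links to the set when added), `p`.
#' @export
diamond_run <- function(network, seeds, n_iter = 200L) {
  stopifnot(inherits(network, "gene_network"))
  assert_count(n_iter, "n_iter")
  seeds <- unique(normalize_symbols(seeds))
  missing <- setdiff(seeds, network$nodes)
  if (length(missing) > 0L) {
    warning(sprintf("%d seed gene(s) absent from the network were dropped",
                    length(missing)))
  }
  seeds <- intersect(seeds, network$nodes)
  if (length(seeds) == 0L) {
    stop_netsig("no seed genes present in the network", "netsig_invalid_input")
  }

  nodes <- network$nodes # sorted, so node index order = lexicographic order
  N <- length(nodes)
  ai <- match(network$edges$gene_a, nodes)
  bi <- match(network$edges$gene_b, nodes)
  adj <- split(c(bi, ai), c(ai, bi))
  neighbors <- function(v) adj[[as.character(v)]]
  deg <- tabulate(c(ai, bi), nbins = N)

  in_set <- logical(N)
  in_set[match(seeds, nodes)] <- TRUE
  ks <- integer(N)
  for (v in which(in_set)) {
    nb <- neighbors(v)
    ks[nb] <- ks[nb] + 1L
  }

  out_gene <- character(n_iter)
  out_deg <- integer(n_iter)
  out_ks <- integer(n_iter)
  out_p <- numeric(n_iter)
  added <- 0L
  s <- sum(in_set)
  repeat {
    if (added >= n_iter) break
    cand <- which(!in_set & ks > 0L)
    if (length(cand) == 0L) {
      message("DIAMOnD frontier exhausted after ", added, " additions")
      break
    }
    p <- diamond_connectivity_p(N, s, deg[cand], pmin(ks[cand], s))
    best <- cand[order(p, -ks[cand], cand)][1L]
    added <- added + 1L
    out_gene[added] <- nodes[best]
    out_deg[added] <- deg[best]
    out_ks[added] <- ks[best]
    out_p[added] <- min(p)
    in_set[best] <- TRUE
    s <- s + 1L
    nb <- neighbors(best)
    if (!is.null(nb)) ks[nb] <- ks[nb] + 1L
  }
  keep <- seq_len(added)
  data.frame(gene = out_gene[keep], rank = keep, degree = out_deg[keep],
             ks = out_ks[keep], p = out_p[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
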