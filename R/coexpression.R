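#' Mutual information of two vectors by equal-frequency binning
#'
#' Discretizes both vectors into `bins` equal-frequency (rank-based) bins,
#' breaking ties by original index, and returns the mutual information of
#' the joint discretization in nats:
#' \deqn{MI = \sum_{ij} p(i,j) \ln\frac{p(i,j)}{p(i)p(j)}}
#'
#' Equal-frequency binning is a deliberately simple, transparent estimator;
#' it carries a positive bias of roughly `(B-1)^2 / (2n)` nats for
#' independent data, so `bins` should stay well below `sqrt(n)` when small
#' MI values matter.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of bins (default `max(2, floor(sqrt(n)))`).
#' @return mutual information in nats (zero, with a warning, for a constant
#'   input).
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  assert_that(length(y) == n, "'x' and 'y' must have equal length")
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  assert_that(bins >= 2L && n >= bins,
              "need length(x) >= bins >= 2")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input vector: mutual information is 0")
    return(0)
  }
  bx <- equal_freq_bins(x, bins)
  by <- equal_freq_bins(y, bins)
  joint <- table(bx, by) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  pij <- as.numeric(joint)
  expected <- as.numeric(outer(px, py))
  pos <- pij > 0
  sum(pij[pos] * log(pij[pos] / expected[pos]))
}

# rank-based equal-frequency bin index in 1..bins; ties by original index
equal_freq_bins <- function(x, bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

#' Build a mutual-information co-expression network
#'
#' Two steps: (1) compute pairwise MI between all gene expression profiles
#' on `log2(x + 1)`-transformed values across all samples and keep pairs
#' with `MI >= threshold`; (2) prune indirect edges with the data processing
#' inequality ([dpi_prune]). Resulting edges are tagged
#' `source = "coexpression"` and carry their MI as metadata.
#'
#' @param expr an [expression_matrix].
#' @param threshold minimum MI in nats (default 1.0).
#' @param bins number of discretization bins (default
#'   `max(2, floor(sqrt(n_samples)))`).
#' @param tolerance DPI tolerance passed to [dpi_prune].
#' @return a [gene_network] with source tag `"coexpression"`.
#' @export
build_mi_network <- function(expr, threshold = 1.0, bins = NULL,
                             tolerance = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  assert_that(threshold >= 0, "'threshold' must be >= 0",
              class = "netsig_invalid_config")
  counts <- expr$counts
  assert_that(nrow(counts) >= 2L, "need at least 2 genes")
  n <- ncol(counts)
  if (is.null(bins)) bins <- max(2L, floor(sqrt(n)))
  assert_that(bins >= 2L && n >= bins, "need n_samples >= bins >= 2")
  lx <- log2(counts + 1)
  binmat <- t(apply(lx, 1L, equal_freq_bins, bins = bins))
  storage.mode(binmat) <- "integer"
  if (!is.finite(threshold)) {
    return(gene_network(source_tag = "coexpression"))
  }
  hits <- mi_pairs_above(binmat, bins, threshold)
  if (nrow(hits) == 0L) {
    return(gene_network(source_tag = "coexpression"))
  }
  genes <- rownames(counts)
  mi_edges <- data.frame(gene_a = genes[hits[, 1L]],
                         gene_b = genes[hits[, 2L]],
                         mi = hits[, 3L], stringsAsFactors = FALSE)
  pruned <- dpi_prune(mi_edges, tolerance = tolerance)
  gene_network(pruned, source_tag = "coexpression")
}

#' Prune indirect edges with the data processing inequality
#'
#' For every triangle of MI edges, the edge with the strictly smallest MI is
#' marked for removal when `mi_weakest < (1 - tolerance) * min(mi_other1,
#' mi_other2)`. Marking is done against the original edge set and all marked
#' edges are removed simultaneously, so the result does not depend on edge
#' iteration order. Ties (no strict minimum) remove nothing.
#'
#' @param mi_edges data frame with columns `gene_a`, `gene_b`, `mi`.
#' @param tolerance DPI tolerance in `[0, 1]` (default 0, the strict rule).
#' @return the pruned edge data frame.
#' @export
dpi_prune <- function(mi_edges, tolerance = 0) {
  assert_that(all(c("gene_a", "gene_b", "mi") %in% names(mi_edges)),
              "'mi_edges' needs columns gene_a, gene_b, mi")
  assert_prob(tolerance, "tolerance")
  ne <- nrow(mi_edges)
  if (ne < 3L) return(mi_edges)
  a <- pmin(mi_edges$gene_a, mi_edges$gene_b)
  b <- pmax(mi_edges$gene_a, mi_edges$gene_b)
  mi <- mi_edges$mi
  nodes <- sort(unique(c(a, b)))
  ai <- match(a, nodes)
  bi <- match(b, nodes)
  eid <- matrix(0L, length(nodes), length(nodes))
  eid[cbind(ai, bi)] <- seq_len(ne)
  eid[cbind(bi, ai)] <- seq_len(ne)
  nbrs <- lapply(seq_along(nodes), function(v) {
    sort(c(bi[ai == v], ai[bi == v]))
  })
  drop <- rep(FALSE, ne)
  for (e in seq_len(ne)) {
    common <- intersect(nbrs[[ai[e]]], nbrs[[bi[e]]])
    for (cn in common) {
      e2 <- eid[ai[e], cn]
      e3 <- eid[bi[e], cn]
      m <- c(mi[e], mi[e2], mi[e3])
      weakest <- which(m == min(m))
      if (length(weakest) == 1L && weakest == 1L &&
          m[1L] < (1 - tolerance) * min(m[2L], m[3L])) {
        drop[e] <- TRUE
        break
      }
    }
  }
  out <- mi_edges[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
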