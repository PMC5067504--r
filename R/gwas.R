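#' Bin SNPs to genes positionally and through LD
#'
#' A SNP belongs to a gene's bin if it lies within the gene's 1-based
#' inclusive coordinates, or if it is in LD (`r2 >= r2_threshold`) with
#' another SNP that lies within those coordinates. A single LD hop only —
#' no transitive chaining — and a SNP may belong to several bins.
#'
#' @param snps data frame with columns `id`, `chrom`, `pos`.
#' @param genes data frame with columns `chrom`, `start`, `end`, `gene`.
#' @param ld optional data frame with columns `snp1`, `snp2`, `r2`.
#' @param r2_threshold minimum r-squared for the LD hop (default 0.8).
#' @return named list mapping gene to the character vector of member SNP
#'   ids (genes with empty bins are omitted).
#' @export
bin_snps_to_genes <- function(snps, genes, ld = NULL, r2_threshold = 0.8) {
  assert_that(all(genes$start <= genes$end),
              "gene intervals must have start <= end")
  assert_that(!anyDuplicated(snps$id), "SNP ids must be unique")
  bins <- lapply(seq_len(nrow(genes)), function(i) {
    inside <- snps$chrom == genes$chrom[i] &
      snps$pos >= genes$start[i] & snps$pos <= genes$end[i]
    members <- snps$id[inside]
    if (!is.null(ld) && nrow(ld) > 0L && length(members) > 0L) {
      hit <- ld$r2 >= r2_threshold &
        (ld$snp1 %in% members | ld$snp2 %in% members)
      partners <- c(ld$snp1[hit], ld$snp2[hit])
      members <- union(members, intersect(partners, snps$id))
    }
    sort(members)
  })
  names(bins) <- genes$gene
  bins[lengths(bins) > 0L]
}

#' Sidak-corrected minimum p-value for a SNP bin
#'
#' Gene-level p from the minimum SNP p in a bin of size `m`:
#' `p_gene = 1 - (1 - p_min)^m`, evaluated via `expm1`/`log1p` so that very
#' small p-values survive.
#'
#' @param p SNP p-values in the bin (or the precomputed minimum).
#' @param m bin size (default `length(p)`).
#' @return the gene-level p-value.
#' @export
gene_p_sidak <- function(p, m = length(p)) {
  assert_count(m, "m")
  assert_prob(p, "p")
  p_min <- min(p)
  -expm1(m * log1p(-p_min))
}

#' Simes combination for a SNP bin
#'
#' Alternative gene-level p: `min_i (m * p_(i) / i)` over the sorted bin
#' p-values.
#'
#' @param p SNP p-values in the bin.
#' @return the Simes p-value.
#' @export
gene_p_simes <- function(p) {
  assert_prob(p, "p")
  assert_that(length(p) >= 1L, "empty bin")
  ps <- sort(p)
  min(1, min(length(p) * ps / seq_along(ps)))
}

#' Gene-level p-values for all bins
#'
#' @param bins output of [bin_snps_to_genes].
#' @param snp_p named vector of SNP p-values.
#' @param method `"sidak"` (default) or `"simes"`.
#' @return named numeric vector of gene-level p-values.
#' @export
gene_level_p <- function(bins, snp_p, method = c("sidak", "simes")) {
  method <- match.arg(method)
  vapply(bins, function(ids) {
    p <- snp_p[ids]
    p <- p[!is.na(p)]
    if (length(p) == 0L) return(NA_real_)
    if (method == "sidak") gene_p_sidak(p) else gene_p_simes(p)
  }, numeric(1L))
}

#' Genomic inflation factor
#'
#' `lambda_gc` is the median 1-df chi-squared association statistic divided
#' by its null median (0.4549364...).
#'
#' @param pvals SNP p-values in (0, 1].
#' @return list of class `gwas_qc` with element `lambda_gc`.
#' @export
lambda_gc <- function(pvals) {
  assert_that(length(pvals) > 0L, "empty p-value vector")
  assert_prob(pvals, "pvals", open_zero = TRUE)
  stat <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  structure(list(lambda_gc = stats::median(stat) /
                   stats::qchisq(0.5, df = 1)),
            class = "gwas_qc")
}

#' @export
print.gwas_qc <- function(x, ...) {
  cat(sprintf("lambda_gc = %.3f\n", x$lambda_gc))
  invisible(x)
}

#' Fraction-below-threshold curves against random control gene sets
#'
#' For each query gene set and each threshold on a log-spaced grid, the
#' fraction of member genes with gene-level p at or below the threshold is
#' compared with a band from `n_controls` uniformly sampled size-matched
#' control sets.
#'
#' @param gene_p named vector of gene-level p-values.
#' @param query_sets named list of gene sets; members missing from
#'   `gene_p` are dropped (count reported via attribute `n_dropped`).
#' @param n_controls number of random control sets (default 100).
#' @param seed RNG seed.
#' @param grid threshold grid (default `10^seq(-8, 0, length.out = 33)`).
#' @return named list, one data frame per query set with columns
#'   `threshold`, `fraction`, `ctrl_mean`, `ctrl_sd`.
#' @export
qq_fraction_comparison <- function(gene_p, query_sets, n_controls = 100L,
                                   seed = 1L,
                                   grid = 10^seq(-8, 0, length.out = 33)) {
  assert_count(n_controls, "n_controls")
  assert_that(length(gene_p) > 0L && !is.null(names(gene_p)),
              "'gene_p' must be a named vector")
  set.seed(seed)
  frac_curve <- function(p) vapply(grid, function(t) mean(p <= t), numeric(1L))
  out <- lapply(query_sets, function(qs) {
    qs <- unique(normalize_symbols(qs))
    assert_that(length(qs) > 0L, "empty query set")
    present <- intersect(qs, names(gene_p))
    n_dropped <- length(qs) - length(present)
    assert_that(length(present) > 0L,
                "no query gene has a gene-level p-value")
    qcurve <- frac_curve(gene_p[present])
    ctrl <- vapply(seq_len(n_controls), function(i) {
      frac_curve(gene_p[sample.int(length(gene_p), length(present))])
    }, numeric(length(grid)))
    res <- data.frame(threshold = grid, fraction = qcurve,
                      ctrl_mean = rowMeans(ctrl),
                      ctrl_sd = apply(ctrl, 1L, stats::sd))
    attr(res, "n_dropped") <- n_dropped
    res
  })
  out
}

#' One-sided Fisher enrichment on a 2x2 table
#'
#' Upper-tail hypergeometric p for the table `[[a, b], [c, d]]` (the
#' `"greater"` alternative on cell `a`) and the sample odds ratio
#' `(a d) / (b c)` (infinite when `b c = 0` and `a d > 0`).
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  assert_that(all(cells >= 0) && all(cells == floor(cells)),
              "cells must be nonnegative integers")
  assert_that(sum(cells) >= 1, "table must contain at least one observation")
  p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NA_real_
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Monte-Carlo enrichment of an annotation in a SNP set
#'
#' The observed statistic is the number of query SNPs carrying the
#' annotation flag; the null is the same count for `n_rand` random
#' size-matched SNP sets drawn without replacement from the background
#' (generated as hypergeometric draws, which is exactly that distribution).
#' The empirical p uses the plus-one convention
#' `(#\{null >= observed\} + 1) / (n_rand + 1)`, so its floor at one
#' million draws is 1e-6.
#'
#' @param query_snps character vector of query SNP ids (subset of the
#'   background).
#' @param background character vector of all background SNP ids.
#' @param flags 0/1 annotation flags: a named vector over background ids,
#'   or a data frame whose first column is `id` and whose remaining columns
#'   are 0/1 annotations (a SNP is flagged if any column is 1).
#' @param n_rand number of randomizations (default 1e6, minimum 100).
#' @param seed RNG seed.
#' @return list with `observed`, `n_query`, `null_mean`, `null_sd`, `p`,
#'   `n_rand`.
#' @export
monte_carlo_snp_enrichment <- function(query_snps, background, flags,
                                       n_rand = 1e6, seed = 1L) {
  assert_count(n_rand, "n_rand", min = 100L)
  if (is.data.frame(flags)) {
    ids <- flags[[1L]]
    mat <- as.matrix(flags[, -1L, drop = FALSE])
    flags <- stats::setNames(as.integer(rowSums(mat) > 0), ids)
  }
  query_snps <- unique(query_snps)
  background <- unique(background)
  assert_that(all(query_snps %in% background),
              "'query_snps' must be a subset of 'background'")
  assert_that(length(query_snps) <= length(background),
              "query larger than background")
  fl <- flags[background]
  fl[is.na(fl)] <- 0L
  K <- sum(fl == 1L)
  N <- length(background)
  q <- length(query_snps)
  observed <- sum(fl[query_snps] == 1L, na.rm = TRUE)
  set.seed(seed)
  null <- stats::rhyper(n_rand, K, N - K, q)
  list(observed = observed, n_query = q,
       null_mean = mean(null), null_sd = stats::sd(null),
       p = (sum(null >= observed) + 1) / (n_rand + 1),
       n_rand = n_rand)
}

#' Expand a SNP set through perfect LD
#'
#' Perfect LD (`r2 = 1` and `D' = 1`) is an equivalence, so the expansion
#' is the union of the connected components containing the query SNPs in
#' the perfect-LD subgraph.
#'
#' @param snps character vector of query SNP ids.
#' @param ld data frame with columns `snp1`, `snp2`, `r2`, `dprime`.
#' @return character vector: the query plus every SNP transitively linked
#'   by perfect-LD pairs.
#' @export
perfect_ld_expand <- function(snps, ld) {
  snps <- unique(snps)
  if (is.null(ld) || nrow(ld) == 0L) return(sort(snps))
  perfect <- ld$r2 == 1 & ld$dprime == 1
  if (!any(perfect)) return(sort(snps))
  a <- ld$snp1[perfect]
  b <- ld$snp2[perfect]
  vertices <- unique(c(a, b, snps))
  comp <- induced_components(vertices, a, b)
  hit_comps <- unique(comp[vertices %in% snps])
  sort(unique(c(snps, vertices[comp %in% hit_comps])))
}

#' Approximate log Bayes factor for one eSNP
#'
#' Wakefield-style approximate Bayes factor on the GWAS z-score of an eSNP:
#' \deqn{LBF = \frac{1}{2}\ln\frac{V}{V+W} + \frac{z^2 W}{2(V+W)}}
#' Negative near `z = 0` (evidence against association), positive for large
#' `|z|`; SNPs outside a gene's eSNP list simply contribute nothing.
#'
#' @param z eSNP GWAS z-score (vectorized).
#' @param V variance of the GWAS effect estimate (`> 0`).
#' @param W prior effect variance (`>= 0`; default 0.04).
#' @return log Bayes factor(s).
#' @export
sherlock_lbf <- function(z, V = 1, W = 0.04) {
  assert_that(all(V > 0), "'V' must be > 0", class = "netsig_domain_error")
  assert_that(all(W >= 0), "'W' must be >= 0", class = "netsig_domain_error")
  0.5 * log(V / (V + W)) + z^2 * W / (2 * (V + W))
}

#' Sherlock-style gene score from eSNP GWAS z-scores
#'
#' Sums the per-eSNP log Bayes factors of a gene's eSNPs and calibrates the
#' total by permutation: each permutation redraws the same number of
#' z-scores (with replacement) from the full GWAS z pool.
#'
#' @param esnp_z GWAS z-scores of the gene's eSNPs (at least one).
#' @param z_pool full GWAS z-score pool to permute from.
#' @param V,W Bayes-factor parameters (see [sherlock_lbf]).
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return list with `total_lbf`, `per_esnp_lbf`, `p`, `n_perm`.
#' @export
sherlock_gene_score <- function(esnp_z, z_pool, V = 1, W = 0.04,
                                n_perm = 1000L, seed = 1L) {
  assert_that(length(esnp_z) >= 1L, "gene has no eSNPs")
  assert_count(n_perm, "n_perm", min = 100L)
  lbf <- sherlock_lbf(esnp_z, V, W)
  total <- sum(lbf)
  m <- length(esnp_z)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    sum(sherlock_lbf(z_pool[sample.int(length(z_pool), m, replace = TRUE)],
                     V, W))
  }, numeric(1L))
  list(total_lbf = total, per_esnp_lbf = lbf,
       p = (sum(perm >= total) + 1) / (n_perm + 1), n_perm = n_perm)
}
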