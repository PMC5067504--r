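#' Two-group negative-binomial Wald test
#'
#' A deliberately simple differential-expression test for two-group count
#' data: library sizes are normalized by the median-of-ratios method, the
#' log2 fold change is computed on normalized group means with a 0.5
#' pseudocount, a per-gene dispersion is estimated by method of moments
#' (floored at 1e-8), and a Wald statistic on the log2 scale is referred to
#' a t distribution with `n1 + n2 - 2` degrees of freedom as a small-sample
#' correction. Genes with all-zero counts get `log2fc = 0`, `p = 1`.
#'
#' This is an approximate stand-in for a full shrinkage-based NB analysis;
#' externally computed per-gene tables (`gene`, `log2fc`, `p`) are accepted
#' everywhere downstream via [dge_stats].
#'
#' @param expr an [expression_matrix] with integer counts and at least two
#'   samples per group.
#' @return data frame with columns `gene`, `log2fc`, `p`.
#' @export
nb_wald_test <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  counts <- expr$counts
  groups <- expr$groups
  if (any(counts != floor(counts))) {
    stop_netsig("non-integer counts: supply an external per-gene stats table via dge_stats() instead",
                "netsig_invalid_input")
  }
  n1 <- sum(groups == "case")
  n0 <- sum(groups == "control")
  assert_that(n1 >= 2L && n0 >= 2L, "need at least 2 samples per group")

  sf <- median_of_ratios(counts)
  norm <- sweep(counts, 2L, sf, `/`)

  case <- norm[, groups == "case", drop = FALSE]
  ctrl <- norm[, groups == "control", drop = FALSE]
  mu1 <- rowMeans(case)
  mu0 <- rowMeans(ctrl)
  log2fc <- log2((mu1 + 0.5) / (mu0 + 0.5))

  v1 <- apply(case, 1L, stats::var)
  v0 <- apply(ctrl, 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  mu_bar <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  phi <- pmax((s2 - mu_bar) / mu_bar^2, 1e-8)
  phi[!is.finite(phi)] <- 1e-8

  var_mean1 <- (mu1 + phi * mu1^2) / n1
  var_mean0 <- (mu0 + phi * mu0^2) / n0
  se <- sqrt(var_mean1 / ((mu1 + 0.5) * log(2))^2 +
               var_mean0 / ((mu0 + 0.5) * log(2))^2)
  wald <- log2fc / se
  p <- 2 * stats::pt(-abs(wald), df = n1 + n0 - 2)

  zero <- mu1 + mu0 == 0
  log2fc[zero] <- 0
  p[zero | !is.finite(p)] <- 1

  data.frame(gene = rownames(counts), log2fc = log2fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# DESeq-style size factors; falls back to column-sum ratios when no gene is
# expressed in every sample.
median_of_ratios <- function(counts) {
  logc <- log(counts)
  ok <- is.finite(rowSums(logc))
  if (any(ok)) {
    logmeans <- rowMeans(logc[ok, , drop = FALSE])
    sf <- apply(logc[ok, , drop = FALSE], 2L,
                function(col) exp(stats::median(col - logmeans)))
  } else {
    cs <- colSums(counts)
    sf <- cs / exp(mean(log(pmax(cs, 1))))
  }
  sf[sf <= 0 | !is.finite(sf)] <- 1
  sf
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, returned in
#' input order and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  assert_prob(pvals, "pvals")
  stats::p.adjust(pvals, method = "BH")
}

#' Assemble a per-gene differential-expression table
#'
#' Adds BH-adjusted p-values and the significance flag
#' `padj < alpha & |log2fc| > lfc_threshold` (both strict) to a raw stats
#' table, which may come from [nb_wald_test] or from any external test.
#'
#' @param stats data frame with columns `gene`, `log2fc`, `p`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_threshold absolute log2-fold-change cutoff (default 0.75).
#' @return the table with `padj` and `significant` columns added.
#' @export
dge_stats <- function(stats, alpha = 0.05, lfc_threshold = 0.75) {
  assert_that(all(c("gene", "log2fc", "p") %in% names(stats)),
              "'stats' needs columns gene, log2fc, p")
  stats$padj <- bh_adjust(stats$p)
  stats$significant <- stats$padj < alpha & abs(stats$log2fc) > lfc_threshold
  stats
}

#' Select differentially expressed genes
#'
#' Applies the significance filter `padj < alpha` and
#' `|log2fc| > lfc_threshold` (both inequalities strict) and reports
#' direction counts and the median absolute log2 fold change per direction
#' as a `summary` attribute.
#'
#' @param stats a table from [dge_stats] (a `padj` column is added if
#'   absent).
#' @param alpha adjusted-p cutoff.
#' @param lfc_threshold absolute log2-fold-change cutoff.
#' @return character vector of significant genes, with attribute `summary`
#'   (list with `n_up`, `n_down`, `median_lfc_up`, `median_lfc_down`).
#' @export
select_deg <- function(stats, alpha = 0.05, lfc_threshold = 0.75) {
  if (!"padj" %in% names(stats)) stats <- dge_stats(stats, alpha, lfc_threshold)
  keep <- stats$padj < alpha & abs(stats$log2fc) > lfc_threshold
  up <- keep & stats$log2fc > 0
  down <- keep & stats$log2fc < 0
  genes <- stats$gene[keep]
  attr(genes, "summary") <- list(
    n_up = sum(up), n_down = sum(down),
    median_lfc_up = if (any(up)) stats::median(stats$log2fc[up]) else NA_real_,
    median_lfc_down = if (any(down)) stats::median(stats$log2fc[down]) else NA_real_)
  genes
}
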