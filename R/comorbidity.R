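#' Filter comorbid diseases by relative risk
#'
#' Keeps diseases with `rr >= rr_min` and a lower confidence bound strictly
#' above `ci_low_min`.
#'
#' @param diseases list of `comorbid_disease` records (fields `name`,
#'   `genes`, `rr`, `rr_ci_low`), e.g. from [read_gmt] or
#'   [simulate_comorbidity].
#' @param rr_min minimum relative risk (default 1.5, inclusive).
#' @param ci_low_min lower confidence bound threshold (default 1.0,
#'   exclusive).
#' @return the filtered list.
#' @export
filter_comorbid <- function(diseases, rr_min = 1.5, ci_low_min = 1.0) {
  Filter(function(d) d$rr >= rr_min && d$rr_ci_low > ci_low_min, diseases)
}

#' Fisher enrichment of signature genes in a comorbid-disease gene set
#'
#' Builds the 2x2 overlap table over the gene universe and delegates to
#' [fisher_enrichment] (one-sided, greater).
#'
#' @param signatures signature gene symbols.
#' @param disease a `comorbid_disease` record or a character gene set.
#' @param universe the gene universe containing both sets.
#' @return list with `overlap`, `odds_ratio`, `p`.
#' @export
comorbid_gene_enrichment <- function(signatures, disease, universe) {
  universe <- unique(normalize_symbols(universe))
  assert_that(length(universe) > 0L, "empty gene universe")
  dis_genes <- if (is.list(disease)) disease$genes else disease
  sig <- intersect(unique(normalize_symbols(signatures)), universe)
  dis <- intersect(unique(normalize_symbols(dis_genes)), universe)
  a <- length(intersect(sig, dis))
  b <- length(sig) - a
  cc <- length(dis) - a
  d <- length(universe) - a - b - cc
  fe <- fisher_enrichment(a, b, cc, d)
  list(overlap = a, odds_ratio = fe$odds_ratio, p = fe$p)
}

#' TF-IDF cosine similarity between disease symptom profiles
#'
#' Weights each term by its frequency in a disease times the inverse
#' document frequency `ln(N / n_t)` (natural log, no smoothing by default;
#' `smooth = TRUE` uses `ln((1 + N) / (1 + n_t))`), then returns pairwise
#' cosine similarities. A term present in every disease gets weight 0; a
#' disease whose whole vector is zero has similarity 0 against all others
#' and is reported in the `zero_vector` attribute.
#'
#' @param corpus either a data frame with columns `disease`, `term`,
#'   `count`, or a named list of term multisets (character vectors with
#'   repeats).
#' @param smooth use smoothed idf (default `FALSE`).
#' @return symmetric similarity matrix with entries in `[0, 1]`; diagonal 1
#'   for diseases with a nonzero vector.
#' @export
tfidf_similarity <- function(corpus, smooth = FALSE) {
  if (!is.data.frame(corpus)) {
    corpus <- do.call(rbind, lapply(names(corpus), function(d) {
      tt <- table(corpus[[d]])
      data.frame(disease = d, term = names(tt), count = as.integer(tt),
                 stringsAsFactors = FALSE)
    }))
  }
  assert_that(all(c("disease", "term", "count") %in% names(corpus)),
              "'corpus' needs columns disease, term, count")
  diseases <- unique(corpus$disease)
  assert_that(length(diseases) >= 2L, "need at least 2 diseases")
  terms <- unique(corpus$term)
  tf <- matrix(0, nrow = length(diseases), ncol = length(terms),
               dimnames = list(diseases, terms))
  tf[cbind(match(corpus$disease, diseases),
           match(corpus$term, terms))] <- corpus$count
  n_t <- colSums(tf > 0)
  N <- length(diseases)
  idf <- if (smooth) log((1 + N) / (1 + n_t)) else log(N / n_t)
  w <- sweep(tf, 2L, idf, `*`)
  norms <- sqrt(rowSums(w^2))
  zero <- norms == 0
  safe <- ifelse(zero, 1, norms)
  sim <- (w %*% t(w)) / outer(safe, safe)
  sim[zero, ] <- 0
  sim[, zero] <- 0
  diag(sim) <- ifelse(zero, 0, 1)
  sim <- pmin(pmax(sim, 0), 1)
  attr(sim, "zero_vector") <- diseases[zero]
  sim
}
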