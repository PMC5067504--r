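#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one set per line with the set
#' name, a free-text description, then the member genes. When the
#' description carries `RR=<x>;CI_low=<y>`, relative-risk metadata is
#' parsed into the returned records so the sets can feed
#' [filter_comorbid].
#'
#' @param path file path.
#' @return `read_gmt`: a list of records with fields `name`, `description`,
#'   `genes`, and (when present in the description) `rr`, `rr_ci_low`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    assert_that(length(parts) >= 3L,
                "malformed GMT line: need name, description, >= 1 gene",
                class = "netsig_parse_error")
    rec <- list(name = parts[1L], description = parts[2L],
                genes = sort(unique(normalize_symbols(parts[-c(1L, 2L)]))))
    m <- regmatches(parts[2L],
                    regexec("RR=([0-9.eE+-]+);CI_low=([0-9.eE+-]+)", parts[2L]))[[1L]]
    if (length(m) == 3L) {
      rec$rr <- as.numeric(m[2L])
      rec$rr_ci_low <- as.numeric(m[3L])
      class(rec) <- "comorbid_disease"
    }
    rec
  })
}

#' @param sets list of records with fields `name`, `description`, `genes`.
#' @rdname read_gmt
#' @return `write_gmt`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts matrix with a sample-group table
#'
#' @param counts_path TSV with a `gene` column followed by one column per
#'   sample.
#' @param samples_path two-column TSV (sample id, group `case`/`control`)
#'   without header.
#' @return an [expression_matrix].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- normalize_symbols(df[[1L]])
  smp <- utils::read.delim(samples_path, header = FALSE,
                           col.names = c("sample", "group"))
  groups <- smp$group[match(colnames(counts), smp$sample)]
  expression_matrix(counts, groups)
}

#' Read GWAS summary statistics, LD pairs, and gene coordinates
#'
#' Thin TSV readers validating the column contracts used across the GWAS
#' integration layer.
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_gwas <- function(path) {
  df <- utils::read.delim(path)
  assert_that(all(c("id", "chrom", "pos", "p") %in% names(df)),
              "GWAS table needs columns id, chrom, pos, p")
  assert_prob(df$p, "p", open_zero = TRUE)
  df
}

#' @rdname read_gwas
#' @export
read_ld <- function(path) {
  df <- utils::read.delim(path)
  assert_that(all(c("snp1", "snp2", "r2", "dprime") %in% names(df)),
              "LD table needs columns snp1, snp2, r2, dprime")
  # canonicalize pair order so (a,b) and (b,a) collapse
  a <- pmin(df$snp1, df$snp2)
  b <- pmax(df$snp1, df$snp2)
  df$snp1 <- a
  df$snp2 <- b
  df[!duplicated(df[, c("snp1", "snp2")]), , drop = FALSE]
}

#' @rdname read_gwas
#' @export
read_gene_coords <- function(path) {
  df <- utils::read.delim(path)
  assert_that(all(c("chrom", "start", "end", "gene") %in% names(df)),
              "gene table needs columns chrom, start, end, gene")
  assert_that(all(df$start <= df$end), "gene intervals must have start <= end")
  df$gene <- normalize_symbols(df$gene)
  df
}
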