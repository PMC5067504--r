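#' Gene network container
#'
#' An undirected simple graph over gene symbols. Edges carry a source tag
#' recording whether they come from the curated physical interactome, the
#' de novo co-expression network, or both. Symbols are upper-cased on entry;
#' self-loops and duplicate edges are collapsed.
#'
#' @param edges a data frame with at least two character columns giving the
#'   endpoints of each edge; an optional `source` column with values in
#'   `"physical"`, `"coexpression"`, `"both"`, and an optional numeric `mi`
#'   column carrying mutual-information scores as edge metadata.
#' @param nodes optional additional node symbols (isolated nodes are kept).
#' @param source_tag default source tag applied when `edges` has no `source`
#'   column.
#' @return an object of class `gene_network` with elements `nodes` (sorted
#'   character vector) and `edges` (data frame with columns `gene_a`,
#'   `gene_b`, `source`, and `mi` where available; `gene_a < gene_b`).
#' @export
gene_network <- function(edges = NULL, nodes = NULL,
                         source_tag = c("physical", "coexpression")) {
  source_tag <- match.arg(source_tag)
  n_loops <- 0L
  if (is.null(edges) || nrow(edges) == 0L) {
    ed <- data.frame(gene_a = character(), gene_b = character(),
                     source = character(), stringsAsFactors = FALSE)
  } else {
    a <- normalize_symbols(edges[[1L]])
    b <- normalize_symbols(edges[[2L]])
    assert_that(all(nzchar(a)) && all(nzchar(b)),
                "gene symbols must be nonempty after trimming whitespace")
    src <- if ("source" %in% names(edges)) as.character(edges$source)
           else rep(source_tag, length(a))
    mi <- if ("mi" %in% names(edges)) as.numeric(edges$mi) else NULL
    keep <- a != b
    n_loops <- sum(!keep)
    ga <- pmin(a[keep], b[keep])
    gb <- pmax(a[keep], b[keep])
    src <- src[keep]
    if (!is.null(mi)) mi <- mi[keep]
    key <- paste(ga, gb, sep = "\r")
    first <- !duplicated(key)
    # an edge reported under both tags collapses to "both"
    kf <- factor(key, levels = key[first])
    has_p <- rowsum(as.integer(src %in% c("physical", "both")), kf) > 0L
    has_c <- rowsum(as.integer(src %in% c("coexpression", "both")), kf) > 0L
    src_merged <- ifelse(has_p & has_c, "both",
                         ifelse(has_p, "physical", "coexpression"))
    ed <- data.frame(gene_a = ga[first], gene_b = gb[first],
                     source = as.vector(src_merged),
                     stringsAsFactors = FALSE)
    if (!is.null(mi)) {
      mi_na <- ifelse(is.na(mi), -Inf, mi)
      mi_merged <- as.vector(rowsum(mi_na, kf))
      # rowsum sums; recover the max for the rare duplicated key
      if (anyDuplicated(key)) {
        dup_keys <- levels(kf)[tabulate(kf) > 1L]
        for (dk in dup_keys) {
          mi_merged[match(dk, levels(kf))] <- max(mi_na[key == dk])
        }
      }
      ed$mi <- ifelse(is.finite(mi_merged), mi_merged, NA_real_)
    }
    o <- order(ed$gene_a, ed$gene_b)
    ed <- ed[o, , drop = FALSE]
    rownames(ed) <- NULL
  }
  all_nodes <- sort(unique(c(ed$gene_a, ed$gene_b,
                             if (!is.null(nodes)) normalize_symbols(nodes))))
  net <- structure(list(nodes = all_nodes, edges = ed,
                        n_self_loops_dropped = n_loops),
                   class = "gene_network")
  if (n_loops > 0L) {
    message(sprintf("dropped %d self-loop(s)", n_loops))
  }
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    print(table(x$edges$source))
  }
  invisible(x)
}

#' Number of nodes and edges
#' @param network a `gene_network`.
#' @return integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Convert a gene network to an igraph object
#'
#' @param network a `gene_network`.
#' @return an undirected [igraph::graph] whose vertices are the gene symbols.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  igraph::graph_from_data_frame(
    network$edges[, c("gene_a", "gene_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

#' Read an undirected edge list from a TSV file
#'
#' Expects two or three tab-separated columns (`geneA`, `geneB`, and an
#' optional `source`). A header row matching those column names is skipped.
#' Symbols are upper-cased, duplicate rows collapsed, and self-loops dropped
#' with a message.
#'
#' @param path file path.
#' @param source_tag source tag used when the file carries no source column.
#' @return a [gene_network].
#' @export
read_edge_list <- function(path, source_tag = "physical") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty edge-list file: returning an empty network")
    return(gene_network())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (tolower(parts[[1L]][1L]) %in% c("genea", "gene_a", "from")) start <- 2L
  if (start > length(parts)) {
    warning("empty edge-list file: returning an empty network")
    return(gene_network())
  }
  body <- parts[start:length(parts)]
  expected <- length(body[[1L]])
  assert_that(expected >= 2L,
              sprintf("parse error at line %d: expected >= 2 columns", start),
              class = "netsig_parse_error")
  nc <- lengths(body)
  bad <- which(nc != expected)
  if (length(bad) > 0L) {
    stop_netsig(sprintf("parse error at line %d: expected %d columns, found %d",
                        bad[1L] + start - 1L, expected, nc[bad[1L]]),
                "netsig_parse_error")
  }
  ed <- data.frame(gene_a = vapply(body, `[[`, "", 1L),
                   gene_b = vapply(body, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (expected >= 3L) ed$source <- vapply(body, `[[`, "", 3L)
  gene_network(ed, source_tag = source_tag)
}

#' Write a gene network as an edge-list TSV
#'
#' @param network a [gene_network].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  ed <- network$edges
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("geneA\tgeneB\tsource",
               if (nrow(ed) > 0L)
                 paste(ed$gene_a, ed$gene_b, ed$source, sep = "\t")),
             con = con)
  invisible(path)
}

#' Merge a physical and a co-expression network
#'
#' Takes the union of the node and edge sets. An edge present in both inputs
#' carries the `"both"` tag, so the merged edge count is
#' `|E_phys| + |E_coexpr| - |E_shared|`.
#'
#' @param physical,coexpr two [gene_network] objects.
#' @return the merged [gene_network].
#' @export
merge_networks <- function(physical, coexpr) {
  stopifnot(inherits(physical, "gene_network"),
            inherits(coexpr, "gene_network"))
  cols <- c("gene_a", "gene_b", "source")
  e1 <- physical$edges[, cols, drop = FALSE]
  e2 <- coexpr$edges[, cols, drop = FALSE]
  ed <- rbind(e1, e2)
  if ("mi" %in% names(coexpr$edges)) {
    ed$mi <- c(rep(NA_real_, nrow(e1)), coexpr$edges$mi)
  }
  gene_network(ed, nodes = c(physical$nodes, coexpr$nodes))
}

#' Fraction of a reference interaction count covered by a network
#'
#' Expresses the size of a merged interactome relative to an estimated total
#' number of interactions in the complete human interactome.
#'
#' @param network a [gene_network], or an edge count.
#' @param reference_total estimated total interaction count
#'   (default 650,000, a published estimate for the human interactome).
#' @return coverage as a percentage.
#' @export
interactome_coverage <- function(network, reference_total = 650000) {
  ne <- if (inherits(network, "gene_network")) n_edges(network)
        else as.numeric(network)
  assert_that(reference_total > 0, "'reference_total' must be positive")
  100 * ne / reference_total
}

#' Maximum-likelihood power-law exponent of the degree distribution
#'
#' Fits the tail of the degree distribution by the continuous
#' maximum-likelihood estimator
#' \deqn{\hat\alpha = 1 + n / \sum_i \ln(k_i / (x_{min} - 0.5))}
#' over all degrees `k_i >= xmin`.
#'
#' @param network a [gene_network], or a numeric vector of degrees.
#' @param xmin minimum degree included in the fit (default 2).
#' @return a list of class `degree_fit` with elements `alpha`, `xmin`,
#'   `n_tail`.
#' @export
power_law_fit <- function(network, xmin = 2) {
  degs <- if (inherits(network, "gene_network")) {
    igraph::degree(as_igraph(network))
  } else {
    as.numeric(network)
  }
  assert_that(xmin >= 1, "'xmin' must be >= 1")
  tail_degs <- degs[degs >= xmin]
  if (length(tail_degs) < 2L) {
    stop_netsig("fewer than 2 nodes with degree >= xmin",
                "netsig_insufficient_data")
  }
  if (all(tail_degs == xmin)) {
    # a flat tail carries no slope information; the MLE diverges
    stop_netsig("degenerate degree tail: all tail degrees equal xmin",
                "netsig_degenerate_input")
  }
  denom <- sum(log(tail_degs / (xmin - 0.5)))
  structure(list(alpha = 1 + length(tail_degs) / denom,
                 xmin = xmin, n_tail = length(tail_degs)),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f (xmin = %g, n_tail = %d)\n",
              x$alpha, x$xmin, x$n_tail))
  invisible(x)
}

#' Largest connected component of a gene set within a network
#'
#' Induces the subgraph on `genes` (symbols absent from the network are kept
#' as isolated vertices) and returns the node set of its largest connected
#' component. Ties are broken in favour of the component containing the
#' lexicographically smallest gene.
#'
#' @param network a [gene_network].
#' @param genes character vector of gene symbols.
#' @return character vector of genes in the largest component (sorted).
#' @export
largest_connected_component <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  genes <- sort(unique(normalize_symbols(genes)))
  if (length(genes) == 0L) return(character())
  ed <- network$edges
  keep <- ed$gene_a %in% genes & ed$gene_b %in% genes
  comp_id <- induced_components(genes, ed$gene_a[keep], ed$gene_b[keep])
  sizes <- tabulate(comp_id)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component holding the lexicographically smallest member wins;
    # genes are sorted, so the first gene of each tied component decides
    firsts <- vapply(best, function(cid) genes[which(comp_id == cid)[1L]], "")
    best <- best[order(firsts)][1L]
  }
  genes[comp_id == best]
}

# Union-find over a fixed sorted vertex vector; returns component ids.
induced_components <- function(vertices, from, to) {
  parent <- seq_along(vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fi <- match(from, vertices)
  ti <- match(to, vertices)
  for (e in seq_along(fi)) {
    a <- find(fi[e]); b <- find(ti[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(vertices), find, integer(1L))
  match(roots, unique(roots))
}
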