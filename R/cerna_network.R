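# Shared-miRNA competing-mRNA (ceRNA) network: hypergeometric overlap test
# on shared targeting miRNAs, network construction, centrality ranking,
# degree power-law check, and gene-set over-representation.

#' Construct a miRNA -> gene target map
#'
#' @param pairs data frame with columns `miRNA`, `gene` and optionally
#'   `energy` (predicted binding free energy, kcal/mol). Duplicate pairs are
#'   collapsed.
#' @return object of class `target_map`: `pairs`, `mirnas`, `genes`,
#'   `gene_sets` (miRNA set per gene), and `m` (number of distinct miRNAs).
#' @export
target_map <- function(pairs) {
  if (!all(c("miRNA", "gene") %in% names(pairs))) {
    stop_strokenet("target pairs need columns miRNA and gene",
                   class = "strokenet_parse")
  }
  pairs <- pairs[!duplicated(pairs[, c("miRNA", "gene")]), , drop = FALSE]
  rownames(pairs) <- NULL
  gene_sets <- split(pairs$miRNA, pairs$gene)
  structure(
    list(pairs = pairs,
         mirnas = sort(unique(pairs$miRNA)),
         genes = sort(unique(pairs$gene)),
         gene_sets = gene_sets,
         m = length(unique(pairs$miRNA))),
    class = "target_map"
  )
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", x$m, "miRNAs,", length(x$genes), "genes,",
      nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' Load a miRNA-target pair table with a binding-energy filter
#'
#' Reads a TSV of predicted miRNA -> mRNA interactions (columns `miRNA`,
#' `gene`, optional `energy` in kcal/mol) and drops pairs whose binding free
#' energy is above the cutoff (weaker than -20 kcal/mol by default),
#' mirroring the reliability filter applied to target predictions.
#'
#' @param path TSV path.
#' @param energy_cutoff maximum binding free energy retained (kcal/mol).
#' @return a [target_map()].
#' @export
load_target_map <- function(path, energy_cutoff = -20) {
  pairs <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  n0 <- nrow(pairs)
  if ("energy" %in% names(pairs)) {
    pairs <- pairs[is.na(pairs$energy) | pairs$energy <= energy_cutoff, ,
                   drop = FALSE]
    msg("energy filter (<= ", energy_cutoff, " kcal/mol): ",
        n0 - nrow(pairs), " of ", n0, " pairs dropped")
  } else {
    msg("no energy column; cutoff inapplicable, all ", n0, " pairs kept")
  }
  if (!nrow(pairs)) {
    stop_strokenet("no target pairs survive the energy filter (",
                   n0, " read, cutoff ", energy_cutoff, " kcal/mol)",
                   class = "strokenet_empty")
  }
  target_map(pairs)
}

# Upper-tail hypergeometric probability P(X >= r) for an overlap of r shared
# miRNAs between genes targeting t and n of m miRNAs, computed in log space
# with log-gamma binomial coefficients for stability at large m.
hyper_upper_tail <- function(r, t, n, m) {
  if (r <= 0) return(1)
  i <- r:min(t, n)
  terms <- lchoose_safe(t, i) + lchoose_safe(m - t, n - i) - lchoose_safe(m, n)
  min(1, exp(logsumexp(terms)))
}

#' Shared-miRNA competition test for one gene pair
#'
#' Tests whether two mRNAs share more targeting miRNAs than expected by
#' chance, using the upper-tail hypergeometric probability
#' `P = 1 - sum_{i=0}^{r-1} C(t,i) C(m-t, n-i) / C(m,n)`
#' where `m` is the number of miRNAs in the map, `t` and `n` the miRNA
#' counts of the two genes, and `r` the number shared. Symmetric in the two
#' genes; `r = 0` gives p = 1 exactly.
#'
#' @param geneA,geneB gene identifiers present in the map.
#' @param map a [target_map()].
#' @return one-row data frame of class `competing_pair`: `geneA`, `geneB`,
#'   `t`, `n`, `r`, `m`, `p_value`.
#' @export
competing_pair_test <- function(geneA, geneB, map) {
  for (gene in c(geneA, geneB)) {
    if (is.null(map$gene_sets[[gene]])) {
      stop_strokenet("gene absent from target map: ", gene,
                     class = "strokenet_key")
    }
  }
  sa <- map$gene_sets[[geneA]]
  sb <- map$gene_sets[[geneB]]
  r <- length(intersect(sa, sb))
  p <- hyper_upper_tail(r, length(sa), length(sb), map$m)
  structure(
    data.frame(geneA = geneA, geneB = geneB, t = length(sa), n = length(sb),
               r = r, m = map$m, p_value = p, stringsAsFactors = FALSE),
    class = c("competing_pair", "data.frame")
  )
}

#' Build the competing-mRNA network
#'
#' Candidate pairs are gene pairs sharing at least one miRNA (all other
#' pairs have r = 0 hence p = 1); when `seed_genes` is given only pairs
#' incident to a seed gene are tested, giving a seed-centric network. An
#' edge is kept iff its shared-miRNA p-value is below `alpha`.
#'
#' @param map a [target_map()].
#' @param seed_genes optional character vector of focal genes.
#' @param alpha edge significance threshold (default 0.05).
#' @return object of class `gene_network`: `edges` (geneA, geneB, t, n, r,
#'   m, p_value), `graph` (an igraph), `alpha`, and counts.
#' @export
build_network <- function(map, seed_genes = NULL, alpha = 0.05) {
  if (!nrow(map$pairs)) {
    stop_strokenet("empty target map", class = "strokenet_empty")
  }
  if (!is.null(seed_genes)) {
    missing_seeds <- setdiff(seed_genes, map$genes)
    if (length(missing_seeds)) {
      warning("seed gene(s) absent from target map: ",
              paste(missing_seeds, collapse = ", "), call. = FALSE)
      seed_genes <- intersect(seed_genes, map$genes)
    }
  }
  # candidate pairs via the miRNA-wise inverted index
  by_mirna <- split(map$pairs$gene, map$pairs$miRNA)
  pair_keys <- new.env(parent = emptyenv())
  for (genes in by_mirna) {
    genes <- sort(unique(genes))
    if (!is.null(seed_genes)) {
      seeds_here <- intersect(genes, seed_genes)
      if (!length(seeds_here)) next
      for (s in seeds_here) {
        for (gene in setdiff(genes, s)) {
          a <- min(s, gene); b <- max(s, gene)
          assign(paste0(a, "\r", b), TRUE, envir = pair_keys)
        }
      }
    } else if (length(genes) >= 2) {
      idx <- combn(genes, 2)
      for (j in seq_len(ncol(idx))) {
        assign(paste0(idx[1, j], "\r", idx[2, j]), TRUE, envir = pair_keys)
      }
    }
  }
  keys <- ls(pair_keys)
  rows <- lapply(keys, function(k) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1]]
    competing_pair_test(ab[1], ab[2], map)
  })
  tested <- if (length(rows)) do.call(rbind, rows) else
    data.frame(geneA = character(), geneB = character(), t = integer(),
               n = integer(), r = integer(), m = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  tested <- tested[order(tested$geneA, tested$geneB), , drop = FALSE]
  rownames(tested) <- NULL
  edges <- tested[tested$p_value < alpha, , drop = FALSE]
  graph <- igraph::graph_from_data_frame(
    edges[, c("geneA", "geneB")], directed = FALSE
  )
  msg("competing-mRNA network: ", nrow(tested), " candidate pairs tested, ",
      nrow(edges), " edges kept at alpha = ", alpha, " (",
      igraph::vcount(graph), " nodes)")
  structure(list(edges = edges, tested = tested, graph = graph,
                 alpha = alpha, n_nodes = igraph::vcount(graph),
                 n_edges = nrow(edges)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", x$n_nodes, "nodes,", x$n_edges,
      "edges (alpha =", x$alpha, ")\n")
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "gene_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop_strokenet("expected a gene_network or igraph",
                      class = "strokenet_invalid")
}

#' Node centralities and the top-k intersection
#'
#' Degree, shortest-path betweenness (normalized by (N-1)(N-2)/2 for an
#' undirected graph) and closeness. Closeness is computed within each
#' connected component and scaled by the component's reachable fraction
#' (Wasserman-Faust), so values are comparable on disconnected graphs;
#' singleton nodes get closeness 0. Each index gets a rank list (ties share
#' the minimum rank) and the genes in the top `k` of all three indices are
#' intersected; for the intersection a tied group only counts as top-k when
#' the whole group fits, so boundary ties cannot flood the head.
#'
#' @param net a `gene_network` or igraph.
#' @param top_k size of the per-index head for the intersection (default 5).
#' @return list with `table` (gene, degree, betweenness, closeness and the
#'   three ranks) and `top_intersection`.
#' @export
centralities <- function(net, top_k = 5) {
  gr <- as_igraph(net)
  if (!igraph::vcount(gr)) {
    stop_strokenet("empty network", class = "strokenet_empty")
  }
  N <- igraph::vcount(gr)
  deg <- igraph::degree(gr)
  btw <- if (N > 2) igraph::betweenness(gr, normalized = TRUE)
         else setNames(rep(0, N), igraph::V(gr)$name)
  comp <- igraph::components(gr)
  dmat <- igraph::distances(gr)
  clo <- vapply(seq_len(N), function(v) {
    members <- which(comp$membership == comp$membership[v])
    nc <- length(members)
    if (nc < 2) return(0)
    dsum <- sum(dmat[v, members])
    ((nc - 1) / dsum) * ((nc - 1) / (N - 1))
  }, numeric(1))
  names(clo) <- igraph::V(gr)$name
  rk <- function(x) rank(-x, ties.method = "min")
  tab <- data.frame(
    gene = igraph::V(gr)$name,
    degree = as.integer(deg), betweenness = as.numeric(btw),
    closeness = clo,
    degree_rank = rk(deg), betweenness_rank = rk(btw),
    closeness_rank = rk(clo),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # a tied group enters the top k only if it fits entirely (max-tie rank),
  # so a large tie at the boundary cannot flood the head of the list
  top <- function(x) tab$gene[rank(-x, ties.method = "max") <= top_k]
  inter <- Reduce(intersect, list(top(tab$degree), top(tab$betweenness),
                                  top(tab$closeness)))
  list(table = tab[order(tab$degree_rank), , drop = FALSE],
       top_intersection = inter)
}

#' Power-law check on the degree distribution
#'
#' Least-squares line on (log10 degree, log10 frequency) over the positive
#' degrees with nonzero frequency, as a scale-free-ness diagnostic.
#'
#' @param net a `gene_network` or igraph.
#' @return list with `slope`, `r_squared` and the fitted points.
#' @export
powerlaw_fit <- function(net) {
  gr <- as_igraph(net)
  deg <- igraph::degree(gr)
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(k) < 3) {
    stop_strokenet("need >= 3 distinct positive degrees for a power-law fit",
                   class = "strokenet_degenerate")
  }
  fit <- lm(log10(freq) ~ log10(k))
  y <- log10(freq)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]),
       r_squared = r2,
       points = data.frame(degree = k, frequency = freq))
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (term, description, genes... per tab-separated line).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, character(1), 1))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list hits more of the set than
#' expected given the universe: upper-tail hypergeometric p for `k` hits out
#' of a query of size `n`, against a set of size `K` in a universe of size
#' `N`. Gene sets are intersected with the universe first.
#'
#' @param query_genes character vector (must be a subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene list.
#' @param alpha significance threshold for the `significant` flag.
#' @param adjust optional p-adjustment method (`"BH"` adds `p_adjusted`).
#' @return data frame sorted by p: term, k, K, n, N, p_value, significant.
#' @export
ora <- function(query_genes, gene_sets, universe, alpha = 0.05,
                adjust = "none") {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  if (!length(query_genes)) {
    stop_strokenet("empty query gene list", class = "strokenet_empty")
  }
  extra <- setdiff(query_genes, universe)
  if (length(extra)) {
    stop_strokenet("query genes outside the universe: ",
                   paste(head(extra, 3), collapse = ", "),
                   class = "strokenet_invalid")
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    k <- length(intersect(query_genes, set))
    p <- if (K == 0) 1 else
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$significant <- out$p_value < alpha
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  rownames(out) <- NULL
  out
}

#' Export a network for external viewers
#'
#' @param net a `gene_network`.
#' @param path output path; format from extension (`.graphml` or `.gml`).
#' @export
write_network <- function(net, path) {
  fmt <- if (grepl("\\.gml$", path)) "gml" else "graphml"
  igraph::write_graph(as_igraph(net), path, format = fmt)
  invisible(path)
}
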