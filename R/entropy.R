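# Entropy-based interaction graph for MDR: per-SNP information gain and
# pairwise synergy/redundancy, as percentages of the class entropy.

entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

cond_entropy_bits <- function(keys, case) {
  # H(C | A) = sum_a p(a) H(C | A = a)
  tab <- table(keys, case)
  w <- rowSums(tab) / sum(tab)
  sum(w * apply(tab, 1, entropy_bits))
}

mutual_info_bits <- function(keys, case) {
  entropy_bits(table(case)) - cond_entropy_bits(keys, case)
}

#' Entropy-based SNP interaction graph
#'
#' Computes the class entropy H(C) in bits, each SNP's information gain
#' IG(A;C) = H(C) - H(C|A), and for each SNP pair the interaction gain
#' IG(A,B;C) = I(A,B;C) - I(A;C) - I(B;C), where positive values indicate
#' synergy and negative values redundancy. All quantities are reported in
#' bits and as percentages of H(C). Subjects with missing genotypes are
#' excluded per node/pair. With >= 3 attributes an interaction dendrogram is
#' built by average-linkage clustering on the reciprocal-transformed synergy
#' distance d = 1 / (synergy - min(synergy) + eps), so strongly synergistic
#' pairs join first.
#'
#' @inheritParams mdr_fit
#' @param eps positive offset in the dendrogram distance transform.
#' @return object of class `entropy_graph`: `class_entropy_bits`, `nodes`
#'   (snp, ig_bits, ig_pct), `edges` (snp_a, snp_b, synergy_bits,
#'   synergy_pct), and (when >= 3 nodes) `dendrogram` (an `hclust`) and
#'   `newick`.
#' @export
entropy_graph <- function(g, status, attributes, eps = 1e-6) {
  if (!length(attributes)) {
    stop_strokenet("need at least one attribute", class = "strokenet_invalid")
  }
  case <- as_case_indicator(status)
  if (length(unique(case)) < 2) {
    stop_strokenet("class entropy is zero (single class)",
                   class = "strokenet_degenerate")
  }
  hC <- entropy_bits(table(case))
  d <- g$dosages[, attributes, drop = FALSE]

  ig <- vapply(attributes, function(s) {
    keep <- !is.na(d[, s])
    mutual_info_bits(d[keep, s], case[keep])
  }, numeric(1))
  nodes <- data.frame(snp = attributes, ig_bits = ig,
                      ig_pct = 100 * ig / hC,
                      row.names = NULL, stringsAsFactors = FALSE)

  edges <- NULL
  if (length(attributes) >= 2) {
    pairs <- combn(attributes, 2, simplify = FALSE)
    edges <- do.call(rbind, lapply(pairs, function(p) {
      keep <- stats::complete.cases(d[, p, drop = FALSE])
      ca <- case[keep]
      ia <- mutual_info_bits(d[keep, p[1]], ca)
      ib <- mutual_info_bits(d[keep, p[2]], ca)
      iab <- mutual_info_bits(cell_keys(d[keep, p, drop = FALSE]), ca)
      syn <- iab - ia - ib
      data.frame(snp_a = p[1], snp_b = p[2], synergy_bits = syn,
                 synergy_pct = 100 * syn / hC, stringsAsFactors = FALSE)
    }))
  }

  dendro <- NULL; newick <- NULL
  if (length(attributes) >= 3) {
    syn_mat <- matrix(0, length(attributes), length(attributes),
                      dimnames = list(attributes, attributes))
    for (i in seq_len(nrow(edges))) {
      syn_mat[edges$snp_a[i], edges$snp_b[i]] <- edges$synergy_bits[i]
      syn_mat[edges$snp_b[i], edges$snp_a[i]] <- edges$synergy_bits[i]
    }
    dist_mat <- 1 / (syn_mat - min(edges$synergy_bits) + eps)
    diag(dist_mat) <- 0
    dendro <- hclust(as.dist(dist_mat), method = "average")
    newick <- ape::write.tree(ape::as.phylo(dendro))
  }

  structure(list(class_entropy_bits = hC, nodes = nodes, edges = edges,
                 dendrogram = dendro, newick = newick),
            class = "entropy_graph")
}

#' @export
print.entropy_graph <- function(x, ...) {
  cat(sprintf("entropy graph: H(C) = %.4f bits\n", x$class_entropy_bits))
  for (i in seq_len(nrow(x$nodes))) {
    cat(sprintf("  %-12s IG = %.4f bits (%.2f%%)\n", x$nodes$snp[i],
                x$nodes$ig_bits[i], x$nodes$ig_pct[i]))
  }
  if (!is.null(x$edges)) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -- %s: %+.4f bits (%+.2f%%)\n",
                  x$edges$snp_a[i], x$edges$snp_b[i],
                  x$edges$synergy_bits[i], x$edges$synergy_pct[i]))
    }
  }
  invisible(x)
}
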