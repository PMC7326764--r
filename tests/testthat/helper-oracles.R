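# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph) so they can certify them.

options(strokenet.verbose = FALSE)

toy_genotypes <- function(dosages, snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("rs", seq_len(ncol(dosages)))
  genotype_matrix(dosages, paste0("S", seq_len(nrow(dosages))), snp_ids)
}

# --- MDR labeling + pooled OR by direct enumeration -------------------------
oracle_mdr <- function(dosages, case) {
  dosages <- as.matrix(dosages)
  keep <- rowSums(is.na(dosages)) == 0
  dosages <- dosages[keep, , drop = FALSE]
  case <- case[keep]
  key <- apply(dosages, 1, paste, collapse = "|")
  thr <- sum(case) / sum(case == 0)
  cells <- unique(key)
  lab <- character(length(cells))
  ch <- cl <- 0; oh <- ol <- 0
  for (i in seq_along(cells)) {
    idx <- key == cells[i]
    nca <- sum(case[idx] == 1); nco <- sum(case[idx] == 0)
    ratio <- if (nco == 0) Inf else nca / nco
    lab[i] <- if (ratio >= thr) "high" else "low"
    if (lab[i] == "high") { ch <- ch + nca; oh <- oh + nco }
    else { cl <- cl + nca; ol <- ol + nco }
  }
  names(lab) <- cells
  or <- if (ch * ol == 0 || cl * oh == 0) {
    if ((ch + oh == 0) || (cl + ol == 0)) NA_real_
    else ((ch + .5) * (ol + .5)) / ((cl + .5) * (oh + .5))
  } else (ch * ol) / (cl * oh)
  degenerate <- all(lab == "high") || all(lab == "low")
  list(labels = lab, pooled = c(case_high = ch, control_high = oh,
                                case_low = cl, control_low = ol),
       odds_ratio = if (degenerate) NA_real_ else or,
       degenerate = degenerate)
}

# --- centralities by Floyd-Warshall + shortest-path counting ----------------
# edges: 2-column matrix of node indices (1..n), undirected, simple
oracle_centralities <- function(n, edges) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  adj <- matrix(FALSE, n, n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    d[i, j] <- d[j, i] <- 1
    adj[i, j] <- adj[j, i] <- TRUE
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  # sigma[s, t]: number of shortest s-t paths
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  ord <- order(as.vector(d))
  for (idx in ord) {
    s <- (idx - 1) %% n + 1; t <- (idx - 1) %/% n + 1
    if (s == t || !is.finite(d[s, t])) next
    if (d[s, t] == 1) { sigma[s, t] <- 1; next }
    preds <- which(adj[, t] & d[s, ] == d[s, t] - 1)
    sigma[s, t] <- sum(sigma[s, preds])
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t]) || sigma[s, t] == 0) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    btw[v] <- tot / ((n - 1) * (n - 2) / 2)
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    nc <- length(reach) + 1
    clo[v] <- if (nc < 2) 0 else
      ((nc - 1) / sum(d[v, reach])) * ((nc - 1) / (n - 1))
  }
  degree <- rowSums(adj)
  list(degree = degree, betweenness = btw, closeness = clo)
}

random_graph_edges <- function(n, p) {
  pairs <- t(combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# --- mutual information by direct summation ---------------------------------
oracle_mi_bits <- function(a, c) {
  tab <- table(a, c)
  p <- tab / sum(tab)
  pa <- rowSums(p); pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pa[i] * pc[j]))
  }
  unname(as.numeric(s))
}
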