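tiny_map <- function() {
  target_map(data.frame(
    miRNA = c("m1", "m2", "m3", "m1", "m2", "m4", "m5"),
    gene = c("A", "A", "A", "B", "B", "B", "C"),
    stringsAsFactors = FALSE
  ))
}

test_that("target map loading filters on binding energy and deduplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tgene\tenergy",
               "m1\tA\t-25", "m2\tA\t-21", "m3\tB\t-15",
               "m1\tB\t-30", "m1\tB\t-30"), path)
  map <- load_target_map(path)
  expect_equal(nrow(map$pairs), 3L)   # -15 dropped, duplicate collapsed
  expect_true(all(map$pairs$energy <= -20))

  # without an energy column everything is kept
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tgene", "m1\tA", "m2\tB"), path2)
  expect_equal(nrow(load_target_map(path2)$pairs), 2L)

  # nothing survives -> fatal
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("miRNA\tgene\tenergy", "m1\tA\t-5"), path3)
  expect_error(load_target_map(path3), class = "strokenet_empty")
})

test_that("shared-miRNA test matches enumeration and its edge cases", {
  map <- tiny_map()
  # A(t=3: m1,m2,m3) vs B(n=3: m1,m2,m4), m=5, r=2
  r <- competing_pair_test("A", "B", map)
  expect_equal(r$r, 2L)
  expect_equal(r$p_value, phyper(1, 3, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetric
  expect_equal(competing_pair_test("B", "A", map)$p_value, r$p_value)
  # r = 0 gives exactly 1
  expect_identical(competing_pair_test("A", "C", map)$p_value, 1)
  expect_error(competing_pair_test("A", "ZZ", map),
               class = "strokenet_key")

  # m=10, t=4, n=5, r=3 -> 66/252 by direct enumeration
  expect_equal(strokenet:::hyper_upper_tail(3, 4, 5, 10), 66 / 252,
               tolerance = 1e-12)
  # sharing forced when one gene targets every miRNA
  expect_equal(strokenet:::hyper_upper_tail(3, 10, 3, 10), 1,
               tolerance = 1e-12)
})

test_that("log-space tail equals phyper across a random grid", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(5:400, 1)
    t <- sample(1:m, 1)
    n <- sample(1:m, 1)
    r <- sample(0:min(t, n), 1)
    expect_equal(strokenet:::hyper_upper_tail(r, t, n, m),
                 phyper(r - 1, t, m - t, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("edge p-values are super-uniform under a random bipartite null", {
  set.seed(7)
  m <- 100
  mirnas <- paste0("m", 1:m)
  pvals <- replicate(2000, {
    sa <- sample(mirnas, 8)
    sb <- sample(mirnas, 10)
    r <- length(intersect(sa, sb))
    strokenet:::hyper_upper_tail(r, 8, 10, m)
  })
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("network construction honors candidates, seeds and row order", {
  # no two genes share a miRNA -> empty edge set
  map0 <- target_map(data.frame(miRNA = c("m1", "m2"), gene = c("A", "B")))
  expect_equal(build_network(map0)$n_edges, 0L)

  map <- simulate_target_map(m = 100, n_genes = 80, targets_per_gene = 4,
                             modules = list(list(genes = 5, shared = 10)),
                             seed = 3)
  net <- build_network(map)
  # row-order invariance
  shuffled <- target_map(map$pairs[sample(nrow(map$pairs)), ])
  net2 <- build_network(shuffled)
  expect_equal(net$edges, net2$edges)

  # seed restriction: every edge touches the seed gene
  seed_gene <- net$edges$geneA[1]
  net3 <- build_network(map, seed_genes = seed_gene)
  expect_true(all(net3$edges$geneA == seed_gene |
                    net3$edges$geneB == seed_gene))
})

test_that("planted competing modules are recovered", {
  hits <- vapply(1:20, function(s) {
    map <- simulate_target_map(
      m = 100, n_genes = 205, targets_per_gene = 5,
      modules = list(list(genes = paste0("gene", 1:5), shared = 10)),
      seed = 300 + s
    )
    net <- build_network(map, alpha = 0.05)
    want <- t(combn(paste0("gene", 1:5), 2))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    all(key(want[, 1], want[, 2]) %in% key(net$edges$geneA, net$edges$geneB))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("centralities match closed forms on P3, K5 and a star", {
  p3 <- igraph::make_graph(~ A - B, B - C)
  cp <- centralities(p3)$table
  b <- cp[cp$gene == "B", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  ck <- centralities(k5)$table
  expect_true(all(ck$betweenness == 0))
  expect_true(all(abs(ck$closeness - 1) < 1e-12))

  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:6))
  cs <- centralities(star)
  expect_equal(cs$table$gene[1], "hub")
  expect_equal(cs$top_intersection, "hub")
})

test_that("centralities agree with a brute-force shortest-path oracle", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(8:30, 1)
    edges <- random_graph_edges(n, 0.15)
    if (nrow(edges) < 2) next
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
    igraph::V(gr)$name <- paste0("v", seq_len(igraph::vcount(gr)))
    got <- centralities(gr)$table
    got <- got[order(as.integer(sub("v", "", got$gene))), ]
    want <- oracle_centralities(igraph::vcount(gr), edges)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
  }
})

test_that("power-law fit recovers an exact line and flags degenerate input", {
  # realize a graph whose degree histogram lies exactly on slope -2:
  # degrees (1, 2, 4) with frequencies (16, 4, 1)
  gr <- igraph::realize_degseq(c(rep(1, 16), rep(2, 4), 4))
  igraph::V(gr)$name <- paste0("d", 1:21)
  pl0 <- powerlaw_fit(gr)
  expect_equal(pl0$slope, -2, tolerance = 1e-10)
  expect_equal(pl0$r_squared, 1, tolerance = 1e-10)

  # regular graph -> undefined fit
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  expect_error(powerlaw_fit(ring), class = "strokenet_degenerate")

  # preferential-attachment graph sits in the scale-free regime
  set.seed(99)
  ba <- igraph::sample_pa(5000, m = 2, directed = FALSE)
  igraph::V(ba)$name <- paste0("n", 1:5000)
  pl <- powerlaw_fit(ba)
  expect_gte(pl$slope, -3.5)
  expect_lte(pl$slope, -1.5)
  expect_gt(pl$r_squared, 0.7)
})

test_that("over-representation matches enumeration and orderings", {
  universe <- paste0("g", 1:20)
  sets <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 15:20))
  # N=20, K=5, n=5, k=4 -> p = 76/15504
  r <- ora(c("g1", "g2", "g3", "g4", "g19"), sets, universe)
  expect_equal(r$p_value[r$term == "T1"], 76 / 15504, tolerance = 1e-12)

  # disjoint query -> all p = 1
  r2 <- ora(paste0("g", 6:10), list(T1 = paste0("g", 1:5)), universe)
  expect_equal(r2$p_value, 1)

  # query identical to one term ranks it first
  universe2 <- paste0("h", 1:100)
  sets2 <- list(hit = paste0("h", 1:5), other = paste0("h", 50:60))
  r3 <- ora(paste0("h", 1:5), sets2, universe2)
  expect_equal(r3$term[1], "hit")
  expect_true(r3$significant[1])

  expect_error(ora(character(0), sets, universe), class = "strokenet_empty")
  expect_error(ora("zzz", sets, universe), class = "strokenet_invalid")
})

test_that("GMT files round-trip through read_gmt", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2\tg3", "T2\tdesc\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_equal(sort(names(sets)), c("T1", "T2"))
  expect_setequal(sets$T1, c("g1", "g2", "g3"))
})
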