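test_that("single-SNP labeling and pooled OR match hand enumeration", {
  # cells (10 case/2 ctrl, 5/5, 2/10); 17 cases, 17 controls; T = 1
  dos <- matrix(rep(0:2, c(12, 10, 12)), ncol = 1)
  case <- c(rep(1, 10), rep(0, 2), rep(1, 5), rep(0, 5),
            rep(1, 2), rep(0, 10))
  fit <- mdr_fit(toy_genotypes(dos), case, "rs1")
  labels <- setNames(fit$cells$label, fit$cells$cell)
  expect_equal(labels[["0"]], "high")
  expect_equal(labels[["1"]], "high")   # ratio 1 == T: tie -> high
  expect_equal(labels[["2"]], "low")
  expect_equal(fit$odds_ratio, 150 / 14, tolerance = 1e-12)
  expect_false(fit$degenerate)
  expect_true(fit$ci[1] < fit$odds_ratio && fit$odds_ratio < fit$ci[2])
})

test_that("all-tie labeling flags a degenerate pooled table", {
  dos <- matrix(rep(0:1, each = 10), ncol = 1)
  case <- rep(c(1, 0), 10)   # every cell ratio = 1 = T -> all high
  fit <- mdr_fit(toy_genotypes(dos), case, "rs1")
  expect_true(all(fit$cells$label == "high"))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$odds_ratio))
  expect_error(mdr_fit(toy_genotypes(dos), case, character(0)),
               class = "strokenet_invalid")
})

test_that("labeling and OR equal brute-force enumeration on random data", {
  for (s in 1:200) {
    set.seed(s)
    k <- sample(1:3, 1)
    n <- sample(20:60, 1)
    dos <- matrix(sample(0:2, n * k, replace = TRUE), ncol = k)
    case <- rbinom(n, 1, 0.5)
    if (sum(case) == 0 || sum(case) == n) next
    fit <- mdr_fit(toy_genotypes(dos), case, paste0("rs", 1:k))
    orc <- oracle_mdr(dos, case)
    expect_equal(setNames(fit$cells$label, fit$cells$cell),
                 orc$labels[fit$cells$cell])
    expect_equal(fit$degenerate, orc$degenerate)
    if (!fit$degenerate && !fit$haldane_corrected) {
      expect_equal(fit$odds_ratio, orc$odds_ratio, tolerance = 1e-12)
    }
    expect_gte(fit$training_accuracy, 0.5)
  }
})

test_that("pooled OR is invariant to subject and column permutations", {
  set.seed(33)
  dos <- matrix(sample(0:2, 200, replace = TRUE), ncol = 2)
  case <- rbinom(100, 1, 0.5)
  g <- toy_genotypes(dos)
  f1 <- mdr_fit(g, case, c("rs1", "rs2"))
  perm <- sample(100)
  f2 <- mdr_fit(toy_genotypes(dos[perm, ]), case[perm], c("rs1", "rs2"))
  f3 <- mdr_fit(g, case, c("rs2", "rs1"))
  expect_equal(f1$odds_ratio, f2$odds_ratio, tolerance = 1e-12)
  expect_equal(f1$odds_ratio, f3$odds_ratio, tolerance = 1e-12)
})

test_that("cross-validation is deterministic and calibrated", {
  # perfect separator: recessive genotype == case
  set.seed(5)
  dos <- matrix(sample(0:2, 200, replace = TRUE), ncol = 1)
  case <- as.integer(dos[, 1] == 2)
  g <- toy_genotypes(dos)
  cv <- mdr_cross_validate(g, case, "rs1", n_folds = 10, seed = 3)
  expect_equal(cv$fold_accuracy, rep(1, 10))

  cv2 <- mdr_cross_validate(g, case, "rs1", n_folds = 10, seed = 3)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$fold_accuracy, cv2$fold_accuracy)

  # permuted labels: mean testing accuracy hovers at chance
  null_acc <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    dosn <- matrix(sample(0:2, 1000, replace = TRUE, prob = c(.25, .5, .25)),
                   ncol = 1)
    mdr_cross_validate(toy_genotypes(dosn), sample(rep(0:1, 500)),
                       "rs1", n_folds = 10, seed = s)$testing_accuracy
  }, numeric(1))
  expect_gte(mean(null_acc), 0.45)
  expect_lte(mean(null_acc), 0.55)
})

test_that("search enumerates all subsets and respects its cap", {
  set.seed(9)
  ep <- simulate_epistasis(
    200, xor_penetrance(0.8, 0.2), c(rsA = 0.5, rsB = 0.5),
    setNames(rep(0.3, 12), paste0("null", 1:12)), seed = 2
  )
  s <- mdr_search(ep$genotypes, ep$status, k_min = 2, k_max = 2,
                  n_folds = 5, seed = 1)
  expect_equal(nrow(s$models), choose(14, 2))   # 91 subsets at k = 2
  expect_true(all(s$models$cvc <= 5))
  expect_error(
    mdr_search(ep$genotypes, ep$status, k_min = 2, k_max = 2,
               n_folds = 5, seed = 1, max_subsets = 10),
    class = "strokenet_invalid"
  )
})

test_that("permutation test obeys its formula, floor and precondition", {
  set.seed(17)
  dos <- matrix(sample(0:2, 240, replace = TRUE), ncol = 2)
  case <- as.integer(dos[, 1] >= 1)   # strong signal
  g <- toy_genotypes(dos)
  s <- mdr_search(g, case, k_min = 1, k_max = 1, n_folds = 5, seed = 2)
  p <- mdr_permutation_test(g, case, s, n_perm = 99, seed = 4)
  expect_equal(p$p_value, 0.01)   # observed beats every permutation
  expect_error(mdr_permutation_test(g, case, s, n_perm = 10, seed = 4),
               class = "strokenet_invalid")
})

test_that("permutation p-values are roughly uniform under the null", {
  pvals <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    dos <- matrix(sample(0:2, 100, replace = TRUE), ncol = 1)
    case <- rbinom(100, 1, 0.5)
    g <- toy_genotypes(dos)
    srch <- mdr_search(g, case, k_min = 1, k_max = 1, n_folds = 5, seed = s)
    mdr_permutation_test(g, case, srch, n_perm = 19, seed = s)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("entropy graph matches hand-computed information gains", {
  # balanced 8/8 class; SNP cells (4 case/0 ctrl, 0/4, 4/4)
  dos <- matrix(rep(0:2, c(4, 4, 8)), ncol = 1)
  case <- c(rep(1, 4), rep(0, 4), rep(1, 4), rep(0, 4))
  eg <- entropy_graph(toy_genotypes(dos), case, "rs1")
  expect_equal(eg$class_entropy_bits, 1, tolerance = 1e-12)
  expect_equal(eg$nodes$ig_bits, 0.5, tolerance = 1e-12)
  expect_equal(eg$nodes$ig_pct, 50, tolerance = 1e-10)

  # proportional counts -> exactly zero information gain
  dos2 <- matrix(rep(0:1, c(10, 20)), ncol = 1)
  case2 <- c(rep(c(1, 0), 5), rep(c(1, 0), 10))
  eg2 <- entropy_graph(toy_genotypes(dos2), case2, "rs1")
  expect_equal(eg2$nodes$ig_bits, 0, tolerance = 1e-12)

  # duplicated SNP columns: pure redundancy, negative pairwise gain
  set.seed(12)
  x <- sample(0:2, 200, replace = TRUE)
  case3 <- rbinom(200, 1, plogis(x - 1))
  eg3 <- entropy_graph(toy_genotypes(cbind(x, x)), case3, c("rs1", "rs2"))
  expect_lt(eg3$edges$synergy_bits, 0)

  expect_error(entropy_graph(toy_genotypes(matrix(0:2, 3)), c(1, 1, 1),
                             "rs1"),
               class = "strokenet_degenerate")
})

test_that("decomposition-based information gain equals direct MI summation", {
  for (s in 1:25) {
    set.seed(s)
    dos <- matrix(sample(0:2, 80, replace = TRUE), ncol = 1)
    case <- rbinom(80, 1, 0.4)
    if (length(unique(case)) < 2) next
    eg <- entropy_graph(toy_genotypes(dos), case, "rs1")
    expect_equal(eg$nodes$ig_bits, oracle_mi_bits(dos[, 1], case),
                 tolerance = 1e-12)
  }
})

test_that("XOR design yields flat margins and positive pairwise synergy", {
  ep <- simulate_epistasis(3000, xor_penetrance(0.7, 0.3),
                           c(rsA = 0.5, rsB = 0.5),
                           c(null1 = 0.3), seed = 6)
  eg <- entropy_graph(ep$genotypes, ep$status, c("rsA", "rsB", "null1"))
  expect_lt(max(eg$nodes$ig_pct[1:2]), 1)   # ~0% marginal information
  syn <- eg$edges$synergy_bits[eg$edges$snp_a == "rsA" &
                                 eg$edges$snp_b == "rsB"]
  expect_gt(syn, 0)
  expect_s3_class(eg$dendrogram, "hclust")
  expect_match(eg$newick, "rsA")
})
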