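test_that("HWE chi-squared matches hand-computed cases", {
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p_value, 1)

  # hand enumeration: expected (25, 50, 25); chi2 = 0.64 + 1.28 + 0.64
  r <- hwe_test(21, 58, 21)
  expect_equal(r$chi2, 2.56, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(2.56, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p_value, 0.1096, tolerance = 1e-3)
  expect_equal(sum(r$expected), sum(r$observed))

  expect_error(hwe_test(-1, 5, 5), class = "strokenet_invalid")
  mono <- hwe_test(10, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(mono$p_value, 1)
})

test_that("HWE p-values are uniform under exact HWE simulation", {
  n <- 1010
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    set.seed(i)
    maf <- runif(1, 0.1, 0.5)
    counts <- as.vector(stats::rmultinom(
      1, n, c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)))
    hwe_test(counts[1], counts[2], counts[3])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("association scan picks the right test and p-values", {
  g <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), ncol = 1))
  coded <- recode(g, "rs1", "dominant")
  y <- c(1, 2, 10, 11)
  r <- assoc_scan(coded, y, "HDL")
  expect_equal(r$test, "point_biserial")
  # closed-form Pearson r and t-transform oracle
  r_exp <- cor(c(0, 0, 1, 1), y)
  t_exp <- r_exp * sqrt(2 / (1 - r_exp^2))
  expect_equal(r$statistic, r_exp, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * stats::pt(abs(t_exp), 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(r$statistic, 0.99)
  expect_lt(r$p_value, 0.05)

  expect_error(assoc_scan(coded, c(5, 5, 5, 5)),
               class = "strokenet_degenerate")
})

test_that("genotypic coding uses ANOVA and equals linear regression", {
  set.seed(7)
  g <- toy_genotypes(matrix(sample(0:2, 120, replace = TRUE), ncol = 1))
  y <- rnorm(120) + 0.3 * g$dosages[, 1]
  r <- assoc_scan(recode(g, "rs1", "genotypic"), y, "TG")
  expect_equal(r$test, "anova_F")
  lm_p <- anova(lm(y ~ factor(g$dosages[, 1])))[["Pr(>F)"]][1]
  expect_equal(r$p_value, lm_p, tolerance = 1e-12)
})

test_that("association p is invariant to affine factor transforms", {
  set.seed(11)
  g <- toy_genotypes(matrix(sample(0:2, 80, replace = TRUE), ncol = 1))
  y <- rnorm(80, 130, 15)
  for (coding in c("dominant", "genotypic")) {
    coded <- recode(g, "rs1", coding)
    p1 <- assoc_scan(coded, y)$p_value
    p2 <- assoc_scan(coded, 3.7 * y - 20)$p_value
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("binary factors route to the chi-squared test", {
  set.seed(3)
  g <- toy_genotypes(matrix(sample(0:2, 200, replace = TRUE), ncol = 1))
  smoke <- rbinom(200, 1, 0.4)
  r <- assoc_scan(recode(g, "rs1", "dominant"), smoke, "smoking")
  expect_equal(r$test, "pearson_chi2")
  expect_true(r$p_value >= 0 && r$p_value <= 1)
})

test_that("subtype contrast reproduces hand-computed 2x2 chi-squared", {
  # independence: identical rows
  coded <- structure(list(snp_id = "rs1", coding = "dominant",
                          values = rep(c(0, 1), each = 20)),
                     class = "coded_genotype")
  labels <- rep(c("lacunar", "none"), 20)
  r0 <- subtype_scan(coded, labels, "lacunar")
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # [[20,5],[5,20]]: uncorrected Pearson chi2 = 50*(400-25)^2/25^4... by hand:
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 50 * 375^2 / 25^4 = 18
  coded2 <- structure(list(snp_id = "rs1", coding = "dominant",
                           values = rep(c(0, 1), each = 25)),
                      class = "coded_genotype")
  labels2 <- c(rep(c("lacunar", "none"), c(20, 5)),
               rep(c("lacunar", "none"), c(5, 20)))
  r1 <- subtype_scan(coded2, labels2, "lacunar")
  expect_equal(r1$statistic, 18, tolerance = 1e-12)
  expect_equal(r1$p_value, pchisq(18, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r1$p_value, 2.1e-5, tolerance = 0.05)

  # perfect association in a toy set
  coded3 <- structure(list(snp_id = "rs1", coding = "recessive",
                           values = rep(c(1, 0), c(15, 15))),
                      class = "coded_genotype")
  labels3 <- rep(c("lacunar", "none"), c(15, 15))
  expect_lt(subtype_scan(coded3, labels3, "lacunar")$p_value, 0.01)

  # zero margin
  expect_error(subtype_scan(coded3, rep("none", 30), "lacunar"),
               class = "strokenet_degenerate")
})

test_that("subtype chi-squared agrees with a permutation null", {
  set.seed(19)
  x <- rbinom(400, 1, 0.5)
  labels <- ifelse(rbinom(400, 1, 0.3 + 0.15 * x) == 1, "lacunar", "none")
  coded <- structure(list(snp_id = "rs1", coding = "dominant", values = x),
                     class = "coded_genotype")
  obs <- subtype_scan(coded, labels, "lacunar")
  perm <- replicate(2000, {
    subtype_scan(coded, sample(labels), "lacunar")$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(p_perm - obs$p_value), 0.05)
})

test_that("hwe_scan and assoc_scan_all cover the cohort", {
  co <- simulate_cohort(n_case = 40, n_control = 40, seed = 8)
  hwe <- hwe_scan(co$genotypes)
  expect_equal(nrow(hwe), length(co$genotypes$snp_ids))
  expect_true(all(hwe$p_value >= 0 & hwe$p_value <= 1))
  scan <- assoc_scan_all(co$genotypes, co$phenotypes,
                         codings = "dominant", adjust = "BH")
  expect_true(all(c("snp_id", "factor", "p_value", "p_adjusted") %in%
                    names(scan)))
  expect_true(all(scan$p_adjusted >= scan$p_value))
})
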