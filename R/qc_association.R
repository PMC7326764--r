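# Hardy-Weinberg QC and SNP-versus-risk-factor / subtype association scans.

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Pearson chi-squared goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectation (p^2, 2pq, q^2) at the estimated
#' allele frequency, on 1 degree of freedom.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts (major homozygote,
#'   heterozygote, minor homozygote).
#' @param snp_id optional label carried into the result.
#' @return an object of class `hwe_result`: observed and expected counts,
#'   estimated major-allele frequency `p_hat`, `chi2`, `df`, `p_value`, and a
#'   `monomorphic` flag (monomorphic SNPs get chi2 = 0, p = 1).
#' @examples
#' hwe_test(25, 50, 25)   # exact HWE proportions: chi2 = 0, p = 1
#' hwe_test(21, 58, 21)   # chi2 = 2.56
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, snp_id = NA_character_) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_strokenet("genotype counts must be non-negative integers",
                   class = "strokenet_invalid")
  }
  n <- sum(counts)
  if (n <= 0) {
    stop_strokenet("total genotype count must be positive",
                   class = "strokenet_invalid")
  }
  p_hat <- (2 * n_AA + n_Aa) / (2 * n)
  q_hat <- 1 - p_hat
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  monomorphic <- p_hat %in% c(0, 1)
  if (monomorphic) {
    chi2 <- 0
    p_value <- 1
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
    p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(snp_id = snp_id, observed = counts, expected = expected,
         p_hat = p_hat, chi2 = chi2, df = 1L, p_value = p_value,
         monomorphic = monomorphic),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE test%s: counts (%d, %d, %d), chi2 = %.4f, p = %.4g%s\n",
              if (is.na(x$snp_id)) "" else paste0(" [", x$snp_id, "]"),
              x$observed[1], x$observed[2], x$observed[3],
              x$chi2, x$p_value,
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' Hardy-Weinberg scan over all SNPs of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param subset optional logical/integer subject subset (e.g. controls only).
#' @return data frame with one row per SNP: counts, `p_hat`, `chi2`,
#'   `p_value`, `monomorphic`.
#' @export
hwe_scan <- function(g, subset = NULL) {
  d <- g$dosages
  if (!is.null(subset)) d <- d[subset, , drop = FALSE]
  rows <- lapply(g$snp_ids, function(s) {
    x <- d[, s]
    x <- x[!is.na(x)]
    r <- hwe_test(sum(x == 0L), sum(x == 1L), sum(x == 2L), snp_id = s)
    data.frame(snp_id = s, n_AA = r$observed[1], n_Aa = r$observed[2],
               n_aa = r$observed[3], p_hat = r$p_hat, chi2 = r$chi2,
               p_value = r$p_value, monomorphic = r$monomorphic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

assoc_result <- function(snp_id, coding, factor_name, test, statistic,
                         p_value, n) {
  structure(
    data.frame(snp_id = snp_id, coding = coding, factor = factor_name,
               test = test, statistic = statistic, p_value = p_value,
               n = n, stringsAsFactors = FALSE),
    class = c("assoc_result", "data.frame")
  )
}

#' Association scan between a coded genotype and one risk factor
#'
#' Test choice follows the coding and factor type: a binary (dominant or
#' recessive) coding against a continuous factor uses the point-biserial
#' correlation test; a 3-level genotypic coding against a continuous factor
#' uses one-way ANOVA; any coding against a binary factor (smoking, drinking)
#' uses a Pearson chi-squared test on the contingency table. Both continuous
#' tests give the same p-value as a linear regression of the factor on the
#' coding. Missing values are removed pairwise.
#'
#' @param coded a `coded_genotype` from [recode()].
#' @param factor_values numeric vector (continuous factor) or 0/1 / logical
#'   vector (binary factor), same subject order as the coding.
#' @param factor_name label for the output row.
#' @param yates apply Yates continuity correction to chi-squared tests
#'   (default FALSE).
#' @return one-row `assoc_result` data frame: snp, coding, factor, test name,
#'   statistic, p-value, n used.
#' @export
assoc_scan <- function(coded, factor_values, factor_name = "factor",
                       yates = FALSE) {
  x <- coded$values
  y <- factor_values
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop_strokenet("too few complete pairs for association",
                   class = "strokenet_degenerate")
  }
  binary_factor <- is.logical(y) || all(y %in% c(0, 1))
  groups <- if (is.factor(x)) droplevels(x) else factor(x)
  if (nlevels(groups) < 2) {
    stop_strokenet("only one genotype group present",
                   class = "strokenet_degenerate")
  }
  if (binary_factor) {
    tab <- table(groups, factor(y))
    if (ncol(tab) < 2) {
      stop_strokenet("constant factor", class = "strokenet_degenerate")
    }
    ct <- suppressWarnings(chisq.test(tab, correct = yates))
    return(assoc_result(coded$snp_id, coded$coding, factor_name,
                        "pearson_chi2", unname(ct$statistic),
                        unname(ct$p.value), length(x)))
  }
  if (sd(y) == 0) {
    stop_strokenet("constant factor", class = "strokenet_degenerate")
  }
  if (coded$coding == "genotypic" || nlevels(groups) > 2) {
    fit <- aov(y ~ groups)
    a <- anova(fit)
    return(assoc_result(coded$snp_id, coded$coding, factor_name,
                        "anova_F", a[["F value"]][1], a[["Pr(>F)"]][1],
                        length(x)))
  }
  xn <- as.numeric(groups) - 1
  r <- cor(xn, y)
  dfree <- length(x) - 2
  tstat <- r * sqrt(dfree / (1 - r^2))
  p <- 2 * pt_abs(tstat, dfree)
  assoc_result(coded$snp_id, coded$coding, factor_name,
               "point_biserial", r, p, length(x))
}

pt_abs <- function(t, df) stats::pt(abs(t), df, lower.tail = FALSE)

#' Genotype-versus-subtype contrast
#'
#' 2x2 Pearson chi-squared test of a binary genotype contrast against one
#' stroke subtype versus everything else.
#'
#' @param coded a binary `coded_genotype` (dominant/recessive, or any 0/1
#'   contrast).
#' @param subtype_labels character/factor of subtype labels per subject.
#' @param subtype the subtype forming the positive class.
#' @param yates apply Yates continuity correction (default FALSE).
#' @return one-row `assoc_result` data frame.
#' @export
subtype_scan <- function(coded, subtype_labels, subtype, yates = FALSE) {
  x <- coded$values
  y <- as.character(subtype_labels)
  keep <- !is.na(x) & !is.na(y)
  x <- factor(x[keep])
  y <- factor(y[keep] == subtype, levels = c(FALSE, TRUE))
  if (nlevels(droplevels(x)) < 2) {
    stop_strokenet("only one genotype group present",
                   class = "strokenet_degenerate")
  }
  tab <- table(x, y)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_strokenet("zero margin in subtype table",
                   class = "strokenet_degenerate")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  assoc_result(coded$snp_id, coded$coding, paste0("subtype:", subtype),
               if (yates) "pearson_chi2_yates" else "pearson_chi2",
               unname(ct$statistic), unname(ct$p.value), sum(keep))
}

#' Full association scan over SNPs, codings and risk factors
#'
#' Convenience driver mirroring the single-locus association section of the
#' analysis: every SNP is tested under the requested codings against every
#' continuous risk factor, age, and the binary smoking/drinking flags.
#'
#' @param g a [genotype_matrix()].
#' @param phenotypes phenotype data frame as from [load_cohort()].
#' @param codings codings to test (default dominant + genotypic).
#' @param adjust optional p-value adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"` reports raw p.
#' @return data frame of `assoc_result` rows; degenerate tests are dropped.
#' @export
assoc_scan_all <- function(g, phenotypes,
                           codings = c("dominant", "genotypic"),
                           adjust = "none") {
  factors <- c(intersect(RISK_FACTORS, names(phenotypes)),
               intersect(c("age", "smoking", "drinking"), names(phenotypes)))
  rows <- list()
  for (s in g$snp_ids) {
    for (cod in codings) {
      coded <- recode(g, s, cod)
      for (f in factors) {
        res <- tryCatch(
          assoc_scan(coded, phenotypes[[f]], factor_name = f),
          strokenet_degenerate = function(e) NULL
        )
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  }
  out
}
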