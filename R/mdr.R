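# Multifactor dimensionality reduction (MDR): exhaustive k-locus interaction
# search with high/low-risk cell labeling, stratified cross-validation,
# permutation testing, pooled odds ratios, and entropy-based interaction
# graphs.

as_case_indicator <- function(status) {
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    if (!all(status %in% c("case", "control"))) {
      stop_strokenet("status labels must be 'case'/'control'",
                     class = "strokenet_invalid")
    }
    return(as.integer(status == "case"))
  }
  if (!all(status %in% c(0, 1))) {
    stop_strokenet("numeric status must be 0/1", class = "strokenet_invalid")
  }
  as.integer(status)
}

cell_keys <- function(dosages) {
  apply(dosages, 1, paste, collapse = "|")
}

# Label every observed multilocus genotype cell high/low by its case:control
# ratio against the threshold T = total cases / total controls. Ties go to
# high-risk; a cell with cases but no controls is high.
label_cells <- function(keys, case) {
  n_case <- sum(case)
  n_control <- sum(1 - case)
  threshold <- n_case / n_control
  cases <- tapply(case, keys, sum)
  totals <- tapply(case, keys, length)
  controls <- totals - cases
  ratio <- ifelse(controls == 0, Inf, cases / controls)
  label <- ifelse(ratio >= threshold, "high", "low")
  data.frame(cell = names(cases), cases = as.integer(cases),
             controls = as.integer(controls), ratio = as.numeric(ratio),
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

balanced_accuracy <- function(predicted_high, case) {
  sens <- if (sum(case) == 0) NA_real_ else
    sum(predicted_high & case == 1) / sum(case)
  spec <- if (sum(1 - case) == 0) NA_real_ else
    sum(!predicted_high & case == 0) / sum(1 - case)
  (sens + spec) / 2
}

#' Fit an MDR model on one attribute subset
#'
#' Builds the k-locus contingency table over all observed multilocus
#' genotypes, labels each cell high- or low-risk by whether its case:control
#' ratio meets the dataset threshold T = total cases / total controls (ties
#' and control-free cells are high), pools the labeled cells into one 2x2
#' table and computes the odds ratio with a Woolf (log) 95% CI, a Pearson
#' chi-squared p-value, and the training balanced accuracy of the implied
#' high-risk = predicted-case rule. Subjects missing any selected genotype
#' are excluded.
#'
#' @param g a [genotype_matrix()].
#' @param status case/control labels (`"case"`/`"control"` or 1/0).
#' @param attributes character vector of 1-4 rsIDs.
#' @return object of class `mdr_model`: cell table, pooled 2x2, `odds_ratio`
#'   with `ci`, `chi2_p`, `training_accuracy`, flags.
#' @export
mdr_fit <- function(g, status, attributes) {
  if (!length(attributes)) {
    stop_strokenet("empty attribute set", class = "strokenet_invalid")
  }
  if (length(attributes) > 4) {
    stop_strokenet("at most 4 attributes supported",
                   class = "strokenet_invalid")
  }
  missing_snps <- setdiff(attributes, g$snp_ids)
  if (length(missing_snps)) {
    stop_strokenet("unknown snp_id: ", paste(missing_snps, collapse = ", "),
                   class = "strokenet_key")
  }
  case <- as_case_indicator(status)
  d <- g$dosages[, attributes, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  case <- case[keep]
  if (!sum(case) || !sum(1 - case)) {
    stop_strokenet("both classes must be present", class = "strokenet_invalid")
  }
  keys <- cell_keys(d)
  cells <- label_cells(keys, case)

  high <- cells$label == "high"
  pooled <- matrix(c(sum(cells$cases[high]), sum(cells$controls[high]),
                     sum(cells$cases[!high]), sum(cells$controls[!high])),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("high", "low"), c("case", "control")))
  degenerate <- all(high) || all(!high)

  ta <- balanced_accuracy(high[match(keys, cells$cell)], case)

  haldane <- FALSE
  if (degenerate) {
    or <- NA_real_; ci <- c(NA_real_, NA_real_); chi2_p <- NA_real_
  } else {
    tab <- pooled
    if (any(tab == 0)) {
      tab <- tab + 0.5
      haldane <- TRUE
    }
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    se <- sqrt(sum(1 / tab))
    ci <- exp(log(or) + c(-1.96, 1.96) * se)
    chi2_p <- suppressWarnings(chisq.test(pooled, correct = FALSE)$p.value)
  }

  structure(
    list(attributes = attributes, cells = cells, pooled = pooled,
         odds_ratio = or, ci = ci, chi2_p = chi2_p,
         training_accuracy = ta, n = length(case),
         n_case = sum(case), n_control = sum(1 - case),
         degenerate = degenerate, haldane_corrected = haldane),
    class = "mdr_model"
  )
}

#' @export
print.mdr_model <- function(x, ...) {
  cat("MDR model:", paste(x$attributes, collapse = " x "), "\n")
  cat(sprintf("  training balanced accuracy = %.4f\n", x$training_accuracy))
  if (x$degenerate) {
    cat("  pooled table degenerate (single label); OR undefined\n")
  } else {
    cat(sprintf("  pooled OR = %.4f  95%% CI [%.4f, %.4f]  chi2 p = %.4g%s\n",
                x$odds_ratio, x$ci[1], x$ci[2], x$chi2_p,
                if (x$haldane_corrected) " (Haldane-corrected)" else ""))
  }
  invisible(x)
}

make_folds <- function(case, n_folds, seed) {
  folds <- integer(length(case))
  for (attempt in 0:9) {
    with_seed(child_seed(seed, attempt), {
      for (cls in c(0L, 1L)) {
        idx <- which(case == cls)
        folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    })
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(case[folds == f])) == 2
    }, logical(1)))
    if (ok) return(folds)
    msg("fold with a single class; refolding (attempt ", attempt + 1, ")")
  }
  stop_strokenet("could not build stratified folds with both classes",
                 class = "strokenet_degenerate")
}

predict_high <- function(train_cells, keys) {
  lab <- train_cells$label[match(keys, train_cells$cell)]
  !is.na(lab) & lab == "high"   # cells unseen in training -> low risk
}

#' Cross-validate one MDR attribute subset
#'
#' Stratified n-fold cross-validation: the cell labeling is learned on each
#' training split and balanced accuracy evaluated on the held-out split,
#' with genotype cells unseen in training predicted low-risk. A fold that
#' ends up single-class triggers a logged refold under a new derived seed.
#'
#' @inheritParams mdr_fit
#' @param n_folds number of folds (>= 2; default 10).
#' @param seed integer seed driving the stratified fold assignment.
#' @return list with `testing_accuracy` (mean over folds), per-fold
#'   `fold_accuracy`, `training_accuracy` per fold, and `folds`.
#' @export
mdr_cross_validate <- function(g, status, attributes, n_folds = 10,
                               seed = 1) {
  if (n_folds < 2) {
    stop_strokenet("n_folds must be >= 2", class = "strokenet_invalid")
  }
  case <- as_case_indicator(status)
  d <- g$dosages[, attributes, drop = FALSE]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  case <- case[keep]
  keys <- cell_keys(d)
  folds <- make_folds(case, n_folds, seed)
  train_acc <- test_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    cells <- label_cells(keys[tr], case[tr])
    train_acc[f] <- balanced_accuracy(predict_high(cells, keys[tr]), case[tr])
    test_acc[f] <- balanced_accuracy(predict_high(cells, keys[!tr]),
                                     case[!tr])
  }
  list(testing_accuracy = mean(test_acc), fold_accuracy = test_acc,
       training_accuracy = train_acc, folds = folds)
}

#' Exhaustive MDR search over attribute subsets
#'
#' Evaluates every subset of each size in `k_min:k_max` by stratified
#' cross-validation (one shared fold assignment per dataset). Within each
#' fold the subset with the best training balanced accuracy is that fold's
#' selected model; cross-validation consistency (CVC) of a subset is the
#' number of folds selecting it. The best model per size is the one with the
#' highest mean testing accuracy; the overall winner is the best-testing
#' model across sizes, CVC breaking ties.
#'
#' @inheritParams mdr_cross_validate
#' @param k_min,k_max subset sizes to search.
#' @param max_subsets guard on the total number of subsets (default 5000).
#' @return object of class `mdr_search`: `models` (data frame over all
#'   subsets: size, attributes, training/testing accuracy, CVC), `best_by_size`
#'   (list of full-data [mdr_fit()] models with CV fields), and `best`.
#' @export
mdr_search <- function(g, status, k_min = 1, k_max = 3, n_folds = 10,
                       seed = 1, max_subsets = 5000) {
  sizes <- k_min:k_max
  n_subsets <- sum(choose(length(g$snp_ids), sizes))
  if (n_subsets > max_subsets) {
    stop_strokenet("search space has ", n_subsets, " subsets (cap ",
                   max_subsets, "); reduce k_max",
                   class = "strokenet_invalid")
  }
  case <- as_case_indicator(status)
  folds <- make_folds(case, n_folds, seed)

  all_rows <- list()
  best_by_size <- list()
  for (k in sizes) {
    subsets <- combn(g$snp_ids, k, simplify = FALSE)
    train_mat <- matrix(NA_real_, length(subsets), n_folds)
    test_mat <- matrix(NA_real_, length(subsets), n_folds)
    for (i in seq_along(subsets)) {
      d <- g$dosages[, subsets[[i]], drop = FALSE]
      keep <- stats::complete.cases(d)
      keys <- cell_keys(d[keep, , drop = FALSE])
      ca <- case[keep]
      fo <- folds[keep]
      for (f in seq_len(n_folds)) {
        tr <- fo != f
        cells <- label_cells(keys[tr], ca[tr])
        train_mat[i, f] <-
          balanced_accuracy(predict_high(cells, keys[tr]), ca[tr])
        test_mat[i, f] <-
          balanced_accuracy(predict_high(cells, keys[!tr]), ca[!tr])
      }
    }
    cvc <- tabulate(apply(train_mat, 2, which.max), nbins = length(subsets))
    mean_test <- rowMeans(test_mat)
    rows <- data.frame(
      size = k,
      attributes = vapply(subsets, paste, character(1), collapse = ","),
      training_accuracy = rowMeans(train_mat),
      testing_accuracy = mean_test,
      cvc = cvc, stringsAsFactors = FALSE
    )
    all_rows[[length(all_rows) + 1L]] <- rows
    ibest <- order(-mean_test, -cvc)[1]
    model <- mdr_fit(g, status, subsets[[ibest]])
    model$testing_accuracy <- mean_test[ibest]
    model$cvc <- cvc[ibest]
    model$n_folds <- n_folds
    best_by_size[[as.character(k)]] <- model
  }
  models <- do.call(rbind, all_rows)
  test_by_size <- vapply(best_by_size, function(m) m$testing_accuracy,
                         numeric(1))
  cvc_by_size <- vapply(best_by_size, function(m) m$cvc, numeric(1))
  winner <- best_by_size[[order(-test_by_size, -cvc_by_size)[1]]]
  structure(list(models = models, best_by_size = best_by_size,
                 best = winner, n_folds = n_folds, seed = seed,
                 k_min = k_min, k_max = k_max),
            class = "mdr_search")
}

#' @export
print.mdr_search <- function(x, ...) {
  cat("MDR search (k =", x$k_min, "..", x$k_max, ",", x$n_folds, "folds)\n")
  for (m in x$best_by_size) {
    cat(sprintf("  k=%d best: %-32s test BA = %.4f  CVC = %d/%d\n",
                length(m$attributes), paste(m$attributes, collapse = ","),
                m$testing_accuracy, m$cvc, x$n_folds))
  }
  cat("Overall winner:", paste(x$best$attributes, collapse = ","), "\n")
  invisible(x)
}

#' Permutation (substitution) test for the best MDR model
#'
#' Permutes the case/control labels `n_perm` times and re-runs the full MDR
#' search each time, recording the best testing accuracy of each permuted
#' search; `p = (1 + #\{perm >= observed\}) / (n_perm + 1)`.
#'
#' @param g a [genotype_matrix()].
#' @param status case/control labels used for the observed search.
#' @param search an `mdr_search` result on the unpermuted labels.
#' @param n_perm number of permutations (>= 19, so alpha = 0.05 is
#'   resolvable; default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `p_value`, `observed`, and the vector of permuted
#'   best-model testing accuracies.
#' @export
mdr_permutation_test <- function(g, status, search, n_perm = 1000,
                                 seed = 1) {
  if (n_perm < 19) {
    stop_strokenet("n_perm must be >= 19 to resolve alpha = 0.05",
                   class = "strokenet_invalid")
  }
  case <- as_case_indicator(status)
  observed <- search$best$testing_accuracy
  perm_stats <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(child_seed(seed, b), sample(case))
    s <- mdr_search(g, perm, k_min = search$k_min, k_max = search$k_max,
                    n_folds = search$n_folds,
                    seed = child_seed(seed, 100000 + b))
    s$best$testing_accuracy
  }, numeric(1))
  list(p_value = (1 + sum(perm_stats >= observed)) / (n_perm + 1),
       observed = observed, permuted = perm_stats)
}
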