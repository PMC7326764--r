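# Model-based causal mediation analysis: genotype -> risk factor -> outcome.
#
# Two parametric component models (a linear mediator model and a logistic —
# or linear — outcome model) are fitted by maximum likelihood, then effects
# are computed by the quasi-Bayesian Monte-Carlo algorithm: parameter vectors
# are drawn from each model's asymptotic normal, potential mediator values
# are simulated under both treatment arms, and the average causal mediation
# effect (ACME), average direct effect (ADE) and total effect are averaged
# over subjects on the risk-difference scale. Identification rests on
# sequential ignorability.

#' Fit the mediator and outcome component models
#'
#' The mediator model is a Gaussian linear regression of the mediator on the
#' treatment (and optional pre-treatment covariates); the outcome model is a
#' logistic (binary outcome) or linear (continuous outcome) regression of the
#' outcome on treatment, mediator and covariates.
#'
#' @param treatment numeric treatment vector (coded genotype; values of a
#'   `coded_genotype` work directly).
#' @param mediator numeric mediator (risk factor) vector.
#' @param outcome 0/1 vector (binomial family) or numeric (gaussian family).
#' @param covariates optional data frame of pre-treatment covariates.
#' @param outcome_family `"binomial"` (logit link) or `"gaussian"`.
#' @return list with elements `mediator_model` (an `lm`), `outcome_model` (a
#'   `glm`/`lm`), the complete-case `data`, and `outcome_family`.
#' @export
fit_component_models <- function(treatment, mediator, outcome,
                                 covariates = NULL,
                                 outcome_family = c("binomial", "gaussian")) {
  outcome_family <- match.arg(outcome_family)
  df <- data.frame(.t = as.numeric(treatment), .m = as.numeric(mediator),
                   .y = as.numeric(outcome))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10) {
    stop_strokenet("fewer than 10 complete cases after missing removal",
                   class = "strokenet_degenerate")
  }
  if (outcome_family == "binomial" && !all(df$.y %in% c(0, 1))) {
    stop_strokenet("binomial outcome must be 0/1", class = "strokenet_invalid")
  }
  cov_terms <- if (is.null(covariates)) NULL else names(covariates)
  m_form <- stats::reformulate(c(".t", cov_terms), response = ".m")
  y_form <- stats::reformulate(c(".t", ".m", cov_terms), response = ".y")

  m_fit <- lm(m_form, data = df)
  check_full_rank(m_fit, "mediator model")

  separation <- FALSE
  y_fit <- withCallingHandlers(
    if (outcome_family == "binomial") {
      glm(y_form, data = df, family = binomial())
    } else {
      lm(y_form, data = df)
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (outcome_family == "binomial" &&
      any(fitted(y_fit) < 1e-8 | fitted(y_fit) > 1 - 1e-8)) {
    separation <- TRUE   # boundary fitted probabilities: separated design
  }
  if (separation) {
    stop_strokenet("perfect separation in the outcome model; ",
                   "reduce the model (drop covariates or pool genotypes)",
                   class = "strokenet_separation")
  }
  check_full_rank(y_fit, "outcome model")
  list(mediator_model = m_fit, outcome_model = y_fit, data = df,
       outcome_family = outcome_family)
}

check_full_rank <- function(fit, label) {
  co <- coef(fit)
  if (anyNA(co)) {
    stop_strokenet("rank-deficient design in the ", label,
                   " (collinear/constant columns: ",
                   paste(names(co)[is.na(co)], collapse = ", "), ")",
                   class = "strokenet_rank")
  }
  invisible(fit)
}

#' Causal mediation analysis for one treatment/mediator/outcome triple
#'
#' Quasi-Bayesian Monte-Carlo mediation: `nsim` parameter vectors are drawn
#' from the asymptotic normal of each fitted component model; for each draw
#' the potential mediator under the control and treated arm is simulated
#' (linear predictor plus Gaussian noise at the fitted residual SD) and the
#' four potential-outcome expectations are evaluated for every subject. On
#' the risk-difference scale, per draw,
#' ACME(t) = mean\[Y(t, M(1)) - Y(t, M(0))\] and
#' ADE(t) = mean\[Y(1, M(t)) - Y(0, M(t))\]; reported ACME/ADE average the
#' two treatment arms, so ACME + ADE equals the total effect exactly within
#' each draw. Point estimates are draw means, intervals are percentile
#' intervals, and two-sided Monte-Carlo p-values are
#' `2 * min(P(draw <= 0), P(draw >= 0))` floored at `1/(nsim + 1)`.
#' The proportion mediated is the median of draw-wise ACME/total ratios,
#' clipped to \[-1, 2\] with an out-of-range flag.
#'
#' @inheritParams fit_component_models
#' @param nsim number of quasi-Bayesian parameter draws (>= 100).
#' @param seed integer seed; fixing it fixes every reported number.
#' @param control_value,treat_value treatment values contrasted (default
#'   0 vs 1, the dominant-coding contrast; use 0 vs 2 for an additive sweep).
#' @param conf_level confidence level for percentile intervals.
#' @return object of class `mediation_result`: a list with `acme`, `ade`,
#'   `total`, `prop_mediated` (each a list of `estimate`, `ci`, `p_value`),
#'   the per-draw matrix `draws`, `nsim`, `seed`, and flags.
#' @export
mediate_path <- function(treatment, mediator, outcome, covariates = NULL,
                         outcome_family = c("binomial", "gaussian"),
                         nsim = 1000, seed = 1,
                         control_value = 0, treat_value = 1,
                         conf_level = 0.95) {
  outcome_family <- match.arg(outcome_family)
  if (nsim < 100) {
    stop_strokenet("nsim must be at least 100", class = "strokenet_invalid")
  }
  fits <- fit_component_models(treatment, mediator, outcome, covariates,
                               outcome_family)
  m_fit <- fits$mediator_model
  y_fit <- fits$outcome_model
  df <- fits$data
  n <- nrow(df)

  # parameter draws from each model's asymptotic normal
  draws <- with_seed(seed, {
    a_sims <- MASS::mvrnorm(nsim, mu = coef(m_fit), Sigma = vcov(m_fit))
    b_sims <- MASS::mvrnorm(nsim, mu = coef(y_fit), Sigma = vcov(y_fit))
    sigma_m <- summary(m_fit)$sigma
    err0 <- matrix(rnorm(n * nsim, sd = sigma_m), n, nsim)
    err1 <- matrix(rnorm(n * nsim, sd = sigma_m), n, nsim)
    list(a = a_sims, b = b_sims, err0 = err0, err1 = err1)
  })

  df0 <- df; df0$.t <- control_value
  df1 <- df; df1$.t <- treat_value
  Xm0 <- stats::model.matrix(stats::terms(m_fit), df0)
  Xm1 <- stats::model.matrix(stats::terms(m_fit), df1)
  M0 <- Xm0 %*% t(draws$a) + draws$err0   # n x nsim potential mediators
  M1 <- Xm1 %*% t(draws$a) + draws$err1

  link <- if (outcome_family == "binomial") plogis else identity
  ym <- stats::model.matrix(stats::terms(y_fit), df)
  m_col <- match(".m", colnames(ym))
  t_col <- match(".t", colnames(ym))
  # expected outcome for treatment value tv and mediator matrix M (n x nsim)
  pred_y <- function(tv, M) {
    base <- ym
    base[, t_col] <- tv
    base[, m_col] <- 0
    eta_base <- base %*% t(draws$b)              # n x nsim
    link(eta_base + M * rep(draws$b[, m_col], each = n))
  }
  p11 <- pred_y(treat_value, M1)
  p10 <- pred_y(treat_value, M0)
  p01 <- pred_y(control_value, M1)
  p00 <- pred_y(control_value, M0)

  d0 <- colMeans(p01 - p00)   # ACME under control
  d1 <- colMeans(p11 - p10)   # ACME under treatment
  z0 <- colMeans(p10 - p00)   # ADE with control-arm mediator
  z1 <- colMeans(p11 - p01)   # ADE with treated-arm mediator
  acme <- (d0 + d1) / 2
  ade <- (z0 + z1) / 2
  total <- acme + ade         # equals colMeans(p11 - p00) identically

  near_zero <- mean(abs(total) < 1e-12)
  pm_draws <- acme / total
  pm_raw <- median(pm_draws[is.finite(pm_draws)])
  pm_out_of_range <- !is.finite(pm_raw) || pm_raw < -1 || pm_raw > 2
  pm <- min(max(pm_raw, -1), 2)

  summarize <- function(x) {
    alpha <- 1 - conf_level
    ci <- unname(quantile(x, c(alpha / 2, 1 - alpha / 2)))
    p <- 2 * min(mean(x <= 0), mean(x >= 0))
    p <- min(1, max(p, 1 / (nsim + 1)))
    list(estimate = mean(x), ci = ci, p_value = p)
  }
  pm_sum <- summarize(pm_draws[is.finite(pm_draws)])
  pm_sum$estimate <- pm

  structure(
    list(acme = summarize(acme), ade = summarize(ade),
         total = summarize(total), prop_mediated = pm_sum,
         draws = cbind(acme = acme, ade = ade, total = total),
         nsim = nsim, seed = seed, n = n,
         conf_level = conf_level, outcome_family = outcome_family,
         prop_mediated_unstable = near_zero > 0.10,
         prop_mediated_out_of_range = pm_out_of_range,
         fits = fits),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(lab, s) {
    sprintf("  %-16s %8.4f  [%7.4f, %7.4f]  p = %.4g\n", lab,
            s$estimate, s$ci[1], s$ci[2], s$p_value)
  }
  cat("Causal mediation analysis (quasi-Bayesian, nsim = ", x$nsim,
      ", n = ", x$n, ")\n", sep = "")
  cat(fmt("ACME", x$acme))
  cat(fmt("ADE", x$ade))
  cat(fmt("Total effect", x$total))
  cat(fmt("Prop. mediated", x$prop_mediated))
  if (x$prop_mediated_unstable) {
    cat("  (proportion mediated unstable: total effect near zero)\n")
  }
  invisible(x)
}

#' Mediation scan over SNP x mediator x outcome triples
#'
#' Runs [mediate_path()] for every combination of the given SNPs, risk
#' factors and outcomes. Outcomes are `"IS"` (all cases vs controls) or a
#' TOAST subtype name (that subtype's cases vs controls; other cases are
#' excluded). Failed triples (degenerate designs etc.) are recorded with an
#' error message and the scan continues.
#'
#' @param cohort list with `genotypes` and `phenotypes`.
#' @param snps character vector of rsIDs.
#' @param mediators character vector of risk-factor column names.
#' @param outcomes character vector: `"IS"` and/or subtype names.
#' @param coding treatment coding passed to [recode()] (default dominant).
#' @param nsim,seed,covariates passed to [mediate_path()]; each triple gets a
#'   deterministic child seed.
#' @return data frame with one row per triple: ACME/ADE/total estimates and
#'   p-values, proportion mediated, and an `error` column (NA on success).
#' @export
mediation_scan <- function(cohort, snps, mediators, outcomes = "IS",
                           coding = "dominant", nsim = 1000, seed = 1,
                           covariates = NULL) {
  ph <- cohort$phenotypes
  grid <- expand.grid(snp = snps, mediator = mediators, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    snp <- grid$snp[i]; med <- grid$mediator[i]; out <- grid$outcome[i]
    keep <- rep(TRUE, nrow(ph))
    if (out == "IS") {
      y <- as.numeric(ph$status == "case")
    } else {
      keep <- ph$status == "control" | ph$subtype == out
      y <- as.numeric(ph$status[keep] == "case")
    }
    res <- tryCatch({
      coded <- recode(cohort$genotypes, snp, coding)
      r <- mediate_path(coded$values[keep], ph[[med]][keep], y,
                        covariates = if (is.null(covariates)) NULL else
                          covariates[keep, , drop = FALSE],
                        nsim = nsim, seed = child_seed(seed, i))
      data.frame(snp = snp, mediator = med, outcome = out,
                 acme = r$acme$estimate, acme_p = r$acme$p_value,
                 ade = r$ade$estimate, ade_p = r$ade$p_value,
                 total = r$total$estimate, total_p = r$total$p_value,
                 prop_mediated = r$prop_mediated$estimate,
                 n = r$n, error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(snp = snp, mediator = med, outcome = out,
                 acme = NA_real_, acme_p = NA_real_, ade = NA_real_,
                 ade_p = NA_real_, total = NA_real_, total_p = NA_real_,
                 prop_mediated = NA_real_, n = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}
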