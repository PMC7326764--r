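# Seeded synthetic-data generators for every pipeline input: HWE genotypes,
# case-control cohorts with planted genotype -> mediator -> outcome pathways,
# epistatic penetrance designs, and bipartite miRNA -> gene target maps.
#
# Every generator is a pure function of its arguments plus the seed; one
# master seed is expanded deterministically per sub-task so streams are
# independent and runs are bit-reproducible.

DEFAULT_SNPS <- c("rs10887800", "rs2576178", "rs2296545", "rs4073259",
                  "rs17286604", "rs7620580", "rs11712619", "rs6438833",
                  "rs243327", "rs243330", "rs33932899", "rs161827",
                  "rs161818", "rs161810")

# plausible null means/SDs for the clinical risk factors (units as measured:
# kg/m2, mmHg, mmol/L, years)
RISK_FACTOR_NULLS <- list(
  BMI = c(24, 3), systolic_BP = c(132, 16), diastolic_BP = c(82, 10),
  Glu = c(5.6, 1.2), TC = c(4.8, 0.9), TG = c(1.6, 0.7),
  HDL = c(1.3, 0.3), LDL = c(2.9, 0.8)
)

check_mafs <- function(mafs) {
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop_strokenet("MAFs must lie in (0, 0.5]", class = "strokenet_invalid")
  }
  mafs
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Dosages are drawn per SNP with probabilities (q^2, 2pq, p^2) for 0/1/2
#' copies of the minor allele (frequency p = MAF), independently across SNPs
#' and subjects.
#'
#' @param n number of subjects.
#' @param mafs numeric vector of minor-allele frequencies in (0, 0.5]; names
#'   become the rsIDs (default names `snp1..`).
#' @param seed integer seed.
#' @param subject_prefix prefix for generated subject ids.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, mafs, seed, subject_prefix = "S") {
  check_mafs(mafs)
  if (is.null(names(mafs))) {
    names(mafs) <- paste0("snp", seq_along(mafs))
  }
  dosages <- matrix(NA_integer_, n, length(mafs))
  for (j in seq_along(mafs)) {
    p <- mafs[j]
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    dosages[, j] <- with_seed(child_seed(seed, j), {
      sample(0:2, n, replace = TRUE, prob = probs)
    })
  }
  genotype_matrix(dosages, sprintf("%s%04d", subject_prefix, seq_len(n)),
                  names(mafs))
}

#' Simulate a case-control cohort with planted mediation pathways
#'
#' Emulates the retrospective design: a source population is generated —
#' HWE genotypes, risk factors from independent null normals, and an
#' outcome from a logistic model — and sampled until exactly `n_case` cases
#' and `n_control` controls are collected. Each planted pathway
#' `list(snp=, mediator=, a=, b=, c_prime=)` adds `a * coded(T)` to its
#' mediator's mean and `c_prime * coded(T) + b * (M - mu_M)` to the outcome
#' log-odds (the mediator enters centered at its null mean `mu_M`, so
#' `baseline_logodds` is the log-odds at the mediator mean for
#' non-carriers). Cases are assigned TOAST subtypes at fixed proportions.
#'
#' @param n_case,n_control target counts (defaults 507 / 503).
#' @param mafs named MAF vector (defaults: the 14 studied rsIDs at
#'   frequencies 0.2-0.5).
#' @param pathways list of planted pathways as above; may be empty (global
#'   null).
#' @param mediator_sd Gaussian noise SD used for planted mediators in place
#'   of the factor's null SD.
#' @param baseline_logodds intercept of the outcome model (0 gives a
#'   balanced source population, matching a ~1:1 case-control study).
#' @param coding treatment coding for `coded(T)` (default dominant).
#' @param subtype_probs proportions of atherothrombosis/lacunar/combination
#'   among cases.
#' @param seed integer seed (mandatory).
#' @param max_batches rejection-sampling cap before erroring.
#' @return list with `genotypes` (a [genotype_matrix()]) and `phenotypes`.
#' @export
simulate_cohort <- function(n_case = 507, n_control = 503,
                            mafs = NULL, pathways = list(),
                            mediator_sd = NULL, baseline_logodds = 0,
                            coding = "dominant",
                            subtype_probs = c(atherothrombosis = 0.45,
                                              lacunar = 0.35,
                                              combination = 0.20),
                            seed, max_batches = 200) {
  if (missing(seed)) {
    stop_strokenet("seed is mandatory", class = "strokenet_invalid")
  }
  if (is.null(mafs)) {
    mafs <- setNames(
      rep(c(0.25, 0.35, 0.45, 0.30, 0.20, 0.40, 0.50), 2),
      DEFAULT_SNPS
    )
  }
  check_mafs(mafs)
  for (pw in pathways) {
    stopifnot(all(c("snp", "mediator", "a", "b", "c_prime") %in% names(pw)))
    if (!pw$snp %in% names(mafs)) {
      stop_strokenet("pathway SNP not among simulated SNPs: ", pw$snp,
                     class = "strokenet_invalid")
    }
    if (!pw$mediator %in% names(RISK_FACTOR_NULLS)) {
      stop_strokenet("pathway mediator must be a risk factor column",
                     class = "strokenet_invalid")
    }
  }

  batch <- max(1000L, 2L * (n_case + n_control))
  got_case <- list(); got_control <- list()
  n_got_case <- 0L; n_got_control <- 0L
  for (b in seq_len(max_batches)) {
    g <- simulate_genotypes(batch, mafs, child_seed(seed, 1000 + b),
                            subject_prefix = sprintf("B%03d_", b))
    ph <- with_seed(child_seed(seed, 2000 + b), {
      out <- data.frame(subject_id = g$subject_ids,
                        stringsAsFactors = FALSE)
      for (f in names(RISK_FACTOR_NULLS)) {
        mu_sd <- RISK_FACTOR_NULLS[[f]]
        # truncate at a small positive floor: these are physically positive
        out[[f]] <- pmax(0.05, rnorm(batch, mu_sd[1], mu_sd[2]))
      }
      out$age <- pmax(20, rnorm(batch, 62, 10))
      out$sex <- sample(c("male", "female"), batch, replace = TRUE)
      out$smoking <- rbinom(batch, 1, 0.35)
      out$drinking <- rbinom(batch, 1, 0.30)
      out
    })
    eta <- rep(baseline_logodds, batch)
    for (k in seq_along(pathways)) {
      pw <- pathways[[k]]
      tvals <- recode(g, pw$snp, coding)$values
      mu_sd <- RISK_FACTOR_NULLS[[pw$mediator]]
      sdm <- if (is.null(mediator_sd)) mu_sd[2] else mediator_sd
      med <- with_seed(child_seed(seed, 3000 + 10 * b + k), {
        pmax(0.05, mu_sd[1] + pw$a * tvals + rnorm(batch, 0, sdm))
      })
      ph[[pw$mediator]] <- med
      eta <- eta + pw$c_prime * tvals + pw$b * (med - mu_sd[1])
    }
    y <- with_seed(child_seed(seed, 4000 + b), rbinom(batch, 1, plogis(eta)))

    need_case <- n_case - n_got_case
    need_control <- n_control - n_got_control
    take_case <- which(y == 1)[seq_len(min(need_case, sum(y == 1)))]
    take_control <- which(y == 0)[seq_len(min(need_control, sum(y == 0)))]
    if (length(take_case)) {
      got_case[[length(got_case) + 1L]] <-
        list(g = g$dosages[take_case, , drop = FALSE],
             ph = ph[take_case, , drop = FALSE])
      n_got_case <- n_got_case + length(take_case)
    }
    if (length(take_control)) {
      got_control[[length(got_control) + 1L]] <-
        list(g = g$dosages[take_control, , drop = FALSE],
             ph = ph[take_control, , drop = FALSE])
      n_got_control <- n_got_control + length(take_control)
    }
    if (n_got_case >= n_case && n_got_control >= n_control) break
  }
  if (n_got_case < n_case || n_got_control < n_control) {
    stop_strokenet("could not reach ", n_case, " cases / ", n_control,
                   " controls in ", max_batches, " batches; ",
                   "outcome probabilities too degenerate",
                   class = "strokenet_degenerate")
  }

  all_blocks <- c(got_case, got_control)
  dosages <- do.call(rbind, lapply(all_blocks, `[[`, "g"))
  ph <- do.call(rbind, lapply(all_blocks, `[[`, "ph"))
  n_total <- n_case + n_control
  ph$status <- rep(c("case", "control"), c(n_case, n_control))
  ph$subtype <- "none"
  ph$subtype[seq_len(n_case)] <- with_seed(child_seed(seed, 5000), {
    sample(names(subtype_probs), n_case, replace = TRUE,
           prob = subtype_probs)
  })
  ph$subject_id <- sprintf("SUB%05d", seq_len(n_total))
  ph <- ph[, PHENO_COLS]
  rownames(ph) <- NULL
  g <- genotype_matrix(dosages, ph$subject_id, names(mafs))
  list(genotypes = g, phenotypes = validate_phenotypes(ph))
}

#' Checkerboard (XOR-style) two-locus penetrance table
#'
#' Cells where the two dosages have odd sum get `p_high`, the rest `p_low`;
#' at MAF 0.5 the single-locus penetrance margins are flat, giving pure
#' epistasis with no marginal effect.
#'
#' @param p_high,p_low penetrances in the two cell classes.
#' @return 3x3 penetrance matrix indexed by dosages 0..2.
#' @export
xor_penetrance <- function(p_high = 0.7, p_low = 0.3) {
  outer(0:2, 0:2, function(i, j) ifelse((i + j) %% 2 == 1, p_high, p_low))
}

#' Simulate an epistatic case-control dataset
#'
#' Planted SNPs are drawn under HWE; case status is Bernoulli with
#' probability read from the multilocus penetrance table; decoy SNPs are
#' null (independent of status).
#'
#' @param n number of subjects.
#' @param penetrance k-dimensional array (each dim of length 3, dosages
#'   0..2) of case probabilities for the planted SNPs.
#' @param planted_mafs named MAF vector for the planted SNPs (length k).
#' @param decoy_mafs named MAF vector for null SNPs (may be empty).
#' @param seed integer seed.
#' @return list with `genotypes` ([genotype_matrix()], planted columns
#'   first), `status` (1 = case), and `planted` (the planted rsIDs).
#' @export
simulate_epistasis <- function(n, penetrance, planted_mafs,
                               decoy_mafs = numeric(0), seed) {
  k <- length(planted_mafs)
  penetrance <- as.array(penetrance)
  if (length(dim(penetrance)) != k || !all(dim(penetrance) == 3)) {
    stop_strokenet("penetrance must be a ", k,
                   "-dimensional array with dims of length 3",
                   class = "strokenet_invalid")
  }
  if (anyNA(penetrance)) {
    stop_strokenet("penetrance table has missing cells",
                   class = "strokenet_invalid")
  }
  if (any(penetrance < 0 | penetrance > 1)) {
    stop_strokenet("penetrance values must lie in [0, 1]",
                   class = "strokenet_invalid")
  }
  mafs <- c(planted_mafs, decoy_mafs)
  g <- simulate_genotypes(n, mafs, child_seed(seed, 1))
  idx <- g$dosages[, seq_len(k), drop = FALSE] + 1L
  pcase <- penetrance[idx]
  status <- with_seed(child_seed(seed, 2), rbinom(n, 1, pcase))
  list(genotypes = g, status = status, planted = names(planted_mafs))
}

#' Simulate a bipartite miRNA -> gene target map
#'
#' Null genes draw their targets uniformly at random from the miRNA pool;
#' each planted module is a gene set sharing a fixed block of miRNAs (plus
#' random extras up to the gene's target count), giving known-positive
#' competing pairs for calibration.
#'
#' @param m number of miRNAs (named `miR-1..m`).
#' @param n_genes number of genes (named `gene1..`).
#' @param targets_per_gene mean target count per gene (Poisson, truncated to
#'   >= 1 and <= m).
#' @param modules list of planted modules, each
#'   `list(genes = <ids or count>, shared = <number of shared miRNAs>)`.
#' @param seed integer seed.
#' @return a [target_map()].
#' @export
simulate_target_map <- function(m, n_genes, targets_per_gene = 5,
                                modules = list(), seed) {
  mirnas <- sprintf("miR-%d", seq_len(m))
  genes <- sprintf("gene%d", seq_len(n_genes))
  with_seed(seed, {
    counts <- pmin(m, pmax(1, stats::rpois(n_genes, targets_per_gene)))
    tgt <- lapply(seq_len(n_genes), function(i) sample(mirnas, counts[i]))
    names(tgt) <- genes
    for (mod in modules) {
      mod_genes <- if (is.numeric(mod$genes)) {
        sample(genes, mod$genes)
      } else {
        mod$genes
      }
      if (!all(mod_genes %in% genes)) {
        stop_strokenet("module genes must be among the simulated genes",
                       class = "strokenet_invalid")
      }
      if (mod$shared > m) {
        stop_strokenet("shared miRNA count exceeds m",
                       class = "strokenet_invalid")
      }
      shared <- sample(mirnas, mod$shared)
      for (gene in mod_genes) {
        extra <- setdiff(tgt[[gene]], shared)
        n_extra <- max(0, length(tgt[[gene]]) - mod$shared)
        tgt[[gene]] <- c(shared, extra[seq_len(min(n_extra, length(extra)))])
      }
    }
    pairs <- data.frame(
      miRNA = unlist(tgt, use.names = FALSE),
      gene = rep(names(tgt), lengths(tgt)),
      stringsAsFactors = FALSE
    )
    target_map(pairs)
  })
}
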