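# One-call pipeline: QC -> association -> mediation scan -> MDR ->
# competing-mRNA network -> enrichment, from a single validated config.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Validate a pipeline configuration
#'
#' Collects every problem before failing, so a bad config reports all its
#' errors at once. See [run_pipeline()] for the accepted fields.
#'
#' @param config list (or path to a YAML file) of pipeline settings.
#' @return the normalized config list, invisibly on success.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  need <- function(cond, what) {
    if (!isTRUE(cond)) problems <<- c(problems, what)
  }
  need(!is.null(config$seed), "seed: required")
  need(!is.null(config$output_dir), "output_dir: required")
  has_paths <- !is.null(config$genotypes) && !is.null(config$phenotypes)
  has_sim <- isTRUE(config$simulate$cohort)
  need(has_paths || has_sim,
       "inputs: give genotypes+phenotypes paths or simulate$cohort: true")
  if (has_paths) {
    for (f in c("genotypes", "phenotypes")) {
      need(file.exists(config[[f]] %||% ""),
           paste0(f, ": file not found: ", config[[f]]))
    }
  }
  if (!is.null(config$targets)) {
    need(file.exists(config$targets),
         paste0("targets: file not found: ", config$targets))
  }
  if (!is.null(config$gene_sets)) {
    need(file.exists(config$gene_sets),
         paste0("gene_sets: file not found: ", config$gene_sets))
  }
  for (a in c("edge_alpha", "ora_alpha")) {
    v <- config[[a]]
    if (!is.null(v)) need(v > 0 && v < 1, paste0(a, ": must be in (0,1)"))
  }
  if (length(problems)) {
    stop_strokenet("invalid pipeline config:\n  - ",
                   paste(problems, collapse = "\n  - "),
                   class = "strokenet_config")
  }
  defaults <- list(
    coding = "dominant", nsim = 1000, n_folds = 10, k_min = 1, k_max = 3,
    n_perm = 0, edge_alpha = 0.05, ora_alpha = 0.05,
    energy_cutoff = -20
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort load (or simulation), Hardy-Weinberg QC,
#' SNP-versus-risk-factor association scan, mediation scan, MDR interaction
#' search with entropy graph, competing-mRNA network with centralities, and
#' gene-set over-representation. Each stage writes a TSV under
#' `output_dir`; every reported number also lands in `summary.json`, and
#' `run.log` records seeds and record counts. Re-running an identical
#' config reproduces the summary byte-for-byte.
#'
#' Config fields (list or YAML): `seed`, `output_dir`; either `genotypes` +
#' `phenotypes` paths or `simulate: {cohort: true, n_case, n_control,
#' pathways}`; optional `targets` (miRNA-gene TSV) or `simulate_targets:
#' {m, n_genes, ...}`; optional `gene_sets` (GMT) and `seed_genes`;
#' `coding`, `nsim`, `n_folds`, `k_min`, `k_max`, `n_perm`, `edge_alpha`,
#' `ora_alpha`, `energy_cutoff`; `mediation: {snps, mediators, outcomes}`.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("strokenet pipeline; seed = ", config$seed),
                 paste0("R ", R.version$major, ".", R.version$minor))
  logit <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    msg(line)
  }
  summary <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "run.log"))
      stop_strokenet("stage '", name, "' failed: ", conditionMessage(e),
                     class = "strokenet_stage")
    })
  }

  # --- cohort -------------------------------------------------------------
  cohort <- stage("cohort", {
    if (isTRUE(config$simulate$cohort)) {
      sc <- config$simulate
      co <- simulate_cohort(
        n_case = sc$n_case %||% 507, n_control = sc$n_control %||% 503,
        pathways = sc$pathways %||% list(), seed = config$seed
      )
      logit("simulated cohort: ", sum(co$phenotypes$status == "case"),
            " cases / ", sum(co$phenotypes$status == "control"), " controls")
      co
    } else {
      load_cohort(config$genotypes, config$phenotypes)
    }
  })
  summary$n_case <- sum(cohort$phenotypes$status == "case")
  summary$n_control <- sum(cohort$phenotypes$status == "control")

  # --- HWE ----------------------------------------------------------------
  hwe <- stage("hwe", hwe_scan(cohort$genotypes))
  write_tsv(hwe, file.path(out_dir, "hwe.tsv"))
  logit("HWE scan: ", nrow(hwe), " SNPs, min p = ",
        format(min(hwe$p_value), digits = 4))
  summary$hwe <- setNames(as.list(hwe$p_value), hwe$snp_id)

  # --- association --------------------------------------------------------
  assoc <- stage("association",
                 assoc_scan_all(cohort$genotypes, cohort$phenotypes))
  write_tsv(assoc, file.path(out_dir, "assoc.tsv"))
  logit("association scan: ", nrow(assoc), " tests")
  summary$assoc_n_tests <- nrow(assoc)
  summary$assoc_min_p <- min(assoc$p_value)

  # --- mediation ----------------------------------------------------------
  med_cfg <- config$mediation %||% list()
  med <- stage("mediation", mediation_scan(
    cohort,
    snps = med_cfg$snps %||% cohort$genotypes$snp_ids,
    mediators = med_cfg$mediators %||% RISK_FACTORS,
    outcomes = med_cfg$outcomes %||% "IS",
    coding = config$coding, nsim = config$nsim,
    seed = child_seed(config$seed, 11)
  ))
  write_tsv(med, file.path(out_dir, "mediation.tsv"))
  logit("mediation scan: ", nrow(med), " triples, ",
        sum(!is.na(med$error)), " failed")
  summary$mediation_n_triples <- nrow(med)
  ok <- is.na(med$error)
  summary$mediation_min_acme_p <- if (any(ok)) min(med$acme_p[ok]) else NA

  # --- MDR ----------------------------------------------------------------
  status <- cohort$phenotypes$status
  search <- stage("mdr", mdr_search(
    cohort$genotypes, status, k_min = config$k_min, k_max = config$k_max,
    n_folds = config$n_folds, seed = child_seed(config$seed, 21)
  ))
  write_tsv(search$models, file.path(out_dir, "mdr_models.tsv"))
  best <- search$best
  write_tsv(best$cells, file.path(out_dir, "mdr_best_cells.tsv"))
  logit("MDR winner: ", paste(best$attributes, collapse = ","),
        " (test BA ", format(best$testing_accuracy, digits = 4), ")")
  summary$mdr_best_attributes <- paste(best$attributes, collapse = ",")
  summary$mdr_best_testing_accuracy <- best$testing_accuracy
  summary$mdr_best_cvc <- best$cvc
  summary$mdr_best_or <- best$odds_ratio
  summary$mdr_best_or_ci <- best$ci
  if (config$n_perm >= 19) {
    perm <- stage("mdr_permutation", mdr_permutation_test(
      cohort$genotypes, status, search, n_perm = config$n_perm,
      seed = child_seed(config$seed, 22)
    ))
    summary$mdr_permutation_p <- perm$p_value
    logit("MDR permutation p = ", format(perm$p_value, digits = 4))
  }
  eg <- stage("entropy", entropy_graph(cohort$genotypes, status,
                                       cohort$genotypes$snp_ids))
  write_tsv(eg$edges, file.path(out_dir, "entropy_edges.tsv"))
  write_tsv(eg$nodes, file.path(out_dir, "entropy_nodes.tsv"))
  if (!is.null(eg$newick)) {
    writeLines(eg$newick, file.path(out_dir, "mdr_dendrogram.nwk"))
  }
  summary$class_entropy_bits <- eg$class_entropy_bits
  summary$max_single_snp_ig_pct <- max(eg$nodes$ig_pct)

  # --- competing-mRNA network --------------------------------------------
  map <- NULL
  if (!is.null(config$targets)) {
    map <- stage("targets",
                 load_target_map(config$targets, config$energy_cutoff))
  } else if (!is.null(config$simulate_targets)) {
    st <- config$simulate_targets
    map <- stage("targets", simulate_target_map(
      m = st$m, n_genes = st$n_genes,
      targets_per_gene = st$targets_per_gene %||% 5,
      modules = st$modules %||% list(),
      seed = child_seed(config$seed, 31)
    ))
  }
  if (!is.null(map)) {
    net <- stage("network", build_network(
      map, seed_genes = config$seed_genes, alpha = config$edge_alpha
    ))
    write_tsv(net$edges, file.path(out_dir, "network_edges.tsv"))
    logit("network: ", net$n_nodes, " nodes, ", net$n_edges, " edges")
    summary$network_nodes <- net$n_nodes
    summary$network_edges <- net$n_edges
    if (net$n_edges > 0) {
      cent <- stage("centrality", centralities(net))
      write_tsv(cent$table, file.path(out_dir, "centrality.tsv"))
      summary$centrality_top_intersection <- cent$top_intersection
      pl <- tryCatch(powerlaw_fit(net), strokenet_degenerate = function(e) NULL)
      if (!is.null(pl)) {
        summary$powerlaw_slope <- pl$slope
        summary$powerlaw_r_squared <- pl$r_squared
      }
      if (!is.null(config$gene_sets)) {
        sets <- stage("gene_sets", read_gmt(config$gene_sets))
        enr <- stage("enrichment", ora(
          query_genes = intersect(cent$table$gene, map$genes),
          gene_sets = sets, universe = map$genes,
          alpha = config$ora_alpha
        ))
        write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
        summary$enrichment_n_significant <- sum(enr$significant)
        summary$enrichment_top_term <- enr$term[1]
      }
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}
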