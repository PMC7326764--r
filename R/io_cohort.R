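# Cohort I/O: genotype matrices, phenotype tables, genotype recoding.

RISK_FACTORS <- c("BMI", "systolic_BP", "diastolic_BP", "Glu",
                  "TC", "TG", "HDL", "LDL")
PHENO_COLS <- c("subject_id", "status", "subtype", RISK_FACTORS,
                "age", "sex", "smoking", "drinking")
SUBTYPES <- c("atherothrombosis", "lacunar", "combination", "none")

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds minor-allele dosages (0/1/2, `NA` allowed) for a
#' set of subjects at a set of SNPs, with optional per-SNP allele labels.
#'
#' @param dosages integer matrix, subjects in rows, SNPs in columns.
#' @param subject_ids character vector of unique subject identifiers.
#' @param snp_ids character vector of unique rsIDs.
#' @param allele_labels optional data frame with columns `snp_id`, `major`,
#'   `minor` giving the allele strings behind the dosage coding.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, subject_ids, snp_ids,
                            allele_labels = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(subject_ids) ||
      ncol(dosages) != length(snp_ids)) {
    stop_strokenet("dosage dimensions (", nrow(dosages), "x", ncol(dosages),
                   ") do not match id lists (", length(subject_ids), ", ",
                   length(snp_ids), ")", class = "strokenet_invalid")
  }
  if (anyDuplicated(subject_ids)) {
    stop_strokenet("duplicate subject_ids", class = "strokenet_invalid")
  }
  if (anyDuplicated(snp_ids)) {
    stop_strokenet("duplicate snp_ids", class = "strokenet_invalid")
  }
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    bad <- vals[!vals %in% c(0L, 1L, 2L)][1L]
    stop_strokenet("dosage values must be 0, 1, 2 or NA (found ", bad, ")",
                   class = "strokenet_parse")
  }
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(as.character(subject_ids), as.character(snp_ids))
  structure(
    list(dosages = dosages,
         subject_ids = as.character(subject_ids),
         snp_ids = as.character(snp_ids),
         allele_labels = allele_labels),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$subject_ids), "subjects x",
      length(x$snp_ids), "SNPs;",
      sum(is.na(x$dosages)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

validate_phenotypes <- function(ph) {
  missing_cols <- setdiff(c("subject_id", "status"), names(ph))
  if (length(missing_cols)) {
    stop_strokenet("phenotype table missing column(s): ",
                   paste(missing_cols, collapse = ", "),
                   class = "strokenet_parse")
  }
  if (anyNA(ph$status)) {
    stop_strokenet("status must be non-missing for every subject",
                   class = "strokenet_invalid")
  }
  if (!all(ph$status %in% c("case", "control"))) {
    stop_strokenet("status values must be 'case' or 'control'",
                   class = "strokenet_parse")
  }
  if ("subtype" %in% names(ph)) {
    if (!all(ph$subtype %in% SUBTYPES)) {
      stop_strokenet("unknown subtype label",
                     class = "strokenet_parse")
    }
    if (any(ph$status == "control" & ph$subtype != "none") ||
        any(ph$status == "case" & ph$subtype == "none")) {
      stop_strokenet("subtype must be 'none' exactly for controls",
                     class = "strokenet_invalid")
    }
  }
  # physically positive quantities
  for (col in intersect(c("systolic_BP", "diastolic_BP", RISK_FACTORS),
                        names(ph))) {
    v <- ph[[col]]
    if (any(!is.na(v) & (!is.finite(v) | v <= 0))) {
      stop_strokenet("column ", col, " must be missing or finite positive",
                     class = "strokenet_invalid")
    }
  }
  ph
}

read_genotype_tsv <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  if (!"subject_id" %in% names(raw)) {
    stop_strokenet("genotype file must have a subject_id column",
                   class = "strokenet_parse")
  }
  snp_ids <- setdiff(names(raw), "subject_id")
  if (!length(snp_ids)) {
    stop_strokenet("genotype file has no SNP columns",
                   class = "strokenet_parse")
  }
  mat <- as.matrix(raw[, snp_ids, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "integer")
  bad <- which(!is.na(mat) & !(mat %in% c(0L, 1L, 2L)), arr.ind = TRUE)
  # non-numeric entries become NA during coercion; re-check against source
  src <- as.matrix(raw[, snp_ids, drop = FALSE])
  coerce_na <- which(is.na(mat) & !is.na(src) & src != "", arr.ind = TRUE)
  if (nrow(coerce_na)) bad <- rbind(bad, coerce_na)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_strokenet("invalid dosage '", src[i, j], "' for ", snp_ids[j],
                   " at data line ", i, " of ", basename(path),
                   class = "strokenet_parse")
  }
  genotype_matrix(mat, raw$subject_id, snp_ids)
}

read_phenotype_csv <- function(path) {
  ph <- read.table(path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_phenotypes(ph)
}

#' Load a matched genotype/phenotype cohort
#'
#' Reads a genotype TSV (column `subject_id` plus one 0/1/2/NA column per
#' rsID) and a phenotype CSV (columns `subject_id`, `status`, `subtype`, the
#' risk factors `BMI`, `systolic_BP`, `diastolic_BP`, `Glu`, `TC`, `TG`,
#' `HDL`, `LDL`, and `age`, `sex`, `smoking`, `drinking`), intersects them on
#' subject id, and returns both in a consistent subject order. Subjects
#' present in only one file are dropped with a warning.
#'
#' @param genotype_path path to the genotype TSV.
#' @param phenotype_path path to the phenotype CSV.
#' @return a list with elements `genotypes` (a [genotype_matrix()]) and
#'   `phenotypes` (a data frame), subject-aligned.
#' @export
load_cohort <- function(genotype_path, phenotype_path) {
  g <- read_genotype_tsv(genotype_path)
  ph <- read_phenotype_csv(phenotype_path)
  common <- intersect(g$subject_ids, ph$subject_id)
  if (!length(common)) {
    stop_strokenet("no overlap between genotype and phenotype subject ids",
                   class = "strokenet_no_overlap")
  }
  dropped <- (length(g$subject_ids) - length(common)) +
    (nrow(ph) - length(common))
  if (dropped > 0) {
    warning(dropped, " subject record(s) present in only one file dropped",
            call. = FALSE)
  }
  g <- genotype_matrix(g$dosages[match(common, g$subject_ids), , drop = FALSE],
                       common, g$snp_ids, g$allele_labels)
  ph <- ph[match(common, ph$subject_id), , drop = FALSE]
  rownames(ph) <- NULL
  msg("loaded cohort: ", length(common), " subjects, ",
      length(g$snp_ids), " SNPs")
  list(genotypes = g, phenotypes = ph)
}

#' Write a cohort back to disk
#'
#' Inverse of [load_cohort()]: writes the genotype TSV and phenotype CSV in
#' the dialect the readers accept, so a write -> read round trip is
#' value-identical.
#'
#' @param cohort list with `genotypes` and `phenotypes` as from
#'   [load_cohort()] or [simulate_cohort()].
#' @param genotype_path,phenotype_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, genotype_path, phenotype_path) {
  g <- cohort$genotypes
  gdf <- data.frame(subject_id = g$subject_ids, g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(gdf, genotype_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$phenotypes, phenotype_path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Import genotypes from a VCF
#'
#' Converts the GT field of a VCF to minor-allele dosages. Only biallelic
#' sites are kept; the minor allele is defined by observed frequency in the
#' file (ties broken lexicographically by allele string), so REF/ALT
#' orientation does not matter.
#'
#' @param vcf_path path to an uncompressed or bgzipped VCF.
#' @return a [genotype_matrix()].
#' @export
vcf_to_genotypes <- function(vcf_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_strokenet("VCF import requires the vcfR package",
                   class = "strokenet_dependency")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  keep <- !grepl(",", fix[, "ALT"])  # biallelic only
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alt_dose <- function(x) {
    ifelse(is.na(x), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", x), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  dos <- t(apply(gt, 1, alt_dose))  # SNPs x subjects, ALT dosage
  labels <- data.frame(snp_id = fix[, "ID"], major = fix[, "REF"],
                       minor = fix[, "ALT"], stringsAsFactors = FALSE)
  # orient to minor-allele dosage per observed frequency
  for (i in seq_len(nrow(dos))) {
    f_alt <- mean(dos[i, ], na.rm = TRUE) / 2
    flip <- f_alt > 0.5 ||
      (f_alt == 0.5 && fix[i, "REF"] < fix[i, "ALT"])
    if (isTRUE(flip)) {
      dos[i, ] <- 2L - dos[i, ]
      labels[i, c("major", "minor")] <- labels[i, c("minor", "major")]
    }
  }
  genotype_matrix(t(dos), colnames(gt), fix[, "ID"], labels)
}

#' Recode a SNP under a genetic model
#'
#' @param g a [genotype_matrix()].
#' @param snp_id rsID present in `g`.
#' @param coding one of `"additive"` (dosage 0/1/2), `"dominant"`
#'   (minor-allele carrier, dosage >= 1, vs non-carrier), `"recessive"`
#'   (dosage 2 vs rest) or `"genotypic"` (3-level factor). Missing dosages
#'   propagate.
#' @return an object of class `coded_genotype`: a list with `snp_id`,
#'   `coding` and `values` (numeric, or factor for `"genotypic"`).
#' @export
recode <- function(g, snp_id,
                   coding = c("additive", "dominant", "recessive",
                              "genotypic")) {
  coding <- match.arg(coding)
  if (!snp_id %in% g$snp_ids) {
    stop_strokenet("unknown snp_id: ", snp_id, class = "strokenet_key")
  }
  d <- g$dosages[, snp_id]
  values <- switch(coding,
    additive = as.numeric(d),
    dominant = as.numeric(d >= 1L),
    recessive = as.numeric(d == 2L),
    genotypic = factor(d, levels = 0:2,
                       labels = c("major_hom", "het", "minor_hom"))
  )
  structure(list(snp_id = snp_id, coding = coding, values = values),
            class = "coded_genotype")
}

#' @export
print.coded_genotype <- function(x, ...) {
  cat("coded_genotype:", x$snp_id, "(", x$coding, "),",
      length(x$values), "subjects\n")
  invisible(x)
}
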