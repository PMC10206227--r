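# Cohort-level frequency summaries: haplotype/diplotype/phenotype
# frequency tables, allele-count thresholds, function-class composition,
# demographics, and a targeted rsID scan.

freq_table <- function(gene, unit, labels, denominator) {
  tab <- table(labels)
  data.frame(gene = gene, unit = unit, label = names(tab),
             count = as.integer(tab),
             freq = as.integer(tab) / denominator,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Haplotype frequency table
#'
#' Each individual contributes two haplotype units per gene; a duplicated
#' allele counts as a single unit under its `xN` label, so the denominator
#' stays 2N.
#'
#' @param calls Diplotype calls (columns `gene`, `allele1`, `allele2`).
#' @param gene Optional single gene; default tabulates every gene present.
#' @return `data.frame` of class `pgx_freq_table`: `gene`, `unit`, `label`,
#'   `count`, `freq`.
#' @export
haplotype_frequencies <- function(calls, gene = NULL) {
  if (!is.null(gene)) calls <- calls[calls$gene == gene, , drop = FALSE]
  out <- do.call(rbind, lapply(split(calls, calls$gene), function(g) {
    freq_table(g$gene[1], "haplotype", c(g$allele1, g$allele2),
               2L * nrow(g))
  }))
  out <- out %||% data.frame(gene = character(0), unit = character(0),
                             label = character(0), count = integer(0),
                             freq = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("pgx_freq_table", "data.frame")
  out
}

#' Diplotype frequency table
#'
#' @inheritParams haplotype_frequencies
#' @return `pgx_freq_table` with one unit per individual (denominator N).
#' @export
diplotype_frequencies <- function(calls, gene = NULL) {
  if (!is.null(gene)) calls <- calls[calls$gene == gene, , drop = FALSE]
  dips <- vapply(seq_len(nrow(calls)), function(i) {
    diplotype_string(calls$allele1[i], calls$allele2[i])
  }, character(1))
  calls$._dip <- dips
  out <- do.call(rbind, lapply(split(calls, calls$gene), function(g) {
    freq_table(g$gene[1], "diplotype", g$._dip, nrow(g))
  }))
  out <- out %||% data.frame(gene = character(0), unit = character(0),
                             label = character(0), count = integer(0),
                             freq = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("pgx_freq_table", "data.frame")
  out
}

#' Phenotype frequency table
#'
#' @param assignments Assignment table from [phenotype_cohort()].
#' @param gene Optional single gene.
#' @return `pgx_freq_table` with one unit per individual.
#' @export
phenotype_frequencies <- function(assignments, gene = NULL) {
  if (!is.null(gene)) {
    assignments <- assignments[assignments$gene == gene, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(assignments, assignments$gene),
                               function(g) {
    freq_table(g$gene[1], "phenotype", g$phenotype, nrow(g))
  }))
  out <- out %||% data.frame(gene = character(0), unit = character(0),
                             label = character(0), count = integer(0),
                             freq = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("pgx_freq_table", "data.frame")
  out
}

#' Partition allele counts by frequency thresholds
#'
#' Counts distinct allele labels in a frequency table: the total, the
#' number strictly below each threshold, and the complement at or above
#' the first threshold (so `total = below + at_or_above` always holds).
#'
#' @param freqs A frequency table (any data frame with a `freq` column,
#'   one row per allele label).
#' @param thresholds Numeric thresholds; default `c(0.05, 0.01)`.
#' @return List: `total`, `below` (named by threshold), `at_or_above`
#'   (first threshold).
#' @export
count_alleles_by_threshold <- function(freqs, thresholds = c(0.05, 0.01)) {
  f <- freqs$freq
  below <- vapply(thresholds, function(t) sum(f < t), integer(1))
  names(below) <- format(thresholds, trim = TRUE)
  list(total = length(f), below = below,
       at_or_above = length(f) - below[[1]])
}

#' Function-class composition among common alleles
#'
#' Proportions of each allele function class (increased / normal /
#' decreased / loss / unknown, derived from activity scores) among alleles
#' with frequency strictly above the threshold.
#'
#' @param freqs A haplotype `pgx_freq_table` (columns `gene`, `label`,
#'   `freq`).
#' @param defs A `pgx_allele_def_set` covering every gene in the table.
#' @param threshold Commonness cutoff (frequency strictly greater).
#' @return Named numeric vector of proportions summing to 1 (empty when no
#'   allele passes the threshold).
#' @export
function_class_composition <- function(freqs, defs, threshold = 0.05) {
  common <- freqs[freqs$freq > threshold, , drop = FALSE]
  if (!nrow(common)) return(stats::setNames(numeric(0), character(0)))
  classes <- vapply(seq_len(nrow(common)), function(i) {
    dg <- defs[[common$gene[i]]]
    if (is.null(dg)) {
      stop_pgx("no allele definitions for gene ", common$gene[i])
    }
    as <- allele_activity_score(dg, common$label[i])
    base <- parse_allele_label(common$label[i])$base
    if (is.na(as) && !base %in% c(dg$alleles$allele, dg$deletion_allele)) {
      stop_pgx("allele ", common$label[i], " (", common$gene[i],
               ") missing from definitions")
    }
    function_class_from_as(as)
  }, character(1))
  tab <- table(classes)
  out <- as.numeric(tab) / sum(tab)
  stats::setNames(out, names(tab))
}

#' Cohort demographics summary
#'
#' Counts and percentages (half-up, one decimal) for sex and color/race
#' categories, plus the age median and interquartile range.
#'
#' @param demographics `data.frame` with `sex`, `age`, `color_race` (a
#'   `pgx_cohort` is also accepted).
#' @return List of class `pgx_demographics`.
#' @export
demographics_summary <- function(demographics) {
  if (inherits(demographics, "pgx_cohort")) {
    demographics <- demographics$demographics
  }
  n <- nrow(demographics)
  if (!n) stop_pgx("empty cohort")
  sex_counts <- table(demographics$sex)
  race_counts <- table(demographics$color_race)
  structure(list(
    n = n,
    sex = data.frame(category = names(sex_counts),
                     count = as.integer(sex_counts),
                     pct = pct(as.integer(sex_counts), n),
                     stringsAsFactors = FALSE),
    age_median = stats::median(demographics$age),
    age_iqr = unname(stats::quantile(demographics$age, c(0.25, 0.75))),
    color_race = data.frame(category = names(race_counts),
                            count = as.integer(race_counts),
                            pct = pct(as.integer(race_counts), n),
                            stringsAsFactors = FALSE)
  ), class = "pgx_demographics")
}

#' @method print pgx_demographics
#' @export
print.pgx_demographics <- function(x, ...) {
  cat("Cohort of", x$n, "individuals; median age", x$age_median,
      sprintf("(IQR %s-%s)\n", x$age_iqr[1], x$age_iqr[2]))
  print(x$sex, row.names = FALSE)
  print(x$color_race, row.names = FALSE)
  invisible(x)
}

#' Targeted rsID scan
#'
#' Allele frequency and carrier counts for a list of rsIDs, straight from
#' the VCF `ID` column and `GT` fields. An rsID not present in the VCF is
#' reported as absent, not an error.
#'
#' @param vcf Path to a VCF or a parsed VCF from [read_phased_vcf()].
#' @param rsids Character vector of rsIDs.
#' @return `data.frame`: `rsid`, `present`, `n_samples`, `het_count`,
#'   `hom_count`, `allele_freq` (alt alleles / 2N).
#' @export
rsid_scan <- function(vcf, rsids) {
  if (is.character(vcf)) vcf <- read_phased_vcf(vcf)
  n <- length(vcf$samples)
  do.call(rbind, lapply(rsids, function(rs) {
    i <- which(vcf$sites$id == rs)
    if (!length(i)) {
      return(data.frame(rsid = rs, present = FALSE, n_samples = n,
                        het_count = 0L, hom_count = 0L, allele_freq = 0,
                        stringsAsFactors = FALSE))
    }
    alt_per_sample <- rep(0L, n)
    for (j in i) {
      g <- vcf$gt[j, ]
      alleles <- strsplit(g, "[|/]")
      alt_per_sample <- alt_per_sample + vapply(alleles, function(a) {
        sum(!is.na(a) & a != "0" & a != ".")
      }, integer(1))
    }
    data.frame(rsid = rs, present = TRUE, n_samples = n,
               het_count = sum(alt_per_sample == 1L),
               hom_count = sum(alt_per_sample >= 2L),
               allele_freq = if (n) sum(alt_per_sample) / (2 * n) else 0,
               stringsAsFactors = FALSE)
  }))
}
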