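# EHR priority risk annotation, medication cross-referencing against
# PharmGKB level 1A drug-gene pairs, and cohort interaction summaries.

#' Annotate phenotype assignments with EHR priority risk
#'
#' Joins each (gene, phenotype) assignment to the EHR Priority Result
#' Notation. "Likely"/"Possible" qualifiers collapse onto their base
#' phenotype before matching. A phenotype with no row for its gene is a
#' vocabulary error.
#'
#' @param assignments Assignment table from [phenotype_cohort()].
#' @param risk_table A `pgx_risk_table`.
#' @return `data.frame`: `sample`, `gene`, `phenotype`, `high_risk`,
#'   `priority_label`.
#' @export
annotate_risk <- function(assignments, risk_table) {
  key <- paste(assignments$gene, collapse_phenotype(assignments$phenotype))
  risk_key <- paste(risk_table$gene, collapse_phenotype(risk_table$phenotype))
  idx <- match(key, risk_key)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop_pgx("phenotype label(s) absent from the EHR risk vocabulary: ",
             paste(miss, collapse = "; "))
  }
  data.frame(sample = assignments$sample, gene = assignments$gene,
             phenotype = assignments$phenotype,
             high_risk = risk_table$high_risk[idx],
             priority_label = risk_table$priority_label[idx],
             stringsAsFactors = FALSE)
}

#' At least one high-risk genotype per individual
#'
#' @param annotations Risk annotations from [annotate_risk()].
#' @param genes Genes to consider (typically the nine PharmGKB level 1A
#'   genes).
#' @return Named logical vector, one element per sample present.
#' @export
any_high_risk <- function(annotations,
                          genes = c("CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6",
                                    "CYP3A5", "NUDT15", "SLCO1B1", "TPMT",
                                    "UGT1A1")) {
  sub <- annotations[annotations$gene %in% genes, , drop = FALSE]
  out <- tapply(sub$high_risk, factor(sub$sample,
                                      levels = unique(annotations$sample)),
                any, default = FALSE)
  stats::setNames(as.logical(out), names(out))
}

#' Read a medications CSV
#'
#' @param path CSV with columns `id`, `drugs` (semicolon-joined) and
#'   `missing` (0/1).
#' @return `data.frame` with `missing` as logical.
#' @export
read_medications <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(c("id", "drugs", "missing"), names(df))
  if (length(missing_cols)) {
    stop_pgx(basename(path), ": missing column(s) ",
             paste(missing_cols, collapse = ", "))
  }
  df$missing <- as.integer(df$missing) == 1L
  df
}

split_drugs <- function(drugs, synonyms = NULL) {
  lapply(strsplit(drugs, ";", fixed = TRUE), function(d) {
    d <- d[nzchar(d)]
    unique(normalize_drug_names(d, synonyms))
  })
}

#' Flag high-risk gene-drug interactions
#'
#' An interaction flag is one (sample, drug, gene) event where the
#' individual takes a level 1A drug and carries a high-risk phenotype for
#' the paired gene. Individuals with missing medication data produce no
#' flags (and are excluded from summary denominators).
#'
#' @param medications Medication table (`id`, `drugs`, `missing`).
#' @param annotations Risk annotations from [annotate_risk()].
#' @param pairs A `pgx_drug_gene_pairs` table.
#' @param synonyms Optional synonym map from [load_drug_synonyms()].
#' @return `data.frame`: `sample`, `drug`, `gene`, `phenotype`.
#' @export
flag_interactions <- function(medications, annotations, pairs,
                              synonyms = NULL) {
  taken <- split_drugs(medications$drugs, synonyms)
  names(taken) <- medications$id
  hr <- annotations[annotations$high_risk, , drop = FALSE]
  rows <- lapply(which(!medications$missing), function(i) {
    id <- medications$id[i]
    drugs <- taken[[i]]
    if (!length(drugs)) return(NULL)
    g <- hr[hr$sample == id, , drop = FALSE]
    hit <- pairs$drug %in% drugs & pairs$gene %in% g$gene
    if (!any(hit)) return(NULL)
    data.frame(sample = id, drug = pairs$drug[hit], gene = pairs$gene[hit],
               phenotype = g$phenotype[match(pairs$gene[hit], g$gene)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame(
    sample = character(0), drug = character(0), gene = character(0),
    phenotype = character(0))
}

#' Cohort-level medication and interaction summary
#'
#' Percentages use individuals with non-missing medication data as the
#' denominator; the high-risk interaction fraction is additionally
#' reported against the subset actually taking a level 1A drug, since both
#' denominators appear in practice. Also returns the per-gene rows
#' (fraction taking a paired drug; fraction taking one while at high
#' risk), the median/IQR drug count, and the polypharmacy fraction
#' (5+ drugs).
#'
#' @param medications Medication table (`id`, `drugs`, `missing`).
#' @param annotations Risk annotations from [annotate_risk()].
#' @param pairs A `pgx_drug_gene_pairs` table.
#' @param synonyms Optional synonym map.
#' @return List of class `pgx_interaction_summary`.
#' @export
cohort_interaction_summary <- function(medications, annotations, pairs,
                                       synonyms = NULL) {
  if (!nrow(medications)) stop_pgx("empty cohort")
  reporting <- medications[!medications$missing, , drop = FALSE]
  n_rep <- nrow(reporting)
  if (!n_rep) stop_pgx("no individuals with medication data")
  taken <- split_drugs(reporting$drugs, synonyms)
  names(taken) <- reporting$id
  drug_counts <- lengths(taken)
  level1a <- unique(pairs$drug)
  takes_any <- vapply(taken, function(d) any(d %in% level1a), logical(1))
  flags <- flag_interactions(medications, annotations, pairs, synonyms)
  n_flags <- table(factor(flags$sample, levels = reporting$id))
  per_gene <- do.call(rbind, lapply(split(pairs, pairs$gene), function(p) {
    gene <- p$gene[1]
    takes <- vapply(taken, function(d) any(d %in% p$drug), logical(1))
    at_risk <- reporting$id %in% flags$sample[flags$gene == gene]
    data.frame(gene = gene,
               n_taking = sum(takes),
               pct_taking = pct(sum(takes), n_rep),
               n_taking_high_risk = sum(at_risk),
               pct_taking_high_risk = pct(sum(at_risk), n_rep),
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  structure(list(
    n = nrow(medications),
    n_reporting = n_rep,
    pct_taking_any_level1a = pct(sum(takes_any), n_rep),
    pct_with_interaction = pct(sum(n_flags >= 1), n_rep),
    pct_with_interaction_among_users =
      if (any(takes_any)) pct(sum(n_flags >= 1), sum(takes_any))
      else 0,
    pct_with_multiple_interactions = pct(sum(n_flags > 1), n_rep),
    median_drug_count = stats::median(drug_counts),
    drug_count_iqr = unname(stats::quantile(drug_counts, c(0.25, 0.75),
                                            type = 1)),
    pct_polypharmacy = pct(sum(drug_counts >= 5), n_rep),
    per_gene = per_gene
  ), class = "pgx_interaction_summary")
}

#' @method print pgx_interaction_summary
#' @export
print.pgx_interaction_summary <- function(x, ...) {
  cat(sprintf(
    "Medication summary: %d individuals (%d reporting)\n", x$n,
    x$n_reporting))
  cat(sprintf("  taking >=1 level 1A drug:        %.1f%%\n",
              x$pct_taking_any_level1a))
  cat(sprintf("  >=1 high-risk interaction:       %.1f%% (%.1f%% of users)\n",
              x$pct_with_interaction, x$pct_with_interaction_among_users))
  cat(sprintf("  >1 high-risk interaction:        %.1f%%\n",
              x$pct_with_multiple_interactions))
  cat(sprintf("  median drugs %s (IQR %s-%s); >=5 drugs: %.1f%%\n",
              x$median_drug_count, x$drug_count_iqr[1], x$drug_count_iqr[2],
              x$pct_polypharmacy))
  print(x$per_gene, row.names = FALSE)
  invisible(x)
}
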