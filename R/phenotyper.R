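# Diplotype -> predicted phenotype translation: table lookup for most
# genes, activity-score summation for CYP2D6, and the warfarin dose
# categories for CYP4F2 / VKORC1.

# CPIC consensus activity-score bins for CYP2D6.
cyp2d6_as_bins <- function(total) {
  if (total == 0) "Poor Metabolizer"
  else if (total < 1.25) "Intermediate Metabolizer"
  else if (total <= 2.25) "Normal Metabolizer"
  else "Ultrarapid Metabolizer"
}

assignment_row <- function(sample, gene, diplotype, phenotype, method,
                           activity_score_total = NA_real_) {
  data.frame(sample = sample, gene = gene, diplotype = diplotype,
             phenotype = phenotype, method = method,
             activity_score_total = activity_score_total,
             stringsAsFactors = FALSE)
}

#' CYP2D6 phenotype from the activity-score sum
#'
#' The diplotype's activity score is the sum over its two alleles, where an
#' `xN` duplication multiplies the base allele's score by N and composite
#' tandem alleles (e.g. `*68+*4`) carry their own score. Bins: 0 is a Poor
#' Metabolizer, (0, 1.25) Intermediate, [1.25, 2.25] Normal, above 2.25
#' Ultrarapid. Any allele with unknown activity score poisons the sum and
#' yields Indeterminate.
#'
#' @param sample Sample id (carried through to the output row).
#' @param allele1,allele2 Star-allele labels.
#' @param defs The CYP2D6 `pgx_allele_defs` table (or any table supplying
#'   activity scores for the labels used).
#' @return One-row assignment `data.frame`.
#' @export
cyp2d6_phenotype <- function(sample, allele1, allele2, defs) {
  known <- c(defs$alleles$allele, defs$deletion_allele)
  for (a in c(allele1, allele2)) {
    if (!parse_allele_label(a)$base %in% known) {
      stop_pgx("allele ", a, " has no activity-score entry for ", defs$gene)
    }
  }
  scores <- c(allele_activity_score(defs, allele1),
              allele_activity_score(defs, allele2))
  dip <- diplotype_string(allele1, allele2)
  if (anyNA(scores)) {
    return(assignment_row(sample, defs$gene, dip, "Indeterminate",
                          "activity_score"))
  }
  total <- sum(scores)
  assignment_row(sample, defs$gene, dip, cyp2d6_as_bins(total),
                 "activity_score", total)
}

#' Translate one diplotype through a translation table
#'
#' Unordered lookup; a pair absent from the table is assigned phenotype
#' `"Unknown"`, except for CYP2D6 where the activity-score sum is used as
#' the fallback (several CYP2D6 diplotypes are routinely missing from
#' published translation tables).
#'
#' @param sample Sample id.
#' @param gene Gene symbol.
#' @param allele1,allele2 Star-allele labels.
#' @param translation A `pgx_translation` object.
#' @param defs Optional `pgx_allele_defs` for the gene (required for the
#'   CYP2D6 fallback).
#' @return One-row assignment `data.frame` with columns `sample`, `gene`,
#'   `diplotype`, `phenotype`, `method`, `activity_score_total`.
#' @export
translate_diplotype <- function(sample, gene, allele1, allele2, translation,
                                defs = NULL) {
  hit <- lookup_phenotype(translation, gene, allele1, allele2)
  if (!is.na(hit)) {
    return(assignment_row(sample, gene, diplotype_string(allele1, allele2),
                          hit, "table"))
  }
  if (gene == "CYP2D6" && !is.null(defs)) {
    return(cyp2d6_phenotype(sample, allele1, allele2, defs))
  }
  assignment_row(sample, gene, diplotype_string(allele1, allele2),
                 "Unknown", "unknown")
}

#' Warfarin dose-category phenotypes for CYP4F2 and VKORC1
#'
#' Carriers of one or two copies of CYP4F2 `*3` are assigned the higher
#' warfarin dose category; carriers of one or two copies of VKORC1 `*2`
#' the decreased warfarin dose category. The two flags are independent.
#'
#' @param cyp4f2_diplotype,vkorc1_diplotype Character vectors of length 2
#'   (the two allele labels).
#' @return Named character vector
#'   `c(CYP4F2 = ..., VKORC1 = ...)` with values among
#'   "Higher Warfarin Dose", "Decreased Warfarin Dose",
#'   "Normal Warfarin Dose".
#' @export
warfarin_phenotype <- function(cyp4f2_diplotype, vkorc1_diplotype) {
  carries <- function(dip, allele) {
    any(vapply(dip, function(a) parse_allele_label(a)$base, "") == allele)
  }
  c(CYP4F2 = if (carries(cyp4f2_diplotype, "*3")) "Higher Warfarin Dose"
             else "Normal Warfarin Dose",
    VKORC1 = if (carries(vkorc1_diplotype, "*2")) "Decreased Warfarin Dose"
             else "Normal Warfarin Dose")
}

warfarin_gene_phenotype <- function(gene, allele1, allele2) {
  dip <- c(allele1, allele2)
  if (gene == "CYP4F2") warfarin_phenotype(dip, "*1")[["CYP4F2"]]
  else warfarin_phenotype("*1", dip)[["VKORC1"]]
}

#' Phenotype a whole cohort of diplotype calls
#'
#' One assignment per (sample, gene). CYP4F2 and VKORC1 use the warfarin
#' dose rules; CYP2D6 falls back to the activity-score sum when its
#' diplotype is not in the translation table; all other genes are
#' table-translated with `"Unknown"` as the miss value.
#'
#' @param calls Diplotype call table from [call_cohort()] (columns
#'   `sample`, `gene`, `allele1`, `allele2`).
#' @param translation A `pgx_translation`.
#' @param defs A `pgx_allele_def_set` covering all called genes.
#' @return `data.frame` of assignments.
#' @export
phenotype_cohort <- function(calls, translation, defs) {
  missing_defs <- setdiff(unique(calls$gene), names(defs))
  if (length(missing_defs)) {
    stop_pgx("no allele definitions for called gene(s): ",
             paste(missing_defs, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    gene <- calls$gene[i]
    a1 <- calls$allele1[i]; a2 <- calls$allele2[i]
    if (gene %in% c("CYP4F2", "VKORC1")) {
      assignment_row(calls$sample[i], gene, diplotype_string(a1, a2),
                     warfarin_gene_phenotype(gene, a1, a2), "warfarin_rule")
    } else {
      translate_diplotype(calls$sample[i], gene, a1, a2, translation,
                          defs[[gene]])
    }
  })
  do.call(rbind, rows) %||% assignment_row(character(0), character(0),
                                           character(0), character(0),
                                           character(0), numeric(0))
}
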