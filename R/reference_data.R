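# Reference tables: star-allele definitions, diplotype-phenotype translation
# tables, EHR priority risk notation, and PharmGKB level 1A drug-gene pairs.
# Loaders validate TSV inputs; constructors let users build tables in code.

PHENOTYPE_VOCABULARY <- c(
  "Ultrarapid Metabolizer", "Rapid Metabolizer", "Normal Metabolizer",
  "Intermediate Metabolizer", "Poor Metabolizer",
  "Increased Function", "Normal Function", "Decreased Function",
  "Poor Function", "Indeterminate", "Unknown",
  "Higher Warfarin Dose", "Decreased Warfarin Dose", "Normal Warfarin Dose"
)

# Function class is derived from the activity score, never stored, so the
# two can't disagree: 0 -> loss, (0,1) -> decreased, 1 -> normal,
# > 1 -> increased, NA -> unknown.
function_class_from_as <- function(activity_score) {
  vapply(activity_score, function(as) {
    if (is.na(as)) return("unknown")
    if (as == 0) return("loss")
    if (as < 1) return("decreased")
    if (as == 1) return("normal")
    "increased"
  }, character(1))
}

#' Build a star-allele definition table for one gene
#'
#' @param gene Gene symbol.
#' @param alleles `data.frame` with columns `allele`, `chrom`, `pos`, `ref`,
#'   `alt`, `rsid`, `activity_score`; one row per defining variant, repeated
#'   rows for multi-variant alleles. The reference allele `*1` appears as a
#'   single row with empty variant fields. Deletion alleles (`*DEL`, or `*5`
#'   for CYP2D6) and composite/tandem alleles (names containing `+`) carry
#'   no defining variants; composites hold their own activity score and are
#'   legal in translation input but are never called from variant data.
#' @param region Optional list `(chrom, start, end)` (hg19). Defaults to the
#'   built-in registry; for unregistered genes it is inferred as the variant
#'   span padded by 1 kb.
#' @param deletion_allele Label used for whole-gene deletion haplotypes.
#'   Defaults to `"*5"` for CYP2D6 and `"*DEL"` otherwise.
#' @return An object of class `pgx_allele_defs`.
#' @export
allele_definitions <- function(gene, alleles, region = NULL,
                               deletion_allele = NULL) {
  stopifnot(is.character(gene), length(gene) == 1L)
  req <- c("allele", "chrom", "pos", "ref", "alt", "rsid", "activity_score")
  missing_cols <- setdiff(req, names(alleles))
  if (length(missing_cols)) {
    stop_pgx("allele definition table for ", gene,
             " lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  alleles$allele <- as.character(alleles$allele)
  alleles$pos <- suppressWarnings(as.integer(alleles$pos))
  has_var <- !is.na(alleles$pos) & nzchar(trimws(as.character(alleles$chrom)))

  deletion_allele <- deletion_allele %||%
    if (gene == "CYP2D6") "*5" else "*DEL"

  allele_order <- unique(alleles$allele)
  if (!"*1" %in% allele_order) {
    stop_pgx("gene ", gene, ": missing reference allele *1")
  }

  # per-allele defining variant sets, duplicate detection
  variants <- list()
  as_map <- numeric(0)
  for (name in allele_order) {
    rows <- alleles[alleles$allele == name, , drop = FALSE]
    vr <- rows[has_var[alleles$allele == name], , drop = FALSE]
    keys <- if (nrow(vr)) {
      variant_key(vr$chrom, vr$pos, vr$ref, vr$alt)
    } else character(0)
    if (anyDuplicated(keys) || (nrow(rows) > 1L && !nrow(vr))) {
      stop_pgx("gene ", gene, ": allele ", name, " defined more than once")
    }
    if (length(keys) && (name == "*1" || name == deletion_allele ||
                         is_composite_allele(name))) {
      stop_pgx("gene ", gene, ": allele ", name,
               " must not carry defining variants")
    }
    as_vals <- unique(rows$activity_score[!is.na(rows$activity_score)])
    if (length(as_vals) > 1L) {
      stop_pgx("gene ", gene, ": allele ", name,
               " has conflicting activity scores")
    }
    variants[[name]] <- keys
    as_map[name] <- if (length(as_vals)) as_vals else NA_real_
  }

  vr <- alleles[has_var, , drop = FALSE]
  if (nrow(vr)) {
    if (any(vr$ref == vr$alt)) {
      stop_pgx("gene ", gene, ": variant with ref == alt")
    }
    # same site listed under two alleles is fine (e.g. SLCO1B1 *5 vs *15),
    # but a key must map to a single rsid
    key <- variant_key(vr$chrom, vr$pos, vr$ref, vr$alt)
    if (any(tapply(as.character(vr$rsid), key,
                   function(x) length(unique(x))) > 1L)) {
      stop_pgx("gene ", gene, ": one variant listed under multiple rsIDs")
    }
  }

  region <- region %||% pgx_gene_region(gene)
  if (is.null(region)) {
    if (!nrow(vr)) {
      stop_pgx("gene ", gene, ": no registered region and no variants ",
               "to infer one from")
    }
    region <- list(chrom = normalize_chrom(vr$chrom[1]),
                   start = min(vr$pos) - 1000L, end = max(vr$pos) + 1000L)
  }
  region$chrom <- normalize_chrom(region$chrom)
  if (nrow(vr)) {
    chrom <- normalize_chrom(vr$chrom)
    bad <- chrom != region$chrom | vr$pos < region$start | vr$pos > region$end
    if (any(bad)) {
      stop_pgx("gene ", gene, ": defining variant(s) outside the gene ",
               "region: ", paste(unique(vr$rsid[bad]), collapse = ", "))
    }
  }
  if (!identical(variants[["*1"]], character(0))) {
    stop_pgx("gene ", gene, ": reference allele *1 must have an empty ",
             "defining-variant set")
  }
  if (!is.na(as_map[["*1"]]) && as_map[["*1"]] != 1.0) {
    stop_pgx("gene ", gene, ": reference allele *1 must have activity ",
             "score 1.0")
  }
  as_map[["*1"]] <- 1.0

  variant_info <- if (nrow(vr)) {
    info <- unique(data.frame(
      key = variant_key(vr$chrom, vr$pos, vr$ref, vr$alt),
      chrom = normalize_chrom(vr$chrom), pos = vr$pos,
      ref = as.character(vr$ref), alt = as.character(vr$alt),
      rsid = as.character(vr$rsid), stringsAsFactors = FALSE))
    info[order(info$pos, info$alt), , drop = FALSE]
  } else {
    data.frame(key = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), rsid = character(0))
  }

  structure(list(
    gene = gene,
    alleles = data.frame(
      allele = allele_order,
      activity_score = unname(as_map[allele_order]),
      function_class = function_class_from_as(unname(as_map[allele_order])),
      n_defining = vapply(variants[allele_order], length, integer(1)),
      stringsAsFactors = FALSE),
    variants = variants,
    variant_info = variant_info,
    region = region,
    deletion_allele = deletion_allele
  ), class = "pgx_allele_defs")
}

#' @method print pgx_allele_defs
#' @export
print.pgx_allele_defs <- function(x, ...) {
  cat("Star-allele definitions for", x$gene,
      sprintf("(%s:%d-%d, hg19)\n", x$region$chrom, x$region$start,
              x$region$end))
  print(x$alleles, row.names = FALSE)
  invisible(x)
}

#' Activity score lookup
#'
#' Activity score of a star allele, honouring `xN` copy multipliers
#' (`*1x2` scores twice `*1`); unknown alleles return `NA`.
#'
#' @param defs A `pgx_allele_defs` table.
#' @param label Allele label.
#' @return Numeric score or `NA`.
#' @export
allele_activity_score <- function(defs, label) {
  parsed <- parse_allele_label(label)
  i <- match(parsed$base, defs$alleles$allele)
  if (is.na(i)) {
    # whole-gene deletion scores 0 even when not listed as a table row
    if (parsed$base == defs$deletion_allele) return(0)
    return(NA_real_)
  }
  defs$alleles$activity_score[i] * parsed$mult
}

read_tsv <- function(path, required) {
  if (!file.exists(path)) stop_pgx("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "#", blank.lines.skip = TRUE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_pgx(basename(path), ": missing column(s) ",
             paste(missing_cols, collapse = ", "))
  }
  df
}

#' Load star-allele definition tables
#'
#' Reads a tab-separated allele definition file (columns `gene`, `allele`,
#' `chrom`, `pos`, `ref`, `alt`, `rsid`, `activity_score`; one variant per
#' row, repeated rows for multi-variant alleles, `pos` 1-based hg19) and
#' validates each gene's table. File order of alleles is preserved and used
#' as the tie-break in haplotype matching.
#'
#' @param path Path to the TSV.
#' @return A named list of `pgx_allele_defs` tables (class
#'   `pgx_allele_def_set`), one per gene.
#' @export
load_allele_definitions <- function(path) {
  df <- read_tsv(path, c("gene", "allele", "chrom", "pos", "ref", "alt",
                         "rsid", "activity_score"))
  df$activity_score <- suppressWarnings(as.numeric(df$activity_score))
  out <- lapply(split(df, factor(df$gene, levels = unique(df$gene))),
                function(g) allele_definitions(g$gene[1], g))
  structure(out, class = "pgx_allele_def_set")
}

#' @method print pgx_allele_def_set
#' @export
print.pgx_allele_def_set <- function(x, ...) {
  cat("Allele definition bundle:", length(x), "gene(s):",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Load diplotype-phenotype translation tables
#'
#' Reads a TSV with columns `gene`, `allele1`, `allele2`, `phenotype`.
#' Lookup is symmetric in allele order; a pair listed twice with different
#' phenotypes is a validation error.
#'
#' @param path Path to the TSV.
#' @return Object of class `pgx_translation`.
#' @export
load_translation_table <- function(path) {
  df <- read_tsv(path, c("gene", "allele1", "allele2", "phenotype"))
  df$phenotype <- trimws(df$phenotype)
  bad <- !collapse_phenotype(df$phenotype) %in% PHENOTYPE_VOCABULARY
  if (any(bad)) {
    stop_pgx("translation table: phenotype label(s) outside the controlled ",
             "vocabulary: ", paste(unique(df$phenotype[bad]), collapse = ", "))
  }
  keys <- pair_key(df$gene, df$allele1, df$allele2)
  conflict <- tapply(df$phenotype, keys, function(x) length(unique(x)) > 1L)
  if (any(conflict)) {
    stop_pgx("translation table: conflicting phenotype for pair(s) ",
             paste(names(conflict)[conflict], collapse = "; "))
  }
  dup <- duplicated(keys)
  df <- df[!dup, , drop = FALSE]
  map <- stats::setNames(df$phenotype, pair_key(df$gene, df$allele1,
                                                df$allele2))
  structure(list(map = map, genes = unique(df$gene), entries = df),
            class = "pgx_translation")
}

#' @method print pgx_translation
#' @export
print.pgx_translation <- function(x, ...) {
  cat("Diplotype-phenotype translation:", length(x$map), "pairs across",
      length(x$genes), "gene(s)\n")
  invisible(x)
}

#' Symmetric diplotype lookup
#'
#' @param translation A `pgx_translation` object.
#' @param gene Gene symbol.
#' @param allele1,allele2 Star-allele labels (order irrelevant).
#' @return Phenotype label, or `NA` when the pair is not listed.
#' @export
lookup_phenotype <- function(translation, gene, allele1, allele2) {
  unname(translation$map[pair_key(gene, allele1, allele2)])
}

check_known_genes <- function(genes, what) {
  unknown <- setdiff(unique(genes), names(.pgx_gene_regions))
  if (length(unknown)) {
    stop_pgx(what, ": unknown gene symbol(s): ",
             paste(unknown, collapse = ", "))
  }
}

#' Load the EHR priority risk table
#'
#' TSV columns: `gene`, `phenotype`, `high_risk` (0/1), `priority_label`.
#' A phenotype is "high-risk" when its EHR Priority Result Notation flags an
#' abnormal/actionable result for the gene.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of class `pgx_risk_table`.
#' @export
load_ehr_risk_table <- function(path) {
  df <- read_tsv(path, c("gene", "phenotype", "high_risk", "priority_label"))
  check_known_genes(df$gene, "EHR risk table")
  bad <- !collapse_phenotype(df$phenotype) %in% PHENOTYPE_VOCABULARY
  if (any(bad)) {
    stop_pgx("EHR risk table: phenotype label(s) outside the controlled ",
             "vocabulary: ", paste(unique(df$phenotype[bad]), collapse = ", "))
  }
  df$high_risk <- as.integer(df$high_risk) == 1L
  class(df) <- c("pgx_risk_table", "data.frame")
  df
}

#' High-risk phenotypes for a gene
#' @param risk A `pgx_risk_table`.
#' @param gene Gene symbol.
#' @return Character vector of phenotype labels flagged high-risk.
#' @export
high_risk_phenotypes <- function(risk, gene) {
  risk$phenotype[risk$gene == gene & risk$high_risk]
}

#' Load PharmGKB evidence level 1A drug-gene pairs
#'
#' TSV columns: `drug`, `gene`, `level`. Drug names are normalized to
#' lower case; `(drug, gene)` must be unique.
#'
#' @param path Path to the TSV.
#' @return `data.frame` of class `pgx_drug_gene_pairs`.
#' @export
load_drug_gene_pairs <- function(path) {
  df <- read_tsv(path, c("drug", "gene", "level"))
  df$drug <- tolower(trimws(df$drug))
  check_known_genes(df$gene, "drug-gene pair list")
  if (anyDuplicated(paste(df$drug, df$gene))) {
    stop_pgx("drug-gene pair list: duplicated (drug, gene) pair")
  }
  class(df) <- c("pgx_drug_gene_pairs", "data.frame")
  df
}

#' Load a drug synonym map (brand name to generic)
#'
#' TSV columns: `synonym`, `drug`. Both sides are lower-cased.
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping synonym to generic name.
#' @export
load_drug_synonyms <- function(path) {
  df <- read_tsv(path, c("synonym", "drug"))
  stats::setNames(tolower(trimws(df$drug)), tolower(trimws(df$synonym)))
}

#' Normalize drug names
#'
#' Lower-cases, trims, and applies the synonym map. Names with no synonym
#' entry pass through unchanged (they simply never match a level 1A pair).
#'
#' @param drugs Character vector of drug names.
#' @param synonyms Optional named vector from [load_drug_synonyms()].
#' @return Character vector of normalized names.
#' @export
normalize_drug_names <- function(drugs, synonyms = NULL) {
  x <- tolower(trimws(drugs))
  if (!is.null(synonyms)) {
    hit <- x %in% names(synonyms)
    x[hit] <- unname(synonyms[x[hit]])
  }
  x
}

#' Path to a shipped reference fixture
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available fixtures.
#' @return Absolute path (or vector of file names).
#' @export
pgx_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pgxcohort")))
  }
  path <- system.file("extdata", file, package = "pgxcohort")
  if (!nzchar(path)) stop_pgx("no fixture named ", file)
  path
}

#' Load the shipped reference bundle
#'
#' Curated minimal subset (2-6 alleles per gene) of allele definitions,
#' translation tables, EHR risk notation, level 1A drug-gene pairs and drug
#' synonyms for the eleven genes the pipeline covers end-to-end: the nine
#' PharmGKB level 1A genes (CYP2B6, CYP2C9, CYP2C19, CYP2D6, CYP3A5,
#' NUDT15, SLCO1B1, TPMT, UGT1A1) plus the warfarin genes CYP4F2 and
#' VKORC1. Full-size tables in the same formats load through the same
#' functions.
#'
#' @param dir Directory holding the TSVs; defaults to the installed
#'   fixtures.
#' @return List with elements `defs`, `translation`, `risk`, `pairs`,
#'   `synonyms`.
#' @export
load_reference_bundle <- function(dir = system.file("extdata",
                                                    package = "pgxcohort")) {
  list(
    defs = load_allele_definitions(file.path(dir, "allele_definitions.tsv")),
    translation = load_translation_table(file.path(dir,
                                                   "translation_tables.tsv")),
    risk = load_ehr_risk_table(file.path(dir, "ehr_risk.tsv")),
    pairs = load_drug_gene_pairs(file.path(dir, "drug_gene_pairs.tsv")),
    synonyms = load_drug_synonyms(file.path(dir, "drug_synonyms.tsv"))
  )
}
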