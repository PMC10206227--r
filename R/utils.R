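# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# hg19 regions for the genes the fixture bundle and scan helpers know about.
# Coordinates bracket the gene body plus proximal regulatory sites used by
# star-allele definitions (e.g. CYP2C19*17, SLCO1B1*17 promoter variants).
.pgx_gene_regions <- list(
  CYP2B6  = list(chrom = "chr19", start = 41497204,  end = 41524301),
  CYP2C9  = list(chrom = "chr10", start = 96698415,  end = 96749148),
  CYP2C19 = list(chrom = "chr10", start = 96521000,  end = 96612671),
  CYP2D6  = list(chrom = "chr22", start = 42522500,  end = 42526883),
  CYP3A5  = list(chrom = "chr7",  start = 99245813,  end = 99277621),
  NUDT15  = list(chrom = "chr13", start = 48611702,  end = 48621358),
  SLCO1B1 = list(chrom = "chr12", start = 21284127,  end = 21392730),
  TPMT    = list(chrom = "chr6",  start = 18128542,  end = 18155374),
  UGT1A1  = list(chrom = "chr2",  start = 234668570, end = 234681945),
  CYP4F2  = list(chrom = "chr19", start = 15988833,  end = 16008884),
  VKORC1  = list(chrom = "chr16", start = 31102163,  end = 31108301),
  GSTM1   = list(chrom = "chr1",  start = 110230418, end = 110236367),
  UGT2B17 = list(chrom = "chr4",  start = 69402902,  end = 69434245),
  DPYD    = list(chrom = "chr1",  start = 97543299,  end = 98386615),
  CFTR    = list(chrom = "chr7",  start = 117120016, end = 117308718),
  IFNL3   = list(chrom = "chr19", start = 39734665,  end = 39738646),
  RYR1    = list(chrom = "chr19", start = 38924331,  end = 39078204),
  CACNA1S = list(chrom = "chr1",  start = 201008639, end = 201081694)
)

#' Known gene regions
#'
#' Returns the hg19 region registered for a gene symbol, or `NULL` when the
#' gene is not in the built-in registry (user-built tables may supply their
#' own region).
#'
#' @param gene Gene symbol, e.g. `"CYP2D6"`.
#' @return A list with `chrom`, `start`, `end`, or `NULL`.
#' @export
pgx_gene_region <- function(gene) {
  .pgx_gene_regions[[gene]]
}

# "19" and "chr19" are both accepted; normalized to "chr19".
normalize_chrom <- function(chrom) {
  chrom <- trimws(as.character(chrom))
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

# Variant keys are strings "chrom:pos:ref:alt" (chrom normalized, pos 1-based
# hg19); haplotypes and defining-variant sets are character vectors of keys.
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos), ref, alt, sep = ":")
}

split_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# Percentages printed in cohort tables: half-up to one decimal.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

pct <- function(count, n, digits = 1) {
  round_half_up(100 * count / n, digits)
}

# --- star-allele label handling -------------------------------------------

# Parse "*4x2" into base "*4" and multiplier 2; composites ("*68+*4") and
# deletion labels ("*DEL", "*5") pass through with multiplier 1.
parse_allele_label <- function(label) {
  m <- regmatches(label, regexec("^(.*)x([0-9]+)$", label))[[1]]
  if (length(m) == 3L && !grepl("[+]", m[2])) {
    list(base = m[2], mult = as.integer(m[3]))
  } else {
    list(base = label, mult = 1L)
  }
}

is_composite_allele <- function(label) {
  grepl("+", label, fixed = TRUE)
}

# Sort key: numeric star number first (non-numeric labels such as *DEL sort
# last), then multiplier, then the label itself for full determinism.
allele_sort_key <- function(labels) {
  num <- vapply(labels, function(l) {
    m <- regmatches(l, regexec("^\\*([0-9]+)", l))[[1]]
    if (length(m) == 2L) as.numeric(m[2]) else Inf
  }, numeric(1))
  mult <- vapply(labels, function(l) parse_allele_label(l)$mult, integer(1))
  order(num, mult, labels)
}

#' Canonical diplotype rendering
#'
#' Renders an unordered allele pair with the numerically lower star allele
#' first (`*1/*4`, not `*4/*1`); non-numeric labels such as `*DEL` sort last.
#'
#' @param allele1,allele2 Star-allele labels.
#' @return Character vector `c(lo, hi)`.
#' @export
sort_diplotype <- function(allele1, allele2) {
  c(allele1, allele2)[allele_sort_key(c(allele1, allele2))]
}

diplotype_string <- function(allele1, allele2) {
  paste(sort_diplotype(allele1, allele2), collapse = "/")
}

# Unordered lookup key for translation tables (vectorized).
pair_key <- function(gene, allele1, allele2) {
  paste(gene, pmin(allele1, allele2), pmax(allele1, allele2), sep = "|")
}

# Number of gene copies contributed by one haplotype label.
haplotype_copies <- function(label, deletion_allele) {
  if (label == deletion_allele) return(0L)
  parse_allele_label(label)$mult
}

# "Likely X" / "Possible X" phenotype qualifiers collapse onto their base
# phenotype for risk matching (the EHR notation groups them).
collapse_phenotype <- function(phenotype) {
  sub("^(Likely|Possible)\\s+", "", phenotype)
}

stop_pgx <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
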