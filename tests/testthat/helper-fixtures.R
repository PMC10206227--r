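# Shared fixtures: the shipped reference bundle (loaded once), small toy
# tables built in code, and independent brute-force oracles.

.bundle_cache <- new.env(parent = emptyenv())

ref_bundle <- function() {
  if (is.null(.bundle_cache$bundle)) {
    .bundle_cache$bundle <- load_reference_bundle()
  }
  .bundle_cache$bundle
}

# 3 non-reference alleles over a 4-variant site set; *B is a superset of
# *A, *C overlaps both. Used for exhaustive subset-matching checks.
toy_defs <- function() {
  allele_definitions("TOYGENE", data.frame(
    allele = c("*1", "*A", "*B", "*B", "*C", "*C"),
    chrom = "chr1",
    pos = c(NA, 100, 100, 200, 200, 300),
    ref = c("", "A", "A", "C", "C", "G"),
    alt = c("", "T", "T", "G", "G", "A"),
    rsid = c("", "rsV1", "rsV1", "rsV2", "rsV2", "rsV3"),
    activity_score = c(1, 0.5, 0, 0, 0.5, 0.5),
    stringsAsFactors = FALSE
  ), region = list(chrom = "chr1", start = 1, end = 1000))
}

toy_variant_keys <- function() {
  c(v1 = "chr1:100:A:T", v2 = "chr1:200:C:G", v3 = "chr1:300:G:A",
    v4 = "chr1:400:T:C")
}

# GSTM1-style table: reference allele plus a whole-gene deletion; a single
# tag variant so the gene has VCF presence.
gstm1_defs <- function() {
  allele_definitions("GSTM1", data.frame(
    allele = c("*1", "*B"),
    chrom = c(NA, "chr1"),
    pos = c(NA, 110231000),
    ref = c("", "G"),
    alt = c("", "A"),
    rsid = c("", "rsGSTM1B"),
    activity_score = c(1, 1),
    stringsAsFactors = FALSE
  ))
}

# Exhaustive-enumeration oracle for haplotype matching: scan every allele,
# keep those whose defining set is contained in the haplotype, take the
# largest (first listed wins ties), default to *1.
oracle_match <- function(hap, defs) {
  best <- "*1"
  best_size <- -1L
  for (a in defs$alleles$allele) {
    v <- defs$variants[[a]]
    if (length(v) > 0L && all(v %in% hap) && length(v) > best_size) {
      best <- a
      best_size <- length(v)
    }
  }
  best
}

# Brute-force cross-product oracle for interaction flagging.
oracle_flags <- function(medications, annotations, pairs, synonyms = NULL) {
  out <- list()
  for (i in seq_len(nrow(medications))) {
    if (medications$missing[i]) next
    drugs <- unique(normalize_drug_names(
      strsplit(medications$drugs[i], ";", fixed = TRUE)[[1]], synonyms))
    drugs <- drugs[nzchar(drugs)]
    for (d in drugs) {
      for (j in seq_len(nrow(pairs))) {
        if (pairs$drug[j] != d) next
        ann <- annotations[annotations$sample == medications$id[i] &
                             annotations$gene == pairs$gene[j], ]
        if (nrow(ann) && ann$high_risk[1]) {
          out[[length(out) + 1L]] <- data.frame(
            sample = medications$id[i], drug = d, gene = pairs$gene[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

# Simulate a cohort, write its VCF/depth, re-call, and merge calls with the
# stored truth (canonical diplotype strings on both sides).
simulate_and_call <- function(n, seed, refs = ref_bundle()) {
  cfg <- default_cohort_config(n = n, seed = seed)
  cohort <- sample_cohort(cfg, refs$defs)
  dir <- file.path(tempdir(), sprintf("rt_%d_%d", n, seed))
  paths <- write_cohort_files(cohort, refs$defs, dir)
  calls <- call_cohort(paths$vcf, paths$depth, refs$defs)
  truth <- cohort$diplotypes
  truth$true_dip <- vapply(seq_len(nrow(truth)), function(i) {
    paste(sort_diplotype(truth$allele1[i], truth$allele2[i]), collapse = "/")
  }, character(1))
  names(truth)[names(truth) == "id"] <- "sample"
  merged <- merge(calls, truth[c("sample", "gene", "allele1", "allele2",
                                 "true_dip")],
                  by = c("sample", "gene"), suffixes = c("", ".true"))
  del <- vapply(merged$gene, function(g) refs$defs[[g]]$deletion_allele, "")
  merged$true_copies <- vapply(seq_len(nrow(merged)), function(i) {
    pgxcohort:::haplotype_copies(merged$allele1.true[i], del[i]) +
      pgxcohort:::haplotype_copies(merged$allele2.true[i], del[i])
  }, integer(1))
  has_cn <- merged$true_copies != 2L |
    merged$allele1.true == del | merged$allele2.true == del
  # recovery is guaranteed for SNV/indel-defined diplotypes and whole-gene
  # CN 0/1/3 events; CN-neutral combinations like *DEL/*1x2 are not
  # identifiable from whole-gene depth
  merged$identifiable <- !has_cn | merged$true_copies %in% c(0L, 1L, 3L)
  unlink(dir, recursive = TRUE)
  merged
}

# Per-gene probability that a random HWE individual is high-risk, by exact
# enumeration over haplotype pairs (the closed-form side of the
# independence oracle for any_high_risk).
gene_high_risk_prob <- function(gene, freqs, refs) {
  haps <- names(freqs)
  p <- 0
  for (i in seq_along(haps)) {
    for (j in seq_along(haps)) {
      pair <- pgxcohort:::canonicalize_cn_pair(
        haps[i], haps[j], refs$defs[[gene]]$deletion_allele)
      phen <- if (gene %in% c("CYP4F2", "VKORC1")) {
        pgxcohort:::warfarin_gene_phenotype(gene, pair[1], pair[2])
      } else {
        translate_diplotype("x", gene, pair[1], pair[2], refs$translation,
                            refs$defs[[gene]])$phenotype
      }
      hr <- refs$risk$high_risk[refs$risk$gene == gene &
        refs$risk$phenotype == pgxcohort:::collapse_phenotype(phen)]
      if (length(hr) && hr[1]) p <- p + freqs[[i]] * freqs[[j]]
    }
  }
  p
}

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Minimal hand-written VCF builder for parser tests.
write_toy_vcf <- function(samples, records) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
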