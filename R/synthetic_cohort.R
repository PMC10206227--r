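# Synthetic cohort generator: per-gene diplotypes under Hardy-Weinberg (or
# direct diplotype frequencies), demographics, medication records, and the
# phased-VCF / read-depth files that carry the corresponding signal. Stands
# in for restricted population data so every downstream stage is testable
# against known truth.

#' Cohort simulation configuration
#'
#' @param n Number of individuals (>= 0).
#' @param seed Integer seed; every sampling function derives its stream from
#'   it, so the same config yields byte-identical outputs.
#' @param genes Named list. Each element is either a named numeric vector of
#'   haplotype frequencies (HWE mode: two haplotypes drawn independently) or
#'   a list `list(diplotypes = c("*1/*2" = p, ...))` drawing the unordered
#'   pair jointly. Frequencies must sum to 1 (tolerance 1e-9). Copy-number
#'   haplotypes are written `*DEL` (or `*5` for CYP2D6) and `*1x2`.
#' @param depth_mean Mean per-position read depth for a diploid (CN 2) gene.
#' @param depth_sd Gaussian noise sd on the depth scale.
#' @param depth_positions Depth positions emitted per gene.
#' @param drug_freqs Named vector of per-drug use probabilities (drawn
#'   independently per individual).
#' @param missing_medication_fraction Probability an individual has no
#'   medication data (flagged missing, excluded from medication
#'   denominators downstream).
#' @param polypharmacy_shape Optional gamma shape for a per-individual
#'   medication-propensity multiplier (mean 1; smaller shape = more
#'   between-individual spread, inflating polypharmacy). `NULL` disables it
#'   and drugs are fully independent.
#' @param sex_probs,race_probs Named probability vectors for demographics.
#' @param age_shape,age_scale Gamma parameters for age above 60 years (an
#'   elderly, census-sampled cohort).
#' @return Object of class `pgx_cohort_config`.
#' @export
cohort_config <- function(n, seed, genes,
                          depth_mean = 30, depth_sd = 3,
                          depth_positions = 16L,
                          drug_freqs = numeric(0),
                          missing_medication_fraction = 0,
                          polypharmacy_shape = NULL,
                          sex_probs = c(male = 0.365, female = 0.635),
                          race_probs = c(White = 0.581, Brown = 0.282,
                                         Black = 0.064, Yellow = 0.027,
                                         Others = 0.021, NoAnswer = 0.025),
                          age_shape = 1.5, age_scale = 9) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop_pgx("n must be a single non-negative count")
  }
  if (length(seed) != 1L || is.na(seed)) stop_pgx("seed is mandatory")
  check_freq_vector <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop_pgx(what, ": frequencies must be named")
    }
    if (any(p < 0 | p > 1)) stop_pgx(what, ": probabilities must be in [0,1]")
    if (abs(sum(p) - 1) > 1e-9) {
      stop_pgx(what, ": frequencies sum to ", format(sum(p)), ", not 1")
    }
  }
  for (gene in names(genes)) {
    g <- genes[[gene]]
    if (is.list(g)) {
      check_freq_vector(g$diplotypes, paste0(gene, " diplotype frequencies"))
    } else {
      check_freq_vector(g, paste0(gene, " haplotype frequencies"))
    }
  }
  if (length(drug_freqs) &&
      any(drug_freqs < 0 | drug_freqs > 1)) {
    stop_pgx("drug frequencies must be in [0,1]")
  }
  if (missing_medication_fraction < 0 || missing_medication_fraction > 1) {
    stop_pgx("missing_medication_fraction must be in [0,1]")
  }
  if (depth_mean <= 0) stop_pgx("depth_mean must be positive")
  check_freq_vector(sex_probs, "sex probabilities")
  check_freq_vector(race_probs, "color/race probabilities")
  structure(list(
    n = as.integer(n), seed = as.integer(seed), genes = genes,
    depth_mean = depth_mean, depth_sd = depth_sd,
    depth_positions = as.integer(depth_positions),
    drug_freqs = drug_freqs,
    missing_medication_fraction = missing_medication_fraction,
    polypharmacy_shape = polypharmacy_shape,
    sex_probs = sex_probs, race_probs = race_probs,
    age_shape = age_shape, age_scale = age_scale
  ), class = "pgx_cohort_config")
}

#' Default simulation scenario
#'
#' A ready-made configuration emulating a population cohort of elderly
#' Brazilian individuals: haplotype frequencies informed by published
#' Brazilian population estimates for the eleven bundled genes (e.g.
#' UGT1A1*28 0.329, VKORC1*2 0.331, CYP4F2*3 0.292, CYP3A5 loss alleles
#' ~0.82), outpatient drug-use frequencies led by simvastatin (0.201) and
#' omeprazole (0.195) plus common non-PGx fillers so total drug counts are
#' realistic, and a ~5% missing-medication fraction.
#'
#' @param n Cohort size; the emulated study size is 1171.
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A `pgx_cohort_config`.
#' @export
default_cohort_config <- function(n = 1171, seed = 1, ...) {
  genes <- list(
    CYP2B6  = c("*1" = 0.69, "*6" = 0.28, "*9" = 0.03),
    CYP2C9  = c("*1" = 0.835, "*2" = 0.113, "*3" = 0.052),
    CYP2C19 = c("*1" = 0.65, "*2" = 0.15, "*3" = 0.02, "*17" = 0.18),
    CYP2D6  = c("*1" = 0.455, "*2" = 0.20, "*4" = 0.12, "*10" = 0.08,
                "*41" = 0.09, "*5" = 0.03, "*1x2" = 0.015, "*2x2" = 0.01),
    CYP3A5  = c("*1" = 0.183, "*3" = 0.767, "*6" = 0.05),
    NUDT15  = c("*1" = 0.984, "*3" = 0.016),
    SLCO1B1 = c("*1" = 0.745, "*5" = 0.055, "*15" = 0.10, "*17" = 0.10),
    TPMT    = c("*1" = 0.956, "*2" = 0.004, "*3A" = 0.03, "*3C" = 0.01),
    UGT1A1  = c("*1" = 0.658, "*28" = 0.329, "*37" = 0.012, "*6" = 0.001),
    CYP4F2  = c("*1" = 0.708, "*3" = 0.292),
    VKORC1  = c("*1" = 0.669, "*2" = 0.331)
  )
  drug_freqs <- c(
    # PharmGKB level 1A drugs seen in elderly outpatient use
    simvastatin = 0.201, omeprazole = 0.195, amitriptyline = 0.033,
    sertraline = 0.023, ibuprofen = 0.022, warfarin = 0.014,
    citalopram = 0.012, clopidogrel = 0.012, metoprolol = 0.012,
    tramadol = 0.010, codeine = 0.008, phenytoin = 0.005,
    paroxetine = 0.005, meloxicam = 0.005, celecoxib = 0.003,
    efavirenz = 0.002, azathioprine = 0.002,
    # common non-PGx medication keeps total counts realistic
    losartan = 0.30, hydrochlorothiazide = 0.28, aspirin = 0.30,
    metformin = 0.22, enalapril = 0.20, atenolol = 0.15,
    levothyroxine = 0.10, furosemide = 0.10, glibenclamide = 0.08,
    amlodipine = 0.08, captopril = 0.10, insulin = 0.06,
    digoxin = 0.05, allopurinol = 0.05, prednisone = 0.04
  )
  cohort_config(n = n, seed = seed, genes = genes, drug_freqs = drug_freqs,
                missing_medication_fraction = 0.053, ...)
}

# Duplication placement is unidentifiable from whole-gene depth, so sampled
# truth is stored in the caller's canonical form: when total copies is 3 the
# x2 goes to the sole non-reference allele, otherwise to haplotype 1.
canonicalize_cn_pair <- function(a1, a2, deletion_allele) {
  copies <- c(haplotype_copies(a1, deletion_allele),
              haplotype_copies(a2, deletion_allele))
  if (sum(copies) != 3L) return(c(a1, a2))
  base <- c(parse_allele_label(a1)$base, parse_allele_label(a2)$base)
  nonref <- which(base != "*1")
  idx <- if (length(nonref) == 1L) nonref else 1L
  out <- base
  out[idx] <- paste0(base[idx], "x2")
  out
}

#' Sample a synthetic cohort
#'
#' Draws demographics and per-gene diplotypes. In HWE mode two haplotypes
#' are drawn independently per gene; in diplotype mode the unordered pair is
#' drawn jointly. Every sampled allele must exist in the matching
#' definition table.
#'
#' @param config A `pgx_cohort_config`.
#' @param defs A `pgx_allele_def_set` from [load_allele_definitions()].
#' @return Object of class `pgx_cohort`: list with `demographics` and
#'   `diplotypes` data frames and the `config`.
#' @export
sample_cohort <- function(config, defs) {
  stopifnot(inherits(config, "pgx_cohort_config"))
  for (gene in names(config$genes)) {
    if (!gene %in% names(defs)) {
      stop_pgx("gene ", gene, " has no allele definition table")
    }
    g <- config$genes[[gene]]
    alleles <- if (is.list(g)) {
      unique(unlist(strsplit(names(g$diplotypes), "/", fixed = TRUE)))
    } else names(g)
    known <- c(defs[[gene]]$alleles$allele, defs[[gene]]$deletion_allele)
    bases <- vapply(alleles, function(a) parse_allele_label(a)$base, "")
    if (!all(bases %in% known)) {
      stop_pgx("gene ", gene, ": allele(s) not in definitions: ",
               paste(alleles[!bases %in% known], collapse = ", "))
    }
  }
  set.seed(config$seed)
  n <- config$n
  ids <- sprintf("S%04d", seq_len(n))
  demographics <- data.frame(
    id = ids,
    sex = if (n) sample(names(config$sex_probs), n, replace = TRUE,
                        prob = config$sex_probs) else character(0),
    age = if (n) 60 + round(stats::rgamma(n, shape = config$age_shape,
                                          scale = config$age_scale))
          else numeric(0),
    color_race = if (n) sample(names(config$race_probs), n, replace = TRUE,
                               prob = config$race_probs) else character(0),
    stringsAsFactors = FALSE
  )
  dip_list <- lapply(names(config$genes), function(gene) {
    g <- config$genes[[gene]]
    del <- defs[[gene]]$deletion_allele
    if (is.list(g)) {
      pick <- sample(names(g$diplotypes), n, replace = TRUE,
                     prob = g$diplotypes)
      pair <- strsplit(pick, "/", fixed = TRUE)
      a1 <- vapply(pair, `[`, "", 1L)
      a2 <- vapply(pair, `[`, "", 2L)
    } else {
      hap <- sample(names(g), 2L * n, replace = TRUE, prob = g)
      a1 <- hap[seq_len(n)]
      a2 <- hap[n + seq_len(n)]
    }
    canon <- mapply(canonicalize_cn_pair, a1, a2,
                    MoreArgs = list(deletion_allele = del),
                    SIMPLIFY = TRUE, USE.NAMES = FALSE)
    if (n == 0L) canon <- matrix(character(0), nrow = 2)
    data.frame(id = ids, gene = rep(gene, n), allele1 = canon[1, ],
               allele2 = canon[2, ], stringsAsFactors = FALSE)
  })
  diplotypes <- do.call(rbind, dip_list) %||%
    data.frame(id = character(0), gene = character(0),
               allele1 = character(0), allele2 = character(0))
  structure(list(demographics = demographics, diplotypes = diplotypes,
                 medications = NULL, config = config),
            class = "pgx_cohort")
}

#' @method print pgx_cohort
#' @export
print.pgx_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$demographics), "individuals,",
      length(unique(x$diplotypes$gene)), "gene(s), seed",
      x$config$seed, "\n")
  if (!is.null(x$medications)) {
    cat("Medication records:", sum(!x$medications$missing),
        "present /", sum(x$medications$missing), "missing\n")
  }
  invisible(x)
}

# Variant keys carried by one haplotype label (base allele's defining set;
# deletion haplotypes carry none -- their signal lives in the depth file).
haplotype_variant_keys <- function(label, defs_gene) {
  base <- parse_allele_label(label)$base
  if (base == defs_gene$deletion_allele) return(character(0))
  if (is_composite_allele(base)) {
    stop_pgx("composite allele ", label, " cannot be emitted as phased ",
             "variants (no defining-variant set)")
  }
  defs_gene$variants[[base]] %||%
    stop_pgx("allele ", label, " not in definitions for ", defs_gene$gene)
}

#' Write the cohort's phased multi-sample VCF
#'
#' Haplotype 1 of each genotype carries the defining variants of
#' `allele1`, haplotype 2 those of `allele2` (`GT` written phased,
#' `a|b`). Deletion haplotypes emit reference calls only; composite alleles
#' are not emittable and raise an error.
#'
#' @param cohort A `pgx_cohort`.
#' @param defs A `pgx_allele_def_set`.
#' @param path Output file (plain-text VCF v4.2, hg19 coordinates).
#' @return `path`, invisibly.
#' @export
emit_phased_vcf <- function(cohort, defs, path) {
  genes <- unique(cohort$diplotypes$gene)
  ids <- cohort$demographics$id
  records <- list()
  for (gene in if (length(ids)) genes else character(0)) {
    dg <- defs[[gene]]
    info <- dg$variant_info
    if (!nrow(info)) next
    sub <- cohort$diplotypes[cohort$diplotypes$gene == gene, , drop = FALSE]
    hap1 <- lapply(sub$allele1, haplotype_variant_keys, defs_gene = dg)
    hap2 <- lapply(sub$allele2, haplotype_variant_keys, defs_gene = dg)
    names(hap1) <- names(hap2) <- sub$id
    gt <- vapply(seq_len(nrow(info)), function(i) {
      key <- info$key[i]
      a <- as.integer(vapply(hap1[ids], function(v) key %in% v, logical(1)))
      b <- as.integer(vapply(hap2[ids], function(v) key %in% v, logical(1)))
      paste0(a, "|", b)
    }, character(length(ids)))
    gt <- matrix(gt, nrow = length(ids))
    records[[gene]] <- data.frame(
      CHROM = info$chrom, POS = info$pos, ID = info$rsid, REF = info$ref,
      ALT = info$alt, stringsAsFactors = FALSE, check.names = FALSE,
      gt = I(t(gt)))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgxcohort synthetic cohort generator",
    "##reference=hg19",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- character(0)
  if (length(records)) {
    rec <- do.call(rbind, lapply(records, function(r) {
      data.frame(CHROM = r$CHROM, POS = r$POS, ID = r$ID, REF = r$REF,
                 ALT = r$ALT,
                 GT = apply(unclass(r$gt), 1, paste, collapse = "\t"),
                 stringsAsFactors = FALSE)
    }))
    rec <- rec[order(rec$CHROM, rec$POS, rec$ALT), , drop = FALSE]
    body <- paste(rec$CHROM, rec$POS, rec$ID, rec$REF, rec$ALT, ".", "PASS",
                  ".", "GT", rec$GT, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the cohort's per-position read-depth table
#'
#' Expected depth scales with total gene copy number: a diploid gene sits at
#' `depth_mean`, one deleted haplotype at 0.5x, homozygous deletion at ~0,
#' one duplicated haplotype at 1.5x, with Gaussian noise of sd `depth_sd`.
#' A control-gene block (gene `CONTROL`) at 1.0x is always present and is
#' the intrasample normalization baseline.
#'
#' @param cohort A `pgx_cohort`.
#' @param defs A `pgx_allele_def_set`.
#' @param config The generating `pgx_cohort_config` (depth parameters).
#' @param path Output TSV (columns `gene`, `chrom`, `pos`, one per sample).
#' @return `path`, invisibly.
#' @export
emit_depth <- function(cohort, defs, config, path) {
  stopifnot(config$depth_mean > 0)
  set.seed(config$seed + 1L)
  ids <- cohort$demographics$id
  genes <- unique(cohort$diplotypes$gene)
  npos <- config$depth_positions
  blocks <- lapply(genes, function(gene) {
    dg <- defs[[gene]]
    sub <- cohort$diplotypes[cohort$diplotypes$gene == gene, , drop = FALSE]
    copies <- vapply(seq_len(nrow(sub)), function(i) {
      haplotype_copies(sub$allele1[i], dg$deletion_allele) +
        haplotype_copies(sub$allele2[i], dg$deletion_allele)
    }, numeric(1))
    names(copies) <- sub$id
    pos <- unique(round(seq(dg$region$start, dg$region$end,
                            length.out = npos)))
    depth <- vapply(ids, function(s) {
      mu <- config$depth_mean * copies[[s]] / 2
      pmax(0, stats::rnorm(length(pos), mean = mu, sd = config$depth_sd))
    }, numeric(length(pos)))
    if (length(pos) == 1L) depth <- matrix(depth, nrow = 1L,
                                           dimnames = list(NULL, ids))
    cbind(data.frame(gene = gene, chrom = dg$region$chrom, pos = pos,
                     stringsAsFactors = FALSE),
          as.data.frame(depth, check.names = FALSE))
  })
  control <- cbind(
    data.frame(gene = "CONTROL", chrom = "control", pos = seq_len(npos),
               stringsAsFactors = FALSE),
    as.data.frame(vapply(ids, function(s) {
      pmax(0, stats::rnorm(npos, mean = config$depth_mean,
                           sd = config$depth_sd))
    }, numeric(npos)), check.names = FALSE))
  out <- do.call(rbind, c(blocks, list(control)))
  num <- vapply(out, is.numeric, logical(1))
  num[names(out) == "pos"] <- FALSE
  out[num] <- lapply(out[num], round, digits = 4)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach medication records to a cohort
#'
#' Each drug is drawn independently per individual at its configured
#' frequency (optionally modulated by a per-individual polypharmacy
#' multiplier); a configured fraction of individuals is flagged as having
#' no medication data at all.
#'
#' @param config A `pgx_cohort_config`.
#' @param cohort A `pgx_cohort`.
#' @return The cohort with a `medications` data frame (`id`, `drugs`
#'   semicolon-joined, `missing` logical).
#' @export
sample_medications <- function(config, cohort) {
  set.seed(config$seed + 2L)
  ids <- cohort$demographics$id
  n <- length(ids)
  freqs <- config$drug_freqs
  missing <- if (n) stats::runif(n) < config$missing_medication_fraction
             else logical(0)
  mult <- if (is.null(config$polypharmacy_shape)) rep(1, n) else
    stats::rgamma(n, shape = config$polypharmacy_shape,
                  rate = config$polypharmacy_shape)
  take <- if (length(freqs) && n) {
    u <- matrix(stats::runif(n * length(freqs)), nrow = n)
    u < outer(mult, freqs, function(m, f) pmin(1, m * f))
  } else matrix(logical(0), nrow = n, ncol = length(freqs))
  drugs <- vapply(seq_len(n), function(i) {
    if (missing[i]) "" else
      paste(names(freqs)[take[i, ]], collapse = ";")
  }, character(1))
  cohort$medications <- data.frame(id = ids, drugs = drugs,
                                   missing = missing,
                                   stringsAsFactors = FALSE)
  cohort
}

#' Write all cohort input files
#'
#' Emits the phased VCF, depth TSV, medications CSV and demographics CSV
#' for a sampled cohort into a directory.
#'
#' @param cohort A `pgx_cohort` (medications sampled if configured).
#' @param defs A `pgx_allele_def_set`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort_files <- function(cohort, defs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                depth = file.path(dir, "depth.tsv"),
                medications = file.path(dir, "medications.csv"),
                demographics = file.path(dir, "demographics.csv"))
  emit_phased_vcf(cohort, defs, paths$vcf)
  emit_depth(cohort, defs, cohort$config, paths$depth)
  meds <- cohort$medications %||%
    data.frame(id = cohort$demographics$id, drugs = "", missing = FALSE)
  meds$missing <- as.integer(meds$missing)
  utils::write.csv(meds, paths$medications, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$demographics, paths$demographics,
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}
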