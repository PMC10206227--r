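# Star-allele caller: phased-haplotype extraction from VCF, defining-variant
# matching (maximal-subset rule), whole-gene copy number from normalized
# depth, and per-sample diplotype calls combining both.

#' Read a multi-sample VCF
#'
#' Thin wrapper over `vcfR::read.vcfR` returning the site table (with
#' normalized chromosome labels and `chrom:pos:ref:alt` keys) and the raw
#' `GT` matrix. Genotypes are kept as strings; phasing is enforced later by
#' [extract_haplotypes()].
#'
#' @param path VCF file (plain text or bgzipped).
#' @return List with `sites` (data.frame `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `key`), `gt` (site x sample character matrix) and `samples`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # always a character matrix with the 8 fixed columns
  sites <- data.frame(
    chrom = normalize_chrom(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"],
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE)
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  samples <- setdiff(colnames(v@gt), "FORMAT") %||% character(0)
  gt <- if (nrow(sites) && length(samples)) {
    # duplicate IDs (same rsid at two alt alleles) break extract.gt rownames
    v@fix[, "ID"] <- as.character(seq_len(nrow(sites)))
    vcfR::extract.gt(v, element = "GT")
  } else {
    matrix(character(0), nrow = nrow(sites), ncol = length(samples),
           dimnames = list(NULL, samples))
  }
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(sites), dimnames = list(NULL, samples))
  }
  list(sites = sites, gt = gt, samples = samples)
}

#' Extract phased haplotypes for a gene region
#'
#' Haplotype k of a sample contains exactly the sites where allele k of the
#' phased genotype is non-reference. Unphased genotypes are refused, not
#' guessed: the caller requires upstream phasing.
#'
#' @param vcf A parsed VCF from [read_phased_vcf()].
#' @param gene_region List `(chrom, start, end)`.
#' @return Named list (one per sample) of `list(hap1, hap2)` character
#'   vectors of variant keys.
#' @export
extract_haplotypes <- function(vcf, gene_region) {
  chrom <- normalize_chrom(gene_region$chrom)
  in_region <- vcf$sites$chrom == chrom &
    vcf$sites$pos >= gene_region$start & vcf$sites$pos <= gene_region$end
  keys <- vcf$sites$key[in_region]
  out <- lapply(vcf$samples, function(s) {
    g <- vcf$gt[in_region, s]
    if (!length(keys)) return(list(hap1 = character(0),
                                   hap2 = character(0)))
    unphased <- grepl("/", g, fixed = TRUE)
    if (any(unphased)) {
      i <- which(unphased)[1]
      stop_pgx("unphased genotype for sample ", s, " at ", keys[i])
    }
    parts <- strsplit(g, "|", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    list(hap1 = keys[!is.na(a) & a != "0" & a != "."],
         hap2 = keys[!is.na(b) & b != "0" & b != "."])
  })
  stats::setNames(out, vcf$samples)
}

#' Read a gene-depth (GDF-like) table
#'
#' @param path TSV with columns `gene`, `chrom`, `pos` and one column per
#'   sample; rows with gene `CONTROL` are the control-region baseline.
#' @return `data.frame`.
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  missing_cols <- setdiff(c("gene", "chrom", "pos"), names(df))
  if (length(missing_cols)) {
    stop_pgx(basename(path), ": missing column(s) ",
             paste(missing_cols, collapse = ", "))
  }
  df
}

#' Intrasample depth normalization
#'
#' Divides a gene's per-position depth by the sample's mean control-region
#' depth, so a diploid (CN 2) gene has expected ratio 1.0.
#'
#' @param depth_profile Numeric per-position depths for the gene.
#' @param control_profile Numeric control-region depths for the same sample.
#' @return Per-position ratio profile.
#' @export
normalize_depth <- function(depth_profile, control_profile) {
  if (!length(control_profile) || mean(control_profile) <= 0) {
    stop_pgx("control coverage absent or zero; cannot normalize")
  }
  depth_profile / mean(control_profile)
}

#' Whole-gene copy number from a ratio profile
#'
#' `cn = clamp(round(2 * median(ratio)), 0, 3)`, rounding ties half away
#' from zero. The cap at 3 reflects the 0-3 copy range the caller supports;
#' per-segment changepoints (hybrid alleles) are out of scope.
#'
#' @param ratio_profile Per-position normalized ratios (>= 1 position).
#' @return List with `cn` (integer) and `mean_ratio` (median of profile).
#' @export
estimate_copy_number <- function(ratio_profile) {
  if (!length(ratio_profile)) stop_pgx("empty ratio profile")
  med <- stats::median(ratio_profile)
  cn <- as.integer(min(3, max(0, round_half_away(2 * med))))
  list(cn = cn, mean_ratio = med)
}

#' Match one phased haplotype to a star allele
#'
#' Candidates are alleles whose defining-variant set is contained in the
#' haplotype; the candidate with the most defining variants wins, ties
#' break by definition-table order. An empty haplotype (or no candidate)
#' is the reference allele. The `exact` flag records whether the winning
#' defining set equals the haplotype exactly; residual unmatched variants
#' demote the flag but never fail.
#'
#' @param hap Character vector of variant keys on the haplotype.
#' @param table A `pgx_allele_defs` table.
#' @return List with `allele` and `exact`.
#' @export
match_haplotype <- function(hap, table) {
  alleles <- table$alleles$allele
  is_cand <- vapply(alleles, function(a) {
    v <- table$variants[[a]]
    length(v) > 0L && all(v %in% hap)
  }, logical(1))
  cand <- alleles[is_cand]
  if (!length(cand)) {
    return(list(allele = "*1", exact = length(hap) == 0L))
  }
  sizes <- vapply(cand, function(a) length(table$variants[[a]]), integer(1))
  winner <- cand[which.max(sizes)]  # first max = earliest in table order
  list(allele = winner, exact = setequal(table$variants[[winner]], hap))
}

#' Combine matched haplotypes and copy number into a diplotype call
#'
#' CN 2 keeps both matched alleles; CN 0 is a homozygous whole-gene
#' deletion; at CN 1 the deletion allele replaces the haplotype carrying
#' fewer non-reference variants (tie: haplotype 2), since read-level
#' phasing of the deletion is not available from these inputs; at CN 3 the
#' `x2` duplication suffix goes to the non-reference matched allele when
#' exactly one haplotype is non-reference, otherwise to haplotype 1, and
#' the ambiguity is recorded by demoting that allele's exact flag.
#'
#' @param hap1,hap2 Variant-key vectors for the two phased haplotypes.
#' @param cn_call List from [estimate_copy_number()] (or an integer CN).
#' @param table A `pgx_allele_defs` table.
#' @return One-row `data.frame`: `allele1`, `allele2` (canonical order),
#'   `diplotype`, `cn`, `exact1`, `exact2`.
#' @export
call_diplotype <- function(hap1, hap2, cn_call, table) {
  cn <- if (is.list(cn_call)) cn_call$cn else as.integer(cn_call)
  if (is.na(cn) || cn < 0L || cn > 3L) {
    stop_pgx("copy number ", cn, " outside the supported range [0, 3]")
  }
  del <- table$deletion_allele
  m1 <- match_haplotype(hap1, table)
  m2 <- match_haplotype(hap2, table)
  alleles <- c(m1$allele, m2$allele)
  exact <- c(m1$exact, m2$exact)
  if (cn == 0L) {
    alleles <- c(del, del)
    exact <- c(length(hap1) == 0L, length(hap2) == 0L)
  } else if (cn == 1L) {
    drop_idx <- if (length(hap1) < length(hap2)) 1L else 2L
    alleles[drop_idx] <- del
    exact[drop_idx] <- length(list(hap1, hap2)[[drop_idx]]) == 0L
  } else if (cn == 3L) {
    nonref <- which(alleles != "*1")
    dup_idx <- if (length(nonref) == 1L) nonref else 1L
    alleles[dup_idx] <- paste0(alleles[dup_idx], "x2")
    if (length(nonref) != 1L) exact[dup_idx] <- FALSE
  }
  ord <- allele_sort_key(alleles)
  data.frame(allele1 = alleles[ord][1], allele2 = alleles[ord][2],
             diplotype = paste(alleles[ord], collapse = "/"),
             cn = cn, exact1 = exact[ord][1], exact2 = exact[ord][2],
             stringsAsFactors = FALSE)
}

#' Call diplotypes for a whole cohort
#'
#' Runs haplotype extraction, depth normalization, copy-number estimation
#' and diplotype calling for every gene in `defs` and every sample shared
#' by the VCF and the depth table. Genes without rows in the depth table
#' are treated as diploid (CN 2).
#'
#' @param vcf Path to a phased multi-sample VCF, or a parsed VCF from
#'   [read_phased_vcf()].
#' @param depth Path to a depth TSV, or a data frame from
#'   [read_depth_table()].
#' @param defs A `pgx_allele_def_set`.
#' @return `data.frame` with one row per (sample, gene): `sample`, `gene`,
#'   `allele1`, `allele2`, `diplotype`, `cn`, `mean_ratio`, `exact1`,
#'   `exact2`.
#' @export
call_cohort <- function(vcf, depth, defs) {
  if (is.character(vcf)) vcf <- read_phased_vcf(vcf)
  if (is.character(depth)) depth <- read_depth_table(depth)
  depth_samples <- setdiff(names(depth), c("gene", "chrom", "pos"))
  if (!setequal(vcf$samples, depth_samples)) {
    stop_pgx("sample mismatch between VCF and depth table; only in VCF: ",
             paste(setdiff(vcf$samples, depth_samples), collapse = ", "),
             "; only in depth: ",
             paste(setdiff(depth_samples, vcf$samples), collapse = ", "))
  }
  control <- depth[depth$gene == "CONTROL", depth_samples, drop = FALSE]
  rows <- list()
  for (gene in names(defs)) {
    dg <- defs[[gene]]
    haps <- extract_haplotypes(vcf, dg$region)
    gene_depth <- depth[depth$gene == gene, depth_samples, drop = FALSE]
    for (s in vcf$samples) {
      if (nrow(gene_depth)) {
        ratio <- normalize_depth(gene_depth[[s]], control[[s]])
        cn_call <- estimate_copy_number(ratio)
      } else {
        cn_call <- list(cn = 2L, mean_ratio = NA_real_)
      }
      call <- call_diplotype(haps[[s]]$hap1, haps[[s]]$hap2, cn_call, dg)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(sample = s, gene = gene, stringsAsFactors = FALSE),
        call, data.frame(mean_ratio = cn_call$mean_ratio))
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    sample = character(0), gene = character(0), allele1 = character(0),
    allele2 = character(0), diplotype = character(0), cn = integer(0),
    exact1 = logical(0), exact2 = logical(0), mean_ratio = numeric(0))
  out[c("sample", "gene", "allele1", "allele2", "diplotype", "cn",
        "mean_ratio", "exact1", "exact2")]
}
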