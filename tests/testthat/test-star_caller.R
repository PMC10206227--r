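test_that("phased haplotype extraction splits genotypes per haplotype", {
  region <- list(chrom = "chr1", start = 1, end = 1000)
  path <- write_toy_vcf(c("A", "B"), c(
    "chr1\t100\trs1\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t200\trs2\tC\tG\t.\tPASS\t.\tGT\t0|0\t1|0"))
  haps <- extract_haplotypes(read_phased_vcf(path), region)
  expect_identical(haps$A$hap1, character(0))
  expect_identical(haps$A$hap2, "chr1:100:A:T")
  expect_setequal(haps$B$hap1, c("chr1:100:A:T", "chr1:200:C:G"))
  expect_identical(haps$B$hap2, "chr1:100:A:T")

  unphased <- write_toy_vcf("A", "chr1\t100\trs1\tA\tT\t.\tPASS\t.\tGT\t0/1")
  expect_error(extract_haplotypes(read_phased_vcf(unphased), region),
               "unphased genotype for sample A at chr1:100:A:T")
})

test_that("haplotype extraction agrees with an independent per-allele scan", {
  set.seed(101)
  n_sites <- 10
  samples <- paste0("S", 1:6)
  gts <- matrix(sample(c("0|0", "0|1", "1|0", "1|1"),
                       n_sites * length(samples), replace = TRUE),
                nrow = n_sites)
  recs <- vapply(seq_len(n_sites), function(i) {
    paste(c("chr1", 100 + i, paste0("rs", i), "A", "T", ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  path <- write_toy_vcf(samples, recs)
  haps <- extract_haplotypes(read_phased_vcf(path),
                             list(chrom = "chr1", start = 1, end = 1000))
  keys <- sprintf("chr1:%d:A:T", 100 + seq_len(n_sites))
  for (j in seq_along(samples)) {
    left <- substr(gts[, j], 1, 1) == "1"
    right <- substr(gts[, j], 3, 3) == "1"
    expect_setequal(haps[[samples[j]]]$hap1, keys[left])
    expect_setequal(haps[[samples[j]]]$hap2, keys[right])
  }
})

test_that("depth normalization and copy-number estimation follow the ratio rule", {
  expect_equal(normalize_depth(rep(30, 5), rep(30, 8)), rep(1, 5))
  expect_equal(normalize_depth(rep(0, 5), rep(30, 8)), rep(0, 5))
  expect_error(normalize_depth(rep(30, 5), rep(0, 4)), "control")
  expect_equal(estimate_copy_number(rep(1.0, 4))$cn, 2L)
  expect_equal(estimate_copy_number(rep(0.02, 4))$cn, 0L)
  expect_equal(estimate_copy_number(rep(1.52, 4))$cn, 3L)
  expect_equal(estimate_copy_number(rep(0.5, 4))$cn, 1L)
  # 2 * 0.75 = 1.5 rounds half away from zero -> CN 2
  expect_equal(estimate_copy_number(rep(0.75, 4))$cn, 2L)
  # estimates are capped at 3 copies
  expect_equal(estimate_copy_number(rep(2.4, 4))$cn, 3L)
  expect_error(estimate_copy_number(numeric(0)), "empty")
})

test_that("haplotype matching picks the maximal defining subset", {
  refs <- ref_bundle()
  m <- match_haplotype("chr19:15990431:C:T", refs$defs$CYP4F2)
  expect_equal(m$allele, "*3")
  expect_true(m$exact)
  expect_equal(match_haplotype(character(0), refs$defs$CYP4F2)$allele, "*1")
  # residual unmatched variants demote the exact flag, never fail
  m <- match_haplotype(c("chr19:15990431:C:T", "chr19:15990500:G:A"),
                       refs$defs$CYP4F2)
  expect_equal(m$allele, "*3")
  expect_false(m$exact)
  # SLCO1B1 *15 (2 variants) beats its subset *5 (1 variant)
  m <- match_haplotype(c("chr12:21329738:A:G", "chr12:21331549:T:C"),
                       refs$defs$SLCO1B1)
  expect_equal(m$allele, "*15")
  expect_true(m$exact)
})

test_that("matching equals exhaustive enumeration on every subset of a toy table", {
  defs <- toy_defs()
  keys <- toy_variant_keys()
  for (mask in 0:15) {
    hap <- keys[bitwAnd(mask, 2^(0:3)) > 0]
    got <- match_haplotype(hap, defs)
    expect_equal(got$allele, oracle_match(hap, defs),
                 info = paste("subset", mask))
  }
})

test_that("matching is monotone under added variants", {
  defs <- toy_defs()
  keys <- toy_variant_keys()
  size_of <- function(a) {
    if (is.null(defs$variants[[a]])) 0L else length(defs$variants[[a]])
  }
  for (mask in 0:15) {
    hap <- keys[bitwAnd(mask, 2^(0:3)) > 0]
    before <- match_haplotype(hap, defs)$allele
    for (extra in setdiff(keys, hap)) {
      after <- match_haplotype(c(hap, extra), defs)$allele
      expect_gte(size_of(after), size_of(before))
    }
  }
})

test_that("diplotype calls combine matching with copy number", {
  gstm1 <- gstm1_defs()
  # homozygous whole-gene deletion
  call <- call_diplotype(character(0), character(0), list(cn = 0L), gstm1)
  expect_equal(call$diplotype, "*DEL/*DEL")
  # diploid all-reference
  call <- call_diplotype(character(0), character(0), list(cn = 2L), gstm1)
  expect_equal(call$diplotype, "*1/*1")
  # CN 1: the haplotype with fewer variants becomes the deletion (tie: hap 2)
  d6 <- ref_bundle()$defs$CYP2D6
  call <- call_diplotype("chr22:42524947:C:T", character(0),
                         list(cn = 1L), d6)
  expect_equal(call$diplotype, "*4/*5")
  call <- call_diplotype(character(0), character(0), list(cn = 1L), d6)
  expect_equal(call$diplotype, "*1/*5")
  # CN 3: duplication suffix lands on the sole non-reference haplotype
  call <- call_diplotype(character(0), "chr22:42524947:C:T",
                         list(cn = 3L), d6)
  expect_equal(call$diplotype, "*1/*4x2")
  # both non-reference: haplotype 1 is duplicated and flagged inexact
  call <- call_diplotype("chr22:42524947:C:T", "chr22:42526694:G:A",
                         list(cn = 3L), d6)
  expect_equal(call$diplotype, "*4x2/*10")
  expect_false(all(c(call$exact1, call$exact2)))
  expect_error(call_diplotype(character(0), character(0), list(cn = 4L),
                              d6), "outside the supported range")
})

test_that("cohort calling is complete, deterministic and order-invariant", {
  refs <- ref_bundle()
  cfg <- default_cohort_config(n = 20, seed = 13)
  coh <- sample_cohort(cfg, refs$defs)
  dir <- tempfile()
  paths <- write_cohort_files(coh, refs$defs, dir)
  calls <- call_cohort(paths$vcf, paths$depth, refs$defs)
  expect_equal(nrow(calls), 20L * length(refs$defs))
  expect_equal(anyDuplicated(paste(calls$sample, calls$gene)), 0L)

  # shuffled depth sample columns change nothing
  depth <- read_depth_table(paths$depth)
  shuffled <- depth[c("gene", "chrom", "pos",
                      sample(setdiff(names(depth),
                                     c("gene", "chrom", "pos"))))]
  expect_identical(call_cohort(paths$vcf, shuffled, refs$defs), calls)

  # shuffled VCF record order changes nothing
  lines <- readLines(paths$vcf)
  hdr <- grepl("^#", lines)
  set.seed(1)
  writeLines(c(lines[hdr], sample(lines[!hdr])), paths$vcf)
  expect_identical(call_cohort(paths$vcf, paths$depth, refs$defs), calls)

  # disjoint samples are reported
  depth2 <- depth
  names(depth2)[names(depth2) == "S0001"] <- "S9999"
  expect_error(call_cohort(paths$vcf, depth2, refs$defs),
               "only in VCF: S0001; only in depth: S9999")
})

test_that("the caller recovers simulated truth for identifiable diplotypes", {
  merged <- simulate_and_call(n = 200, seed = 31)
  idf <- merged[merged$identifiable, ]
  expect_gt(nrow(idf) / nrow(merged), 0.97)
  expect_identical(idf$diplotype, idf$true_dip)
})
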