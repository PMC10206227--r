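mk_assignments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = r[[1]], gene = r[[2]], phenotype = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("EHR risk annotation applies the per-gene priority rules", {
  refs <- ref_bundle()
  ann <- annotate_risk(mk_assignments(
    list("A", "CYP2C19", "Rapid Metabolizer"),
    list("A", "CYP2C19", "Normal Metabolizer"),
    list("A", "TPMT", "Indeterminate"),
    list("A", "CYP3A5", "Normal Metabolizer"),
    list("A", "CYP3A5", "Poor Metabolizer"),
    list("A", "UGT1A1", "Intermediate Metabolizer"),
    list("A", "UGT1A1", "Poor Metabolizer"),
    list("A", "CYP2C19", "Likely Poor Metabolizer")), refs$risk)
  expect_equal(ann$high_risk,
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_error(annotate_risk(mk_assignments(
    list("A", "CYP2C19", "Hyper Metabolizer")), refs$risk),
    "absent from the EHR risk vocabulary")
})

test_that("any_high_risk aggregates across the level 1A genes", {
  refs <- ref_bundle()
  nine <- c("CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A5", "NUDT15",
            "SLCO1B1", "TPMT", "UGT1A1")
  normal <- c(CYP2B6 = "Normal Metabolizer", CYP2C9 = "Normal Metabolizer",
              CYP2C19 = "Normal Metabolizer", CYP2D6 = "Normal Metabolizer",
              CYP3A5 = "Poor Metabolizer", NUDT15 = "Normal Metabolizer",
              SLCO1B1 = "Normal Function", TPMT = "Normal Metabolizer",
              UGT1A1 = "Normal Metabolizer")
  all_normal <- data.frame(sample = "A", gene = nine,
                           phenotype = unname(normal[nine]))
  expect_false(any_high_risk(annotate_risk(all_normal, refs$risk))[["A"]])
  one_hit <- all_normal
  one_hit$phenotype[one_hit$gene == "TPMT"] <- "Poor Metabolizer"
  expect_true(any_high_risk(annotate_risk(one_hit, refs$risk))[["A"]])
  # a high-risk warfarin gene alone does not count toward the nine
  warf <- data.frame(sample = "A", gene = c(nine, "CYP4F2"),
                     phenotype = c(unname(normal[nine]),
                                   "Higher Warfarin Dose"))
  expect_false(any_high_risk(annotate_risk(warf, refs$risk))[["A"]])
})

test_that("cohort high-risk fraction follows the independence product", {
  refs <- ref_bundle()
  set.seed(202)
  p_g <- c(CYP2C19 = 0.5, CYP2C9 = 0.3, TPMT = 0.1, UGT1A1 = 0.12)
  n <- 20000
  ann <- do.call(rbind, lapply(names(p_g), function(g) {
    hr <- stats::runif(n) < p_g[[g]]
    data.frame(sample = sprintf("S%05d", seq_len(n)), gene = g,
               phenotype = "x", high_risk = hr, priority_label = "")
  }))
  frac <- mean(any_high_risk(ann, genes = names(p_g)))
  expected <- 1 - prod(1 - p_g)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("interaction flags join taken drugs with high-risk genes", {
  refs <- ref_bundle()
  ann <- annotate_risk(mk_assignments(
    list("A", "SLCO1B1", "Decreased Function"),
    list("B", "SLCO1B1", "Normal Function")), refs$risk)
  meds <- data.frame(id = c("A", "B"),
                     drugs = c("simvastatin", "simvastatin"),
                     missing = FALSE)
  flags <- flag_interactions(meds, ann, refs$pairs, refs$synonyms)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$sample, "A")
  expect_equal(flags$gene, "SLCO1B1")
  # empty medication list or missing record produce no flags
  meds$drugs <- ""
  expect_equal(nrow(flag_interactions(meds, ann, refs$pairs)), 0L)
  meds <- data.frame(id = "A", drugs = "simvastatin", missing = TRUE)
  expect_equal(nrow(flag_interactions(meds, ann, refs$pairs)), 0L)
})

test_that("flags equal the brute-force cross-product filter on a toy cohort", {
  refs <- ref_bundle()
  set.seed(55)
  ids <- paste0("I", 1:6)
  genes <- c("CYP2C19", "SLCO1B1", "CYP2C9")
  phen <- list(CYP2C19 = c("Normal Metabolizer", "Poor Metabolizer"),
               SLCO1B1 = c("Normal Function", "Decreased Function"),
               CYP2C9 = c("Normal Metabolizer", "Intermediate Metabolizer"))
  ann <- annotate_risk(do.call(rbind, lapply(genes, function(g) {
    data.frame(sample = ids, gene = g,
               phenotype = sample(phen[[g]], 6, replace = TRUE))
  })), refs$risk)
  drugs <- c("omeprazole", "simvastatin", "ibuprofen")
  meds <- data.frame(id = ids, drugs = vapply(ids, function(i) {
    paste(sample(drugs, sample(0:3, 1)), collapse = ";")
  }, character(1)), missing = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  got <- flag_interactions(meds, ann, refs$pairs)
  want <- oracle_flags(meds, ann, refs$pairs)
  key <- function(df) {
    if (is.null(df) || !nrow(df)) return(character(0))
    sort(paste(df$sample, df$drug, df$gene))
  }
  expect_identical(key(got), key(want))
  # monotonicity: dropping a drug never adds a flag
  for (i in which(!meds$missing & nzchar(meds$drugs))) {
    fewer <- meds
    d <- strsplit(fewer$drugs[i], ";")[[1]]
    fewer$drugs[i] <- paste(d[-1], collapse = ";")
    expect_true(all(key(flag_interactions(fewer, ann, refs$pairs)) %in%
                      key(got)))
  }
})

test_that("interaction summary percentages and denominators are coherent", {
  refs <- ref_bundle()
  ann <- annotate_risk(mk_assignments(
    list("A", "SLCO1B1", "Decreased Function"),
    list("B", "SLCO1B1", "Normal Function"),
    list("C", "CYP2C19", "Poor Metabolizer")), refs$risk)
  # nobody takes a listed drug -> all zero
  meds <- data.frame(id = c("A", "B", "C"), drugs = "losartan",
                     missing = FALSE)
  s <- cohort_interaction_summary(meds, ann, refs$pairs)
  expect_equal(s$pct_taking_any_level1a, 0)
  expect_equal(s$pct_with_interaction, 0)
  # one individual with two interacting drugs counts as multiple
  meds <- data.frame(id = "C", drugs = "omeprazole;sertraline",
                     missing = FALSE)
  s <- cohort_interaction_summary(meds, ann, refs$pairs)
  expect_equal(s$pct_with_multiple_interactions, 100)
  # missing records leave the denominator
  meds <- data.frame(id = c("A", "B", "C"),
                     drugs = c("simvastatin", "", "omeprazole"),
                     missing = c(FALSE, TRUE, FALSE))
  s <- cohort_interaction_summary(meds, ann, refs$pairs)
  expect_equal(s$n_reporting, 2L)
  expect_equal(s$pct_taking_any_level1a, 100)
  expect_equal(s$pct_with_interaction, 100)
  # ordering invariance and the denominator inequality chain
  perm <- meds[c(3, 1, 2), ]
  s2 <- cohort_interaction_summary(perm, ann, refs$pairs)
  s$per_gene <- s$per_gene[order(s$per_gene$gene), ]
  s2$per_gene <- s2$per_gene[order(s2$per_gene$gene), ]
  rownames(s$per_gene) <- rownames(s2$per_gene) <- NULL
  expect_equal(unclass(s), unclass(s2))
  expect_lte(s$pct_with_multiple_interactions, s$pct_with_interaction)
  expect_lte(s$pct_with_interaction, s$pct_taking_any_level1a)
  expect_error(cohort_interaction_summary(
    meds[0, ], ann, refs$pairs), "empty cohort")
})
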