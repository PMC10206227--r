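# End-to-end pipeline: simulate (or load) cohort inputs, call diplotypes,
# assign phenotypes, annotate risk, cross-reference medications, and write
# frequency summaries plus a JSON report.

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_pgx("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full cohort analysis pipeline
#'
#' Stages: simulate (or load) inputs, call star alleles and copy number,
#' translate diplotypes to phenotypes, annotate EHR priority risk, flag
#' gene-drug interactions, and summarize. All tables are written as TSV
#' and the headline numbers as a single JSON report; given the same config
#' (including seed) the outputs are byte-identical.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{n, seed}{Cohort size (>= 1) and simulation seed (simulation
#'       mode).}
#'     \item{vcf, depth, medications, demographics}{Input file paths (file
#'       mode; used when `simulate` is `FALSE`).}
#'     \item{simulate}{Default `TRUE`.}
#'     \item{reference_dir}{Directory with the reference TSVs; defaults to
#'       the shipped bundle.}
#'     \item{out_dir}{Output directory (required).}
#'   }
#' @return Invisibly, a list with the `report` and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop_pgx("config needs out_dir")
  simulate <- config$simulate %||% TRUE
  refs <- pipeline_stage("reference_data", {
    dir <- config$reference_dir %||%
      system.file("extdata", package = "pgxcohort")
    load_reference_bundle(dir)
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (simulate) {
    if (is.null(config$n) || config$n < 1) {
      stop_pgx("simulation requires n >= 1")
    }
    if (is.null(config$seed)) stop_pgx("simulation requires a seed")
    sim <- pipeline_stage("simulate", {
      cfg <- default_cohort_config(n = config$n, seed = config$seed)
      cohort <- sample_cohort(cfg, refs$defs)
      cohort <- sample_medications(cfg, cohort)
      paths <- write_cohort_files(cohort, refs$defs, out_dir)
      list(cohort = cohort, paths = paths)
    })
    vcf_path <- sim$paths$vcf
    depth_path <- sim$paths$depth
    medications <- sim$cohort$medications
    demographics <- sim$cohort$demographics
  } else {
    vcf_path <- config$vcf
    depth_path <- config$depth
    medications <- pipeline_stage("load_inputs",
                                  read_medications(config$medications))
    demographics <- pipeline_stage("load_inputs", utils::read.csv(
      config$demographics, stringsAsFactors = FALSE))
  }

  calls <- pipeline_stage("star_caller",
                          call_cohort(vcf_path, depth_path, refs$defs))
  assignments <- pipeline_stage("phenotyper",
                                phenotype_cohort(calls, refs$translation,
                                                 refs$defs))
  annotations <- pipeline_stage("risk",
                                annotate_risk(assignments, refs$risk))
  interactions <- pipeline_stage("interact",
                                 flag_interactions(medications, annotations,
                                                   refs$pairs,
                                                   refs$synonyms))
  summary <- pipeline_stage("summarize", {
    hap <- haplotype_frequencies(calls)
    list(
      demographics = demographics_summary(demographics),
      haplotype_frequencies = hap,
      diplotype_frequencies = diplotype_frequencies(calls),
      phenotype_frequencies = phenotype_frequencies(assignments),
      allele_counts = count_alleles_by_threshold(hap),
      function_classes = as.list(function_class_composition(hap,
                                                            refs$defs)),
      pct_any_high_risk = pct(sum(any_high_risk(annotations)),
                              nrow(demographics)),
      interactions = cohort_interaction_summary(medications, annotations,
                                                refs$pairs, refs$synonyms)
    )
  })

  paths <- list(
    calls = file.path(out_dir, "calls.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    risk = file.path(out_dir, "risk_annotations.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    haplotype_frequencies = file.path(out_dir, "haplotype_frequencies.tsv"),
    report = file.path(out_dir, "report.json"))
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE,
                                              row.names = FALSE)
  wt(calls, paths$calls)
  wt(assignments, paths$phenotypes)
  wt(annotations, paths$risk)
  wt(interactions, paths$interactions)
  wt(summary$haplotype_frequencies, paths$haplotype_frequencies)

  report <- list(
    package_version = as.character(utils::packageVersion("pgxcohort")),
    seed = config$seed,
    n = nrow(demographics),
    demographics = list(
      sex = summary$demographics$sex,
      age_median = summary$demographics$age_median,
      age_iqr = summary$demographics$age_iqr,
      color_race = summary$demographics$color_race),
    allele_counts = summary$allele_counts,
    function_class_composition = summary$function_classes,
    pct_any_high_risk = summary$pct_any_high_risk,
    medication = unclass(summary$interactions))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(report = report, summary = summary, paths = paths))
}
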