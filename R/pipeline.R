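#' Pipeline configuration
#'
#' Bundles input locations (file paths, or an in-memory cohort from
#' [generateCohort()]/[makeFixture()]), all analysis thresholds and the
#' output directory. Thresholds are validated here, before any
#' computation runs.
#'
#' @param segments,genes,patients Input paths (SEG-style TSV, BED,
#'   patient TSV), or `NULL` when `cohort` is given.
#' @param cohort Optional in-memory cohort list (`lesions`, `genes`,
#'   `patientTable`).
#' @param outdir Output directory (created if absent).
#' @param gainThreshold,lossThreshold Gain/loss calling thresholds.
#' @param ampHighLevel,ampIntermediate Amplification thresholds
#'   (additional copies).
#' @param varianceThreshold Variance filter for the legacy heterogeneity
#'   variant.
#' @param lengthWeighted,minSharedRegions Distance options (see
#'   [patientHeterogeneity()]).
#' @param covariates Patient-table columns entered into the univariable
#'   Cox screen.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `pipeline_config`.
#' @export
pipelineConfig <- function(segments = NULL, genes = NULL, patients = NULL,
                           cohort = NULL, outdir = tempfile("metCNA_run_"),
                           gainThreshold = 1, lossThreshold = -1,
                           ampHighLevel = 15, ampIntermediate = 5,
                           varianceThreshold = 0.03,
                           lengthWeighted = FALSE, minSharedRegions = 10,
                           covariates = c("sex", "age", "size_largest_mm",
                                          "extrahepatic_disease"),
                           seed = 1L) {
  if (gainThreshold <= 0) stop("gainThreshold must be > 0")
  if (lossThreshold >= 0) stop("lossThreshold must be < 0")
  if (!(ampHighLevel > ampIntermediate && ampIntermediate > 0))
    stop("need ampHighLevel > ampIntermediate > 0")
  if (varianceThreshold < 0) stop("varianceThreshold must be >= 0")
  if (is.null(cohort) && (is.null(segments) || is.null(patients)))
    stop("provide either input paths or an in-memory cohort")
  structure(as.list(environment()), class = "pipeline_config")
}

writeTable <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(hash), con)
  if (is.null(df) || nrow(df) == 0L)
    writeLines("# (empty)", con)
  else {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], formatNum)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

ampEventsToDf <- function(events) {
  if (!length(events))
    return(data.frame(patient_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  data.frame(patient_id = events$patient_id,
             chrom = as.character(seqnames(events)),
             start = start(events), end = end(events),
             min_additional = events$min_additional,
             max_additional = events$max_additional,
             concordance = events$concordance,
             multi_lesion = events$multi_lesion,
             genes = if (is.null(events$genes)) ""
                     else vapply(events$genes, paste, "", collapse = ","),
             cancer_critical_genes =
               if (is.null(events$cancer_critical_genes)) ""
               else vapply(events$cancer_critical_genes, paste, "",
                           collapse = ","))
}

#' Run the end-to-end analysis pipeline
#'
#' Load -> harmonize -> call -> burden -> heterogeneity -> amplification
#' -> mutation groups -> survival, writing every result table (TSV with a
#' version/config-hash header) plus a run manifest into
#' `config$outdir`. Given identical inputs and configuration, the output
#' files are byte-identical across runs. Patients enter each analysis
#' with nested denominators: CNA summaries use all patients with profiles,
#' heterogeneity needs at least two lesions, and survival additionally
#' applies the MSS and R0/R1 eligibility filter.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, the result bundle (matrices, tables, survival fits,
#'   manifest data.frame).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    lesions <- cohort$lesions
    genes <- cohort$genes
    ptab <- cohort$patientTable
  } else {
    ptab <- readPatientTable(config$patients)
    ld <- merge(data.frame(lesion_id = ptab$lesions$lesion_id,
                           patient_id = ptab$lesions$patient_id),
                ptab$patients[, "patient_id", drop = FALSE], by = "patient_id")
    lesions <- readSegments(config$segments, lesionData = ld)
    genes <- if (is.null(config$genes)) NULL else readGeneIntervals(config$genes)
  }
  # cross-consistency before any computation
  orphan <- setdiff(lesionIDs(lesions), ptab$lesions$lesion_id)
  if (length(orphan))
    stop("lesion(s) missing from the patient table: ",
         paste(orphan, collapse = ", "))
  m <- match(lesionIDs(lesions), ptab$lesions$lesion_id)
  if (!identical(patientIDs(lesions), as.character(ptab$lesions$patient_id[m])))
    stop("patient assignment differs between segments and patient table")

  hash <- configHash(config[c("gainThreshold", "lossThreshold", "ampHighLevel",
                              "ampIntermediate", "varianceThreshold",
                              "lengthWeighted", "minSharedRegions", "seed")])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  rm <- harmonizeLesions(lesions)
  cm <- callAberrations(rm, config$gainThreshold, config$lossThreshold)
  burden <- cnaBurden(cm)
  pstats <- ploidyStats(lesions)
  freq <- cohortCNAFrequency(cm)
  het <- patientHeterogeneity(cm, genes = genes,
                              varianceThreshold = config$varianceThreshold,
                              lengthWeighted = config$lengthWeighted,
                              minSharedRegions = config$minSharedRegions)
  ampCfg <- ampConfig(config$ampHighLevel, config$ampIntermediate)
  events <- detectAmplifications(rm, ampCfg, genes = genes)

  status <- patientMutationStatus(ptab$lesions)
  status$group <- classifyMutationGroup(status)
  exclViol <- exclusivityCheck(status)

  patients <- merge(ptab$patients, status, by = "patient_id", sort = TRUE)
  patients <- merge(patients, burden$perPatient[, c("patient_id", "burden")],
                    by = "patient_id", all.x = TRUE)
  if (!is.null(het))
    patients <- merge(patients,
                      het[, c("patient_id", "euclidean", "euclidean_label")],
                      by = "patient_id", all.x = TRUE)
  else {
    patients$euclidean <- NA_real_
    patients$euclidean_label <- "missing"
  }
  patients$burden_label <- dichotomizeByMedian(patients$burden)

  eligible <- survivalEligible(patients, quiet = TRUE)
  removed <- attr(eligible, "removed")
  surv <- cbind(eligible, cssEncode(eligible))

  safely <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  kmAll <- kmEstimate(surv$time, surv$status)
  survResults <- list(
    overall_5y_css = fiveYearCSS(kmAll),
    by_group = safely({
      ok <- !is.na(surv$group)
      stratifiedSurvival(surv$time[ok], surv$status[ok], surv$group[ok])
    }),
    by_burden = safely({
      ok <- surv$burden_label %in% c("high", "low")
      stratifiedSurvival(surv$time[ok], surv$status[ok],
                         factor(surv$burden_label[ok], c("low", "high")))
    }),
    by_heterogeneity = safely({
      ok <- surv$euclidean_label %in% c("high", "low")
      stratifiedSurvival(surv$time[ok], surv$status[ok],
                         factor(surv$euclidean_label[ok], c("low", "high")))
    }),
    combined_mut_het = safely({
      st <- combinedStrata(surv$group, surv$euclidean_label)
      ok <- !is.na(st)
      stratifiedSurvival(surv$time[ok], surv$status[ok], st[ok])
    }),
    combined_mut_burden = safely({
      st <- combinedStrata(surv$group, surv$burden_label)
      ok <- !is.na(st)
      stratifiedSurvival(surv$time[ok], surv$status[ok], st[ok])
    }),
    cox_covariates = safely({
      covs <- intersect(config$covariates, colnames(surv))
      coxFit(surv, covs, mode = "univariable")
    }))

  manifest <- data.frame(
    key = c("package_version", "config_hash", "seed", "gain_threshold",
            "loss_threshold", "amp_high_level", "amp_intermediate",
            "variance_threshold", "length_weighted", "n_lesions",
            "n_regions", "n_patients_total", "n_patients_multilesion",
            "n_patients_survival_eligible", "n_removed_msi", "n_removed_r2",
            "n_amplification_events", "n_exclusivity_violations",
            "heterogeneity_note"),
    value = c(as.character(utils::packageVersion("metCNA")), hash,
              config$seed, config$gainThreshold, config$lossThreshold,
              config$ampHighLevel, config$ampIntermediate,
              config$varianceThreshold, config$lengthWeighted,
              length(lesions), nrow(rm), nrow(ptab$patients),
              if (is.null(het)) 0L else nrow(het), nrow(eligible),
              removed[["msi"]], removed[["r2"]], length(events),
              length(exclViol),
              if (is.null(het)) "no multi-lesion patients; table empty"
              else "ok"))

  writeRegionMatrix(rm, out("region_matrix.tsv"), "copyNumber", hash)
  writeRegionMatrix(cm, out("call_matrix.tsv"), "calls", hash)
  writeTable(burden$perLesion, out("burden_lesion.tsv"), hash)
  writeTable(burden$perPatient, out("burden_patient.tsv"), hash)
  writeTable(pstats, out("ploidy_patient.tsv"), hash)
  writeTable(freq, out("cna_frequency.tsv"), hash)
  writeTable(het, out("heterogeneity.tsv"), hash)
  writeTable(ampEventsToDf(events), out("amplification_events.tsv"), hash)
  gdf <- status
  gdf$group <- as.character(gdf$group)
  writeTable(gdf, out("mutation_groups.tsv"), hash)
  writeTable(survivalTestsDf(survResults), out("survival_tests.tsv"), hash)
  coxDf <- if (is.data.frame(survResults$cox_covariates))
    survResults$cox_covariates else NULL
  writeTable(coxDf, out("cox_univariable.tsv"), hash)
  writeTable(kmStepDf(kmAll), out("km_overall.tsv"), hash)
  writeTable(manifest, out("manifest.tsv"), hash)

  invisible(list(lesions = lesions, regionMatrix = rm, callMatrix = cm,
                 burden = burden, ploidy = pstats, frequency = freq,
                 heterogeneity = het, events = events, mutationStatus = status,
                 patients = patients, survival = survResults,
                 manifest = manifest, outdir = config$outdir))
}

#' Combined mutation-by-CNA strata
#'
#' Three ordered strata used for the trend test and Cox model:
#' patients without co-mutation (`other`, the reference group), co-mutated
#' patients with a low CNA label, and co-mutated patients with a high CNA
#' label.
#'
#' @param group Mutation group factor (from [classifyMutationGroup()]).
#' @param label CNA label (`high`/`low`/`missing`).
#' @return Factor with levels `other < co_mut_low < co_mut_high` (`NA`
#'   where the group or label is unresolved).
#' @export
combinedStrata <- function(group, label) {
  g <- as.character(group)
  st <- ifelse(is.na(g) | !label %in% c("high", "low"), NA_character_,
        ifelse(g != "co_mut", "other",
        ifelse(label == "high", "co_mut_high", "co_mut_low")))
  factor(st, levels = c("other", "co_mut_low", "co_mut_high"))
}

kmStepDf <- function(fit) {
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

survivalTestsDf <- function(sr) {
  row <- function(name, x) {
    if (is.null(x) || !is.null(x$error))
      return(data.frame(analysis = name, statistic = NA_real_,
                        p.value = NA_real_,
                        note = if (is.null(x)) "not run" else x$error))
    t <- x$test
    data.frame(analysis = name,
               statistic = if (!is.null(t$z) && !is.na(t$z)) t$z else t$chisq,
               p.value = t$p.value, note = "ok")
  }
  rbind(row("mutation_group_trend", sr$by_group),
        row("burden_logrank", sr$by_burden),
        row("heterogeneity_logrank", sr$by_heterogeneity),
        row("comutation_x_heterogeneity_trend", sr$combined_mut_het),
        row("comutation_x_burden_trend", sr$combined_mut_burden))
}
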