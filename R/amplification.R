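#' Amplification-calling configuration
#'
#' Thresholds are in additional copies relative to the lesion's estimated
#' ploidy. A region is a high-level amplification event when at least one
#' lesion carries `highLevel` (default 15) additional copies; concordance
#' across a patient's lesions is judged against `highLevel` and the
#' `intermediate` (default 5) lower-amplitude threshold. `legacyLow`
#' (default 6) supports the screen asserting that a gene set carries no
#' high-level events when all its values stay at or below 6 additional
#' copies.
#'
#' @param highLevel Additional copies for a high-level amplification.
#' @param intermediate Additional copies for an intermediate-level gain.
#' @param legacyLow Upper bound used by [screenNoHighLevel()].
#' @return A named list of class `amp_config`.
#' @export
ampConfig <- function(highLevel = 15, intermediate = 5, legacyLow = 6) {
  stopifnot(highLevel > intermediate, intermediate > 0)
  structure(list(highLevel = highLevel, intermediate = intermediate,
                 legacyLow = legacyLow), class = "amp_config")
}

#' Additional copies relative to ploidy
#'
#' Copy number minus the owning lesion's ploidy, unrounded. Ploidy is
#' taken from the lesion metadata where supplied, otherwise from the
#' length-weighted median copy number.
#'
#' @param x A [RegionMatrix-class].
#' @param ploidy Optional per-lesion ploidies (named or in column order).
#' @return Numeric matrix, regions x lesions.
#' @export
additionalCopies <- function(x, ploidy = NULL) {
  stopifnot(is(x, "RegionMatrix"))
  if (is.null(ploidy)) ploidy <- lesionPloidy(x)
  sweep(copyNumber(x), 2L, unname(ploidy), `-`)
}

#' Classify intrapatient intermetastatic concordance of an amplification
#'
#' Given the per-lesion additional copies of one amplification event, the
#' event is `homogeneous` when every lesion reaches the high-level
#' threshold, `intermediate_concordant` when every lesion reaches at
#' least the intermediate threshold (but not all the high-level one), and
#' `heterogeneous` otherwise. The rule depends only on the minimum across
#' lesions. Single-lesion patients are trivially homogeneous; callers
#' should flag them.
#'
#' @param copies Numeric vector of per-lesion additional copies (one
#'   event), or a list of such vectors.
#' @param config An [ampConfig()].
#' @return Character scalar (or vector for list input) in
#'   `c("homogeneous", "intermediate_concordant", "heterogeneous")`.
#' @export
classifyConcordance <- function(copies, config = ampConfig()) {
  if (is.list(copies))
    return(vapply(copies, classifyConcordance, "", config = config))
  m <- min(copies, na.rm = TRUE)
  if (m >= config$highLevel) "homogeneous"
  else if (m >= config$intermediate) "intermediate_concordant"
  else "heterogeneous"
}

#' Detect high-level amplification events
#'
#' Genome-wide search on the harmonized matrix: a region qualifies for a
#' patient when any of the patient's lesions carries at least
#' `config$highLevel` additional copies; qualifying regions that are
#' adjacent (abutting) on the same chromosome merge into one event whose
#' per-lesion additional copies are the maximum across member regions.
#' Events of patients with a single analyzed lesion are flagged
#' (`multi_lesion = FALSE`) and excluded from concordance summaries.
#'
#' @param x A [RegionMatrix-class] covering one or more patients.
#' @param config An [ampConfig()].
#' @param genes Optional gene `GRanges` for [annotateCancerGenes()].
#' @return A `GRanges` of events with metadata: `patient_id`,
#'   `lesion_copies` (`NumericList`, per analyzed lesion, named),
#'   `min_additional`, `max_additional`, `concordance`, `multi_lesion`,
#'   and when `genes` is supplied `genes` / `cancer_critical_genes`
#'   (`CharacterList`).
#' @export
detectAmplifications <- function(x, config = ampConfig(), genes = NULL) {
  stopifnot(is(x, "RegionMatrix"))
  add <- additionalCopies(x)
  pid <- patientIDs(x)
  rr <- rowRanges(x)
  out <- list()
  for (p in unique(pid)) {
    sub <- add[, pid == p, drop = FALSE]
    colnames(sub) <- lesionIDs(x)[pid == p]
    qual <- apply(sub, 1L, function(v) any(v >= config$highLevel, na.rm = TRUE))
    if (!any(qual)) next
    ev <- reduce(rr[qual])  # merges abutting qualifying regions only
    memb <- findOverlaps(rr[qual], ev)
    copies <- lapply(seq_along(ev), function(k) {
      rows <- which(qual)[queryHits(memb)[subjectHits(memb) == k]]
      apply(sub[rows, , drop = FALSE], 2L, max, na.rm = TRUE)
    })
    ev$patient_id <- p
    ev$lesion_copies <- NumericList(copies)
    ev$min_additional <- vapply(copies, min, 0)
    ev$max_additional <- vapply(copies, max, 0)
    ev$concordance <- classifyConcordance(copies, config)
    ev$multi_lesion <- ncol(sub) >= 2L
    out[[p]] <- ev
  }
  events <- if (length(out)) unlist(GRangesList(out), use.names = FALSE)
            else GRanges(patient_id = character(0))
  if (!is.null(genes) && length(events))
    events <- annotateCancerGenes(events, genes)
  events
}

#' Annotate amplification events with overlapping genes
#'
#' Attaches the names of genes overlapping each event region, and the
#' subset flagged cancer-critical in the input gene list.
#'
#' @param events `GRanges` of events (from [detectAmplifications()]).
#' @param genes `GRanges` with `gene_name`, `cancer_critical`.
#' @return `events` with `genes` and `cancer_critical_genes`
#'   `CharacterList` columns added.
#' @export
annotateCancerGenes <- function(events, genes) {
  hits <- findOverlaps(events, genes)
  gl <- split(genes$gene_name[subjectHits(hits)],
              factor(queryHits(hits), levels = seq_along(events)))
  cl <- split(genes$gene_name[subjectHits(hits)][
                genes$cancer_critical[subjectHits(hits)]],
              factor(queryHits(hits)[genes$cancer_critical[subjectHits(hits)]],
                     levels = seq_along(events)))
  events$genes <- CharacterList(gl)
  events$cancer_critical_genes <- CharacterList(cl)
  events
}

#' Screen a gene set for absence of high-level amplification
#'
#' Verifies that, over the given genes, no lesion exceeds
#' `config$legacyLow` additional copies (the "no high-level events at
#' <= 6 additional copies" check applied to the four driver genes).
#'
#' @param x A [RegionMatrix-class].
#' @param genes `GRanges` of the genes to screen.
#' @param config An [ampConfig()].
#' @return A data.frame per gene: `gene_name`, `max_additional`,
#'   `clear` (TRUE when the gene never exceeds `legacyLow`).
#' @export
screenNoHighLevel <- function(x, genes, config = ampConfig()) {
  add <- additionalCopies(x)
  hits <- findOverlaps(genes, rowRanges(x))
  mx <- vapply(seq_along(genes), function(i) {
    rows <- subjectHits(hits)[queryHits(hits) == i]
    if (!length(rows)) return(NA_real_)
    max(add[rows, , drop = FALSE], na.rm = TRUE)
  }, 0)
  data.frame(gene_name = genes$gene_name, max_additional = mx,
             clear = !is.na(mx) & mx <= config$legacyLow)
}
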