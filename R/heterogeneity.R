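#' @name heterogeneity
#' @title Intrapatient intermetastatic CNA heterogeneity estimators
#'
#' @description Four per-patient summaries of how much a patient's
#' metastatic lesions diverge on the copy-number level, all computed on
#' the harmonized region-by-lesion matrix:
#'
#' * `hetEuclidean()`: mean Euclidean distance over all lesion pairs.
#' * `hetCorrelation()`: mean (1 - Pearson correlation) over lesion pairs.
#' * `hetDiscordantFraction()`: fraction of aberrant genes whose ternary
#'   call is not shared by all lesions (amplitude differences within a
#'   shared call are concordant).
#' * `hetVarianceFiltered()`: mean pairwise Euclidean distance restricted
#'   to regions whose across-lesion variance exceeds a threshold
#'   (default 0.03), the legacy segment-variance-filtered variant.
#'
#' Distances use one coordinate per region (unweighted) by default;
#' `lengthWeighted = TRUE` weights squared differences by region length
#' as a fraction of the pair's shared length (a length-weighted
#' root-mean-square difference, invariant under segment subdivision).
#' Missing regions are handled
#' pairwise-complete; a lesion pair sharing fewer than
#' `minSharedRegions` regions is refused with status
#' `"insufficient_overlap"` rather than silently computed.
#'
#' Scores are returned as numeric scalars with a `"status"` attribute
#' (`"ok"`, or a reason when the score is `NA`/degenerate).
NULL

hetStatus <- function(score, status = "ok") {
  attr(score, "status") <- status
  score
}

#' @rdname heterogeneity
#' @param vals Numeric matrix, regions x lesions, for one patient (or a
#'   [RegionMatrix-class]/[CallMatrix-class] together with `patient`).
#' @param lengths Optional region lengths (bp) for `lengthWeighted` mode;
#'   taken from the object when `vals` is a `RegionMatrix`.
#' @param lengthWeighted Weight squared differences by region length over
#'   mean region length.
#' @param minSharedRegions Minimum pairwise-complete regions per lesion
#'   pair.
#' @param patient When `vals` is a `RegionMatrix`, restrict to this
#'   patient's lesions.
#' @export
hetEuclidean <- function(vals, lengths = NULL, lengthWeighted = FALSE,
                         minSharedRegions = 10, patient = NULL) {
  m <- asPatientMatrix(vals, patient)
  if (is.null(lengths) && is(vals, "RegionMatrix")) lengths <- regionLengths(vals)
  meanPairwise(m, lengths, lengthWeighted, minSharedRegions,
               pairFun = euclidPair)
}

#' @rdname heterogeneity
#' @export
hetCorrelation <- function(vals, minSharedRegions = 10, patient = NULL) {
  m <- asPatientMatrix(vals, patient)
  meanPairwise(m, NULL, FALSE, minSharedRegions, pairFun = corPair)
}

euclidPair <- function(x, y, w) sqrt(sum(w * (x - y)^2))

corPair <- function(x, y, w) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  if (identical(x, y)) return(0)  # exact zero for identical profiles
  1 - cor(x, y)
}

meanPairwise <- function(m, lengths, lengthWeighted, minSharedRegions, pairFun) {
  n <- ncol(m)
  if (n < 2L) return(hetStatus(NA_real_, "fewer_than_two_lesions"))
  d <- c()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) < minSharedRegions)
      return(hetStatus(NA_real_, "insufficient_overlap"))
    if (sum(ok) == 0L) return(hetStatus(NA_real_, "insufficient_overlap"))
    # length weights sum to 1, giving a length-weighted RMS difference
    # that is exactly invariant under segment subdivision
    w <- if (lengthWeighted && !is.null(lengths)) {
      lw <- as.numeric(lengths[ok]); lw / sum(lw)
    } else rep(1, sum(ok))
    d <- c(d, pairFun(m[ok, i], m[ok, j], w))
  }
  if (all(is.na(d))) return(hetStatus(NA_real_, "undefined"))
  hetStatus(mean(d, na.rm = TRUE), if (anyNA(d)) "some_pairs_undefined" else "ok")
}

asPatientMatrix <- function(x, patient) {
  if (is(x, "RegionMatrix")) {
    if (!is.null(patient)) x <- x[, patientIDs(x) == patient]
    copyNumber(x)
  } else as.matrix(x)
}

#' @rdname heterogeneity
#' @param geneCalls Genes x lesions ternary call matrix for one patient
#'   (e.g. a patient's columns of [geneLevelCalls()]` $calls`).
#' @export
hetDiscordantFraction <- function(geneCalls) {
  m <- as.matrix(geneCalls)
  if (ncol(m) < 2L) return(hetStatus(NA_real_, "fewer_than_two_lesions"))
  known <- rowSums(!is.na(m)) >= 2L
  m <- m[known, , drop = FALSE]
  aberrant <- apply(m, 1L, function(v) any(v[!is.na(v)] != 0))
  if (!any(aberrant)) return(hetStatus(NA_real_, "no_aberrant_genes"))
  discordant <- apply(m[aberrant, , drop = FALSE], 1L, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) > 1L
  })
  hetStatus(sum(discordant) / sum(aberrant))
}

#' @rdname heterogeneity
#' @param varianceThreshold Regions with across-lesion variance at or
#'   below this value are dropped before the distance computation
#'   (default 0.03).
#' @export
hetVarianceFiltered <- function(vals, varianceThreshold = 0.03,
                                lengths = NULL, lengthWeighted = FALSE,
                                patient = NULL) {
  if (varianceThreshold < 0) stop("varianceThreshold must be >= 0")
  m <- asPatientMatrix(vals, patient)
  if (ncol(m) < 2L) return(hetStatus(NA_real_, "fewer_than_two_lesions"))
  if (is.null(lengths) && is(vals, "RegionMatrix")) lengths <- regionLengths(vals)
  v <- apply(m, 1L, var, na.rm = TRUE)
  keep <- !is.na(v) & v > varianceThreshold
  if (!any(keep)) return(hetStatus(0, "no_variable_regions"))
  meanPairwise(m[keep, , drop = FALSE],
               if (!is.null(lengths)) lengths[keep] else NULL,
               lengthWeighted, minSharedRegions = 0, pairFun = euclidPair)
}

#' Per-patient heterogeneity score table
#'
#' Computes the four heterogeneity estimators for every patient with at
#' least two lesions and dichotomizes each defined score at the cohort
#' median.
#'
#' @param x A [CallMatrix-class] (copy numbers and calls).
#' @param genes Optional gene `GRanges`; without it the discordant-gene
#'   fraction is computed over harmonized regions instead of genes.
#' @param varianceThreshold Passed to [hetVarianceFiltered()].
#' @param lengthWeighted,minSharedRegions Passed to the distance measures.
#' @return data.frame with one row per multi-lesion patient: scores
#'   `euclidean`, `correlation`, `discordant`, `variance_filtered`,
#'   `n_lesions`, per-measure `<measure>_label` (`high`/`low`/`missing`)
#'   and `status`.
#' @export
patientHeterogeneity <- function(x, genes = NULL, varianceThreshold = 0.03,
                                 lengthWeighted = FALSE, minSharedRegions = 10) {
  stopifnot(is(x, "CallMatrix"))
  pid <- patientIDs(x)
  keep <- pid %in% names(which(table(pid) >= 2))
  upat <- unique(pid[keep])
  gene_calls <- if (!is.null(genes)) geneLevelCalls(x, genes)$calls else cnaCalls(x)
  rows <- lapply(upat, function(p) {
    sel <- pid == p
    vals <- copyNumber(x)[, sel, drop = FALSE]
    eu <- hetEuclidean(vals, regionLengths(x), lengthWeighted, minSharedRegions)
    co <- hetCorrelation(vals, minSharedRegions)
    di <- hetDiscordantFraction(gene_calls[, sel, drop = FALSE])
    vf <- hetVarianceFiltered(vals, varianceThreshold, regionLengths(x),
                              lengthWeighted)
    data.frame(patient_id = p, n_lesions = sum(sel),
               euclidean = as.numeric(eu), correlation = as.numeric(co),
               discordant = as.numeric(di), variance_filtered = as.numeric(vf),
               status = paste(attr(eu, "status"), attr(co, "status"),
                              attr(di, "status"), attr(vf, "status"),
                              sep = ";"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  for (mname in c("euclidean", "correlation", "discordant", "variance_filtered"))
    out[[paste0(mname, "_label")]] <- dichotomizeByMedian(out[[mname]])
  out
}

#' Dichotomize scores at the cohort median
#'
#' `high` when strictly above the median of the defined scores; scores
#' equal to the median are `low` (so "high" always means strictly above
#' the median); undefined scores are `missing`.
#'
#' @param x Numeric scores (NA = undefined).
#' @return Character vector in `c("high", "low", "missing")`.
#' @export
dichotomizeByMedian <- function(x) {
  if (sum(!is.na(x)) < 2L)
    return(ifelse(is.na(x), "missing", "low"))
  med <- median(x, na.rm = TRUE)
  ifelse(is.na(x), "missing", ifelse(x > med, "high", "low"))
}

#' Rank correlation among heterogeneity estimators
#'
#' Spearman correlations between the four per-patient measures,
#' pairwise-complete.
#'
#' @param scores data.frame from [patientHeterogeneity()].
#' @return 4x4 Spearman correlation matrix.
#' @export
compareHetEstimators <- function(scores) {
  m <- as.matrix(scores[, c("euclidean", "correlation", "discordant",
                            "variance_filtered")])
  cor(m, method = "spearman", use = "pairwise.complete.obs")
}
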