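#' Harmonize lesion profiles into smallest regions of overlap
#'
#' Splits the sample-wise segments of all lesions at every breakpoint that
#' occurs in any sample, yielding a partition of the covered genome on
#' which all lesions can be compared position-wise. Each resulting region
#' is fully inside, or fully outside, every input segment, so the region's
#' copy number for a lesion is the (unique) value of the covering segment,
#' or `NA` where the lesion has no coverage.
#'
#' The operation is idempotent: harmonizing the harmonized output
#' introduces no new breakpoints. The per-lesion genomic footprint is
#' preserved exactly.
#'
#' @param x A [LesionSet-class] with at least one lesion.
#' @return A [RegionMatrix-class].
#' @examples
#' ls <- exampleLesionPair()
#' harmonizeLesions(ls)
#' @export
harmonizeLesions <- function(x) {
  stopifnot(is(x, "LesionSet"))
  if (length(x) == 0L) stop("cannot harmonize an empty LesionSet")
  all <- unlist(profiles(x), use.names = FALSE)
  regions <- sort(disjoin(granges(all)))
  vals <- matrix(NA_real_, length(regions), length(x),
                 dimnames = list(NULL, lesionIDs(x)))
  for (i in seq_along(x)) {
    p <- profiles(x)[[i]]
    hits <- findOverlaps(regions, p, type = "within")
    vals[queryHits(hits), i] <- p$copyNumber[subjectHits(hits)]
  }
  se <- SummarizedExperiment(assays = list(copyNumber = vals),
                             rowRanges = regions,
                             colData = lesionData(x))
  new("RegionMatrix", se)
}

#' Convert a RegionMatrix back to per-lesion segment profiles
#'
#' Drops `NA` regions per lesion; used for round-trips and idempotence
#' checks. Adjacent equal-valued regions are deliberately kept split.
#'
#' @param x A [RegionMatrix-class].
#' @return A [LesionSet-class].
#' @export
regionMatrixToLesionSet <- function(x) {
  vals <- copyNumber(x)
  rr <- rowRanges(x)
  grl <- GRangesList(lapply(seq_len(ncol(vals)), function(i) {
    keep <- !is.na(vals[, i])
    g <- rr[keep]
    g$copyNumber <- vals[keep, i]
    g
  }))
  names(grl) <- lesionIDs(x)
  LesionSet(grl, colData(x))
}

#' Per-lesion baseline: length-weighted median genome-wide copy number
#'
#' The gain/loss baseline for a lesion is its median genome-wide copy
#' number. Since segments have very different lengths, the median is
#' length-weighted (equivalent to the ordinary median over per-base-pair
#' copy numbers); an unweighted median over segments would be biased
#' toward short segments.
#'
#' @param x A `GRanges` profile with `copyNumber`, a [LesionSet-class], or
#'   a [RegionMatrix-class] (per-lesion, `NA` regions ignored).
#' @return A numeric baseline per lesion (scalar for a single `GRanges`).
#' @export
lesionBaseline <- function(x) {
  if (is(x, "GRanges")) {
    if (sum(width(x)) == 0) stop("profile has zero covered length")
    return(weightedMedian(x$copyNumber, width(x)))
  }
  if (is(x, "LesionSet"))
    return(vapply(profiles(x), lesionBaseline, 0))
  if (is(x, "RegionMatrix")) {
    w <- regionLengths(x)
    vals <- copyNumber(x)
    b <- vapply(seq_len(ncol(vals)), function(i) {
      ok <- !is.na(vals[, i])
      if (!any(ok)) stop("lesion ", lesionIDs(x)[i], " has zero covered length")
      weightedMedian(vals[ok, i], w[ok])
    }, 0)
    names(b) <- lesionIDs(x)
    return(b)
  }
  stop("unsupported input for lesionBaseline")
}

#' Call copy-number gains and losses
#'
#' A region is called gained (+1) in a lesion when its copy number exceeds
#' the lesion's median genome-wide copy number by at least
#' `gainThreshold` copies, and lost (-1) when it falls below it by at
#' least `|lossThreshold|` copies (closed comparisons); 0 otherwise.
#' Missing regions stay missing.
#'
#' @param x A [RegionMatrix-class].
#' @param gainThreshold Copies above baseline for a gain call (default +1).
#' @param lossThreshold Copies below baseline for a loss call (default -1).
#' @param baseline Optional per-lesion baselines; defaults to
#'   [lesionBaseline()] on `x`.
#' @return A [CallMatrix-class].
#' @export
callAberrations <- function(x, gainThreshold = 1, lossThreshold = -1,
                            baseline = NULL) {
  stopifnot(is(x, "RegionMatrix"))
  if (gainThreshold <= 0) stop("gainThreshold must be > 0")
  if (lossThreshold >= 0) stop("lossThreshold must be < 0")
  if (is.null(baseline)) baseline <- lesionBaseline(x)
  vals <- copyNumber(x)
  rel <- sweep(vals, 2L, baseline, `-`)
  calls <- (rel >= gainThreshold) - (rel <= lossThreshold)
  cd <- colData(x)
  cd$baseline <- unname(baseline)
  se <- SummarizedExperiment(
    assays = list(copyNumber = vals, calls = calls),
    rowRanges = rowRanges(x), colData = cd,
    metadata = list(gain_threshold = gainThreshold,
                    loss_threshold = lossThreshold))
  new("CallMatrix", new("RegionMatrix", se))
}

#' Genome-wide CNA burden (fraction of genome altered)
#'
#' Per-lesion burden is the percent of covered base pairs whose call is
#' non-neutral; regions missing in a lesion are excluded from that
#' lesion's denominator. The patient-wise burden is the arithmetic mean
#' over the patient's lesions.
#'
#' @param x A [CallMatrix-class].
#' @return A list with `perLesion` (lesion_id, patient_id, burden) and
#'   `perPatient` (patient_id, n_lesions, burden) data.frames; burdens in
#'   percent, in \[0, 100\].
#' @export
cnaBurden <- function(x) {
  stopifnot(is(x, "CallMatrix"))
  calls <- cnaCalls(x)
  w <- as.numeric(regionLengths(x))
  burden <- vapply(seq_len(ncol(calls)), function(i) {
    ok <- !is.na(calls[, i])
    tot <- sum(w[ok])
    if (tot == 0) stop("lesion ", lesionIDs(x)[i], " has zero covered length")
    100 * sum(w[ok & calls[, i] != 0]) / tot
  }, 0)
  perLesion <- data.frame(lesion_id = lesionIDs(x),
                          patient_id = patientIDs(x),
                          burden = burden)
  agg <- aggregate(burden ~ patient_id, perLesion, mean)
  n <- aggregate(lesion_id ~ patient_id, perLesion, length)
  perPatient <- data.frame(patient_id = agg$patient_id,
                           n_lesions = n$lesion_id[match(agg$patient_id, n$patient_id)],
                           burden = agg$burden)
  list(perLesion = perLesion, perPatient = perPatient)
}

#' Patient-wise ploidy summaries
#'
#' Median and range (max - min) of per-lesion ploidy within each patient.
#' Lesions without a supplied ploidy estimate fall back to their
#' length-weighted median copy number.
#'
#' @param x A [LesionSet-class] or [RegionMatrix-class].
#' @return data.frame with `patient_id`, `n_lesions`, `median_ploidy`,
#'   `ploidy_range`.
#' @export
ploidyStats <- function(x) {
  pl <- ploidies(x)
  if (anyNA(pl)) pl[is.na(pl)] <- lesionBaseline(x)[is.na(pl)]
  pid <- patientIDs(x)
  res <- lapply(split(pl, pid), function(p)
    c(n = length(p), med = median(p), rng = max(p) - min(p)))
  out <- do.call(rbind, res)
  data.frame(patient_id = names(res), n_lesions = as.integer(out[, "n"]),
             median_ploidy = out[, "med"], ploidy_range = out[, "rng"],
             row.names = NULL)
}

# Per-lesion ploidy with baseline fallback, as a named vector.
lesionPloidy <- function(x) {
  pl <- ploidies(x)
  if (anyNA(pl)) pl[is.na(pl)] <- lesionBaseline(x)[is.na(pl)]
  names(pl) <- lesionIDs(x)
  pl
}

#' Gene-level copy-number calls and per-patient heterogeneity flags
#'
#' Each gene takes the ternary call of the harmonized region it overlaps
#' most (ties broken by the earlier region on the genome). The per-patient
#' flag marks genes whose call differs across that patient's lesions.
#'
#' @param x A [CallMatrix-class].
#' @param genes `GRanges` with `gene_name` (from [readGeneIntervals()]).
#' @return A list with `calls` (genes x lesions ternary matrix, `NA` where
#'   a gene has no overlapping region or the region is missing) and
#'   `heterogeneous` (genes x patients logical matrix: call differs among
#'   the patient's non-missing lesion calls).
#' @export
geneLevelCalls <- function(x, genes) {
  stopifnot(is(x, "CallMatrix"))
  hits <- findOverlaps(genes, rowRanges(x))
  ovw <- width(pintersect(genes[queryHits(hits)],
                          rowRanges(x)[subjectHits(hits)]))
  # largest-overlap region per gene; ties -> earlier (lower region index)
  h <- data.frame(gene = queryHits(hits), region = subjectHits(hits), w = ovw)
  h <- h[order(h$gene, -h$w, h$region), , drop = FALSE]
  h <- h[!duplicated(h$gene), , drop = FALSE]
  assign <- rep(NA_integer_, length(genes))
  assign[h$gene] <- h$region
  if (anyNA(assign))
    warning(sum(is.na(assign)), " gene(s) with no overlapping region; status missing")
  calls <- cnaCalls(x)[ifelse(is.na(assign), 1L, assign), , drop = FALSE]
  calls[is.na(assign), ] <- NA
  rownames(calls) <- genes$gene_name
  pid <- patientIDs(x)
  upat <- unique(pid)
  het <- vapply(upat, function(p) {
    sub <- calls[, pid == p, drop = FALSE]
    apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      length(v) >= 2L && length(unique(v)) > 1L
    })
  }, logical(nrow(calls)))
  het <- matrix(het, nrow = nrow(calls),
                dimnames = list(rownames(calls), upat))
  list(calls = calls, heterogeneous = het)
}

#' Cohort-level CNA frequencies, summarized per patient
#'
#' A patient contributes a gain in a region when at least one of their
#' lesions is called +1 there, and a loss when at least one lesion is
#' called -1 (a patient can contribute both in the same region).
#' Frequencies are contributing patients over total patients.
#'
#' @param x A [CallMatrix-class].
#' @return data.frame with region coordinates, `gain_freq` and `loss_freq`.
#' @export
cohortCNAFrequency <- function(x) {
  stopifnot(is(x, "CallMatrix"))
  calls <- cnaCalls(x)
  pid <- patientIDs(x)
  upat <- unique(pid)
  gain <- loss <- matrix(FALSE, nrow(calls), length(upat))
  for (k in seq_along(upat)) {
    sub <- calls[, pid == upat[k], drop = FALSE]
    gain[, k] <- apply(sub, 1L, function(v) any(v == 1, na.rm = TRUE))
    loss[, k] <- apply(sub, 1L, function(v) any(v == -1, na.rm = TRUE))
  }
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)),
             start = start(rr), end = end(rr),
             gain_freq = rowMeans(gain), loss_freq = rowMeans(loss))
}

#' Two-lesion toy profile pair used in examples
#' @return A small [LesionSet-class].
#' @export
exampleLesionPair <- function() {
  a <- GRanges("1", IRanges(1, 100), copyNumber = 2)
  b <- GRanges("1", IRanges(c(1, 61), c(60, 100)), copyNumber = c(2, 4))
  LesionSet(GRangesList(A = a, B = b),
            data.frame(lesion_id = c("A", "B"), patient_id = c("P1", "P1")))
}
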