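#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<- sortSeqlevels Seqinfo
#' @import SummarizedExperiment
NULL

AUTOSOMES <- as.character(1:22)

#' LesionSet: segmented copy-number profiles for a cohort of lesions
#'
#' Container for one copy-number profile per metastatic lesion. Each profile
#' is a \link[GenomicRanges]{GRanges} of non-overlapping segments (native
#' 1-based closed `IRanges` coordinates) with a `copyNumber` metadata column
#' holding the total copy number. Per-lesion metadata (owning patient, optional ploidy
#' and aberrant-cell-fraction estimates from upstream allele-specific
#' segmentation) live in `lesionData`. Sex chromosomes are never present;
#' the analysis is restricted to autosomes 1-22.
#'
#' @slot profiles A `GRangesList`, one element per lesion, each sorted and
#'   non-overlapping, with numeric `copyNumber` metadata column.
#' @slot lesionData A `DataFrame` with columns `lesion_id`, `patient_id`,
#'   and optionally `ploidy` and `aberrant_cell_fraction`.
#' @export
setClass("LesionSet",
  representation(profiles = "CompressedGRangesList", lesionData = "DFrame"))

setValidity("LesionSet", function(object) {
  p <- object@profiles
  d <- object@lesionData
  if (length(p) != nrow(d))
    return("number of profiles differs from rows of lesionData")
  if (!all(c("lesion_id", "patient_id") %in% colnames(d)))
    return("lesionData must have lesion_id and patient_id columns")
  if (!identical(names(p), as.character(d$lesion_id)))
    return("names(profiles) must equal lesionData$lesion_id")
  if (anyDuplicated(d$lesion_id))
    return("duplicated lesion_id")
  bad <- setdiff(unique(as.character(unlist(seqnames(p), use.names = FALSE))), AUTOSOMES)
  if (length(bad))
    return(paste0("non-autosomal chromosome(s): ", paste(bad, collapse = ", ")))
  u <- unlist(p, use.names = FALSE)
  if (length(u)) {
    if (is.null(u$copyNumber) || !is.numeric(u$copyNumber))
      return("profiles lack a numeric copyNumber metadata column")
    if (any(u$copyNumber < 0, na.rm = TRUE)) {
      bad <- rep(names(p), lengths(p))[which(u$copyNumber < 0)[1L]]
      return(sprintf("lesion %s has negative copy number", bad))
    }
    # vectorized disjointness: within (lesion, chromosome), sorted starts
    # must begin after the previous end
    les <- rep(seq_along(p), lengths(p))
    ch <- as.integer(seqnames(u))
    o <- order(les, ch, start(u))
    n <- length(u)
    same <- les[o][-1L] == les[o][-n] & ch[o][-1L] == ch[o][-n]
    bad <- same & start(u)[o][-1L] <= end(u)[o][-n]
    if (any(bad))
      return(sprintf("lesion %s has overlapping segments",
                     names(p)[les[o][-1L][bad][1L]]))
  }
  TRUE
})

#' Construct a LesionSet
#'
#' @param profiles A `GRangesList` (or list of `GRanges`) of per-lesion
#'   segments with a `copyNumber` metadata column; 0-based half-open
#'   coordinates are assumed to have been produced by [readSegments()] or
#'   equivalent.
#' @param lesionData A data.frame or `DataFrame` with `lesion_id`,
#'   `patient_id` and optional `ploidy`, `aberrant_cell_fraction`.
#' @return A [LesionSet-class] object.
#' @export
LesionSet <- function(profiles, lesionData) {
  if (is.list(profiles) && !is(profiles, "GRangesList"))
    profiles <- GRangesList(profiles)
  lesionData <- as(lesionData, "DataFrame")
  lesionData$lesion_id <- as.character(lesionData$lesion_id)
  lesionData$patient_id <- as.character(lesionData$patient_id)
  if (is.null(names(profiles)))
    names(profiles) <- lesionData$lesion_id
  profiles <- sortLesionProfiles(profiles)
  new("LesionSet", profiles = profiles, lesionData = lesionData)
}

sortLesionProfiles <- function(profiles) {
  lv <- intersect(AUTOSOMES, unique(as.character(unlist(seqnames(profiles), use.names = FALSE))))
  seqlevels(profiles) <- lv[order(as.integer(lv))]
  u <- unlist(profiles, use.names = FALSE)
  les <- rep(seq_along(profiles), lengths(profiles))
  o <- order(les, as.integer(seqnames(u)), start(u))
  relist(u[o], profiles)
}

#' @describeIn LesionSet-class Number of lesions.
#' @param x,object A `LesionSet`.
#' @export
setMethod("length", "LesionSet", function(x) length(x@profiles))

#' Accessors for LesionSet
#'
#' `profiles()` returns the per-lesion segment `GRangesList`; `lesionData()`
#' the per-lesion metadata; `lesionIDs()`, `patientIDs()` and `ploidies()`
#' the corresponding columns.
#'
#' @param x A [LesionSet-class].
#' @return See individual descriptions.
#' @name LesionSet-accessors
NULL

#' @rdname LesionSet-accessors
#' @export
profiles <- function(x) x@profiles

#' @rdname LesionSet-accessors
#' @export
lesionData <- function(x) x@lesionData

#' @rdname LesionSet-accessors
#' @export
lesionIDs <- function(x) {
  if (is(x, "LesionSet")) as.character(x@lesionData$lesion_id)
  else as.character(colData(x)$lesion_id)
}

#' @rdname LesionSet-accessors
#' @export
patientIDs <- function(x) {
  if (is(x, "LesionSet")) as.character(x@lesionData$patient_id)
  else as.character(colData(x)$patient_id)
}

#' @rdname LesionSet-accessors
#' @export
ploidies <- function(x) {
  d <- if (is(x, "LesionSet")) x@lesionData else colData(x)
  if (is.null(d$ploidy)) rep(NA_real_, nrow(d)) else as.numeric(d$ploidy)
}

#' Subset a LesionSet by lesion
#' @param x A `LesionSet`.
#' @param i Index, logical, or lesion-id character vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "LesionSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, lesionIDs(x))
  initialize(x, profiles = x@profiles[i], lesionData = x@lesionData[i, , drop = FALSE])
})

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet with %d lesion(s) from %d patient(s)\n",
              length(object), length(unique(patientIDs(object)))))
  segs <- sum(lengths(object@profiles))
  cat(sprintf("  %d segments over %s covered bp\n", segs,
              format(sum(as.numeric(sum(width(object@profiles)))), big.mark = ",")))
  cat(sprintf("  lesionData columns: %s\n",
              paste(colnames(object@lesionData), collapse = ", ")))
})

#' RegionMatrix: harmonized region-by-lesion copy numbers
#'
#' A `RangedSummarizedExperiment` whose rows are the smallest genomic regions
#' of overlap across all lesions (the partition induced by the union of all
#' samples' segment breakpoints), with a `copyNumber` assay. A matrix entry
#' is `NA` where the lesion has no segment covering the region. Column data
#' carry `lesion_id`, `patient_id` and optional `ploidy`.
#'
#' @export
setClass("RegionMatrix", contains = "RangedSummarizedExperiment")

setValidity("RegionMatrix", function(object) {
  if (!"copyNumber" %in% assayNames(object))
    return("RegionMatrix requires a 'copyNumber' assay")
  if (!isDisjoint(rowRanges(object)))
    return("regions must be non-overlapping")
  TRUE
})

#' CallMatrix: ternary gain/neutral/loss calls on harmonized regions
#'
#' Extends [RegionMatrix-class] with a `calls` assay in \{-1, 0, +1\}
#' (`NA` where the copy number is missing), a per-lesion `baseline` column
#' (the length-weighted median genome-wide copy number), and the calling
#' thresholds in `metadata()`.
#'
#' @export
setClass("CallMatrix", contains = "RegionMatrix")

setValidity("CallMatrix", function(object) {
  if (!"calls" %in% assayNames(object))
    return("CallMatrix requires a 'calls' assay")
  if (is.null(colData(object)$baseline))
    return("CallMatrix requires a per-lesion baseline column")
  cl <- assay(object, "calls")
  if (!all(cl %in% c(-1, 0, 1) | is.na(cl)))
    return("calls must be -1, 0, +1 or NA")
  TRUE
})

#' @describeIn RegionMatrix-class Copy-number assay matrix (regions x lesions).
#' @param x A `RegionMatrix`.
#' @export
copyNumber <- function(x) assay(x, "copyNumber")

#' @describeIn RegionMatrix-class Region widths in base pairs.
#' @export
regionLengths <- function(x) width(rowRanges(x))

#' @describeIn CallMatrix-class Ternary call matrix (regions x lesions).
#' @param x A `CallMatrix`.
#' @export
cnaCalls <- function(x) assay(x, "calls")

#' @describeIn CallMatrix-class Per-lesion median genome-wide copy number.
#' @export
baselines <- function(x) {
  b <- colData(x)$baseline
  names(b) <- lesionIDs(x)
  b
}

#' @describeIn CallMatrix-class Named gain/loss thresholds used for calling.
#' @export
callThresholds <- function(x)
  unlist(metadata(x)[c("gain_threshold", "loss_threshold")])

setMethod("show", "RegionMatrix", function(object) {
  cat(sprintf("%s: %d regions x %d lesions (%d patients)\n",
              class(object), nrow(object), ncol(object),
              length(unique(patientIDs(object)))))
  cat(sprintf("  assays: %s\n", paste(assayNames(object), collapse = ", ")))
  if (is(object, "CallMatrix"))
    cat(sprintf("  thresholds: gain >= %+g, loss <= %+g (vs per-lesion median)\n",
                metadata(object)$gain_threshold, metadata(object)$loss_threshold))
})
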