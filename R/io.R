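#' @importFrom utils read.delim write.table packageVersion
NULL

MUTATION_GENES <- c("KRAS", "NRAS", "BRAF", "TP53")
MUTATION_LEVELS <- c("mutated", "wild-type", "unknown")
EVENT_LEVELS <- c("CRC death", "other death", "alive")

chromNormalize <- function(x) sub("^chr", "", as.character(x))

readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""))
}

#' Read segmented copy-number profiles (SEG-style TSV)
#'
#' Reads a tab-delimited segment file with header columns
#' `sample, chrom, start, end, value` where coordinates follow the SEG
#' convention (1-based, inclusive). Coordinates are converted to the
#' internal 0-based half-open convention. Rows on chromosomes X or Y are
#' dropped (with a message); the analysis is autosome-only.
#'
#' @param path Path to the tab-delimited file.
#' @param dialect `"absolute_cn"` if `value` is the total copy number;
#'   `"log2_ratio"` if `value` is a log2 ratio against a diploid baseline,
#'   converted as \eqn{2 \cdot 2^{value}}.
#' @param lesionData Optional data.frame with `lesion_id`, `patient_id`
#'   (and optionally `ploidy`) to attach; by default every sample becomes
#'   its own patient.
#' @return A [LesionSet-class] with one profile per distinct sample.
#' @export
readSegments <- function(path, dialect = c("absolute_cn", "log2_ratio"),
                         lesionData = NULL) {
  dialect <- match.arg(dialect)
  df <- readTsv(path)
  need <- c("sample", "chrom", "start", "end", "value")
  if (!all(need %in% colnames(df)))
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  df$chrom <- chromNormalize(df$chrom)
  sex <- df$chrom %in% c("X", "Y")
  if (any(sex)) {
    message(sum(sex), " segment(s) on chromosomes X/Y dropped")
    df <- df[!sex, , drop = FALSE]
  }
  unknown <- setdiff(unique(df$chrom), AUTOSOMES)
  if (length(unknown))
    stop("unknown chromosome label(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(df$start) || !is.numeric(df$end) || any(df$end < df$start))
    stop("malformed coordinates (need numeric start <= end, 1-based inclusive)")
  cn <- if (dialect == "log2_ratio") 2 * 2^df$value else df$value
  if (any(cn < 0, na.rm = TRUE))
    stop("negative copy number in sample(s): ",
         paste(unique(df$sample[cn < 0]), collapse = ", "))
  # SEG 1-based inclusive maps directly onto the 1-based closed IRanges
  # representation (identical information content to 0-based half-open)
  gr <- GRanges(df$chrom, IRanges(start = df$start, end = df$end),
                copyNumber = cn)
  grl <- split(gr, factor(df$sample, levels = unique(df$sample)))
  for (s in names(grl)) {
    g <- grl[[s]]
    if (!isDisjoint(g)) {
      ov <- findOverlaps(g, drop.self = TRUE, drop.redundant = TRUE)
      i <- queryHits(ov)[1L]; j <- subjectHits(ov)[1L]
      stop(sprintf("overlapping segments in sample %s: chr%s:%d-%d and chr%s:%d-%d",
                   s, seqnames(g)[i], start(g)[i], end(g)[i],
                   seqnames(g)[j], start(g)[j], end(g)[j]))
    }
  }
  # lesion order is independent of input row order: lesionData order when
  # supplied, lexicographic sample order otherwise
  if (is.null(lesionData)) {
    grl <- grl[order(names(grl))]
    lesionData <- data.frame(lesion_id = names(grl), patient_id = names(grl))
  } else {
    lesionData <- as.data.frame(lesionData)
    missing <- setdiff(names(grl), lesionData$lesion_id)
    if (length(missing))
      stop("lesionData lacks entries for sample(s): ",
           paste(missing, collapse = ", "))
    lesionData <- lesionData[lesionData$lesion_id %in% names(grl), ,
                             drop = FALSE]
    grl <- grl[lesionData$lesion_id]
  }
  LesionSet(grl, lesionData)
}

#' Write a LesionSet as a SEG-style TSV
#'
#' Inverse of [readSegments()] for the `absolute_cn` dialect: coordinates
#' are emitted 1-based inclusive, so write-then-read round-trips exactly.
#'
#' @param x A [LesionSet-class].
#' @param path Output path.
#' @param hash Configuration fingerprint recorded in the header comment.
#' @return `path`, invisibly.
#' @export
writeSegments <- function(x, path, hash = "none") {
  stopifnot(is(x, "LesionSet"))
  gr <- unlist(profiles(x), use.names = FALSE)
  df <- data.frame(
    sample = rep(lesionIDs(x), lengths(profiles(x))),
    chrom = as.character(seqnames(gr)),
    start = start(gr), end = end(gr),
    value = formatNum(gr$copyNumber))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals (BED, 0-based half-open)
#'
#' Columns: chrom, start, end, name, and an optional fifth column flagging
#' cancer-critical genes (non-zero/TRUE = flagged). Genes on X/Y are
#' dropped; duplicate gene names are rejected.
#'
#' @param path Path to a BED file (no header; `#` comments allowed).
#' @return A `GRanges` with metadata columns `gene_name` and
#'   `cancer_critical`.
#' @export
readGeneIntervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gene interval file: ", path)
    return(GRanges(gene_name = character(0), cancer_critical = logical(0)))
  }
  parts <- strsplit(lines, "\t| +")
  ncol <- lengths(parts)
  if (any(ncol < 4L)) stop("BED gene file needs at least 4 columns")
  chrom <- chromNormalize(vapply(parts, `[`, "", 1L))
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  name <- vapply(parts, `[`, "", 4L)
  flag <- vapply(seq_along(parts), function(i)
    if (ncol[i] >= 5L) parts[[i]][5L] else "0", "")
  if (anyNA(start0) || anyNA(end0) || any(end0 <= start0))
    stop("malformed BED coordinates (need numeric start < end, 0-based half-open)")
  keep <- !chrom %in% c("X", "Y")
  chrom <- chrom[keep]; start0 <- start0[keep]; end0 <- end0[keep]
  name <- name[keep]; flag <- flag[keep]
  bad <- setdiff(unique(chrom), AUTOSOMES)
  if (length(bad)) stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(name))
    stop("duplicate gene name(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0),
                gene_name = name,
                cancer_critical = flag %in% c("1", "TRUE", "true"))
  lv <- intersect(AUTOSOMES, unique(chrom))
  seqlevels(gr) <- lv[order(as.integer(lv))]
  sort(gr)
}

#' Write gene intervals as BED
#' @param genes `GRanges` with `gene_name`, `cancer_critical`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneIntervals <- function(genes, path) {
  df <- data.frame(chrom = as.character(seqnames(genes)),
                   start = start(genes) - 1, end = end(genes),
                   name = genes$gene_name,
                   flag = as.integer(genes$cancer_critical))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a patient/lesion clinical table (TSV)
#'
#' One row per lesion (long format). Required columns: `patient_id`,
#' `lesion_id`, per-lesion mutation calls `KRAS`, `NRAS`, `BRAF`, `TP53`
#' (levels `mutated`/`wild-type`/`unknown`), `msi_status` (`MSI`/`MSS`),
#' `r_status` (`R0`/`R1`/`R2`), `extrahepatic_disease` (logical),
#' `followup_months` (non-negative) and `event` (`CRC death`/`other
#' death`/`alive`). Any further columns are carried along as clinical
#' covariates. An optional `level` column may mark dedicated
#' patient-level rows (`level == "patient"`), whose covariates then
#' override those on the lesion rows; every lesion row must then
#' reference a declared patient.
#'
#' @param path Path to the TSV.
#' @return A list with `lesions` (one row per lesion: ids plus mutation
#'   calls) and `patients` (one row per patient: clinical covariates,
#'   follow-up and event).
#' @export
readPatientTable <- function(path) {
  df <- readTsv(path)
  need <- c("patient_id", "lesion_id", MUTATION_GENES)
  if (!all(need %in% colnames(df)))
    stop("patient table must have columns: ", paste(need, collapse = ", "))
  if ("level" %in% colnames(df)) {
    pat <- df[df$level == "patient", , drop = FALSE]
    les <- df[df$level != "patient", , drop = FALSE]
    orphan <- setdiff(les$patient_id, pat$patient_id)
    if (length(orphan))
      stop("lesion row(s) reference unknown patient(s): ",
           paste(orphan, collapse = ", "))
  } else {
    les <- df
    pat <- df[!duplicated(df$patient_id), , drop = FALSE]
  }
  for (g in MUTATION_GENES) {
    bad <- setdiff(unique(stats::na.omit(les[[g]])), MUTATION_LEVELS)
    if (length(bad))
      stop(sprintf("invalid %s call(s): %s", g, paste(bad, collapse = ", ")))
  }
  if ("event" %in% colnames(pat)) {
    bad <- setdiff(unique(stats::na.omit(pat$event)), EVENT_LEVELS)
    if (length(bad))
      stop("invalid event label(s): ", paste(bad, collapse = ", "))
  }
  if ("followup_months" %in% colnames(pat) &&
      any(pat$followup_months < 0, na.rm = TRUE))
    stop("negative followup_months")
  lesionCols <- c("patient_id", "lesion_id", MUTATION_GENES)
  patientCols <- setdiff(colnames(pat), c("lesion_id", MUTATION_GENES, "level"))
  list(lesions = les[, lesionCols, drop = FALSE],
       patients = pat[, patientCols, drop = FALSE])
}

#' Write a lesion-level patient table
#' @param lesions Lesion-level data.frame (`patient_id`, `lesion_id`,
#'   mutation calls).
#' @param patients Patient-level data.frame (covariates, follow-up, event).
#' @param path Output path.
#' @param hash Configuration fingerprint for the header comment.
#' @return `path`, invisibly.
#' @export
writePatientTable <- function(lesions, patients, path, hash = "none") {
  merged <- merge(lesions, patients, by = "patient_id", sort = FALSE)
  merged <- merged[order(match(merged$lesion_id, lesions$lesion_id)), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(hash), con)
  write.table(merged, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region-level matrix (copy numbers or calls) as TSV
#'
#' Region coordinates occupy three leading columns (1-based inclusive,
#' matching the segment writer), followed by one column per lesion.
#'
#' @param x A [RegionMatrix-class] or [CallMatrix-class].
#' @param path Output path.
#' @param assay Which assay to write.
#' @param hash Configuration fingerprint for the header comment.
#' @return `path`, invisibly.
#' @export
writeRegionMatrix <- function(x, path, assay = assayNames(x)[1L], hash = "none") {
  rr <- rowRanges(x)
  m <- SummarizedExperiment::assay(x, assay)
  df <- data.frame(chrom = as.character(seqnames(rr)),
                   start = start(rr), end = end(rr),
                   apply(m, 2L, formatNum), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(outputHeader(hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
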