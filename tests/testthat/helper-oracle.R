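# Brute-force per-base-pair oracle for harmonization / calling / burden,
# plus random miniature cohort builders. The oracle expands every lesion
# into one copy-number value per base pair and never touches the
# package's region machinery.

# random miniature cohort: few short chromosomes, 2-5 lesions,
# integer-ish copy numbers, occasional coverage gaps
randomMiniCohort <- function(seed, nChrom = 3, chromLen = 300,
                             gapProb = 0.15, patients = 1) {
  set.seed(seed)
  chroms <- as.character(seq_len(nChrom))
  grl <- list()
  ld <- list()
  k <- 0
  for (p in seq_len(patients)) {
    nl <- sample(2:5, 1)
    for (j in seq_len(nl)) {
      k <- k + 1
      segs <- list()
      for (ch in chroms) {
        nbr <- sample(0:4, 1)
        brk <- sort(unique(c(1, chromLen + 1,
                             sample(2:chromLen, nbr, replace = FALSE))))
        s <- brk[-length(brk)]
        e <- brk[-1] - 1
        cn <- sample(c(0:6, 1.5, 2.5), length(s), replace = TRUE)
        keep <- runif(length(s)) > gapProb
        if (!any(keep)) keep[1] <- TRUE
        segs[[ch]] <- data.frame(chrom = ch, start = s[keep], end = e[keep],
                                 cn = cn[keep])
      }
      df <- do.call(rbind, segs)
      id <- sprintf("P%d_L%d", p, j)
      grl[[id]] <- GenomicRanges::GRanges(
        df$chrom, IRanges::IRanges(df$start, df$end), copyNumber = df$cn)
      ld[[id]] <- data.frame(lesion_id = id, patient_id = sprintf("P%d", p))
    }
  }
  LesionSet(GenomicRanges::GRangesList(grl), do.call(rbind, ld))
}

# expand one lesion profile to per-base values (NA where uncovered)
expandProfile <- function(gr, chromLens) {
  out <- lapply(names(chromLens), function(ch) rep(NA_real_, chromLens[[ch]]))
  names(out) <- names(chromLens)
  for (i in seq_along(gr)) {
    ch <- as.character(GenomicRanges::seqnames(gr))[i]
    out[[ch]][GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
      gr$copyNumber[i]
  }
  out
}

cohortChromLens <- function(ls) {
  u <- unlist(profiles(ls), use.names = FALSE)
  tapply(GenomicRanges::end(u), as.character(GenomicRanges::seqnames(u)), max)
}

# full per-base oracle: values, baselines, calls, burden per lesion
perBaseOracle <- function(ls, gain = 1, loss = -1) {
  chromLens <- cohortChromLens(ls)
  vals <- lapply(seq_along(ls), function(i)
    expandProfile(profiles(ls)[[i]], chromLens))
  names(vals) <- lesionIDs(ls)
  baselines <- vapply(vals, function(v) {
    x <- unlist(v, use.names = FALSE)
    stats::median(x[!is.na(x)])
  }, 0)
  calls <- lapply(seq_along(vals), function(i)
    lapply(vals[[i]], function(v) (v - baselines[i] >= gain) -
                                  (v - baselines[i] <= loss)))
  names(calls) <- lesionIDs(ls)
  burden <- vapply(calls, function(cl) {
    x <- unlist(cl, use.names = FALSE)
    100 * sum(x != 0, na.rm = TRUE) / sum(!is.na(x))
  }, 0)
  list(chromLens = chromLens, values = vals, baselines = baselines,
       calls = calls, burden = burden)
}

# expand a region-level matrix (copyNumber or calls assay) to per-base
expandRegionAssay <- function(x, assay, chromLens) {
  rr <- SummarizedExperiment::rowRanges(x)
  m <- SummarizedExperiment::assay(x, assay)
  lapply(seq_len(ncol(m)), function(i) {
    out <- lapply(names(chromLens), function(ch) rep(NA_real_, chromLens[[ch]]))
    names(out) <- names(chromLens)
    for (r in seq_along(rr)) {
      ch <- as.character(GenomicRanges::seqnames(rr))[r]
      out[[ch]][GenomicRanges::start(rr)[r]:GenomicRanges::end(rr)[r]] <- m[r, i]
    }
    out
  })
}

# split one random segment of every lesion in two (same value);
# downstream results must be invariant
subdivideSegments <- function(ls, seed) {
  set.seed(seed)
  grl <- as.list(profiles(ls))
  for (i in seq_along(grl)) {
    g <- grl[[i]]
    wide <- which(GenomicRanges::width(g) >= 2)
    if (!length(wide)) next
    k <- sample(wide, 1)
    s <- GenomicRanges::start(g)[k]
    e <- GenomicRanges::end(g)[k]
    cut <- sample(s:(e - 1), 1)
    left <- g[k]
    GenomicRanges::end(left) <- cut
    right <- g[k]
    GenomicRanges::start(right) <- cut + 1
    grl[[i]] <- sort(c(g[-k], left, right))
  }
  LesionSet(GenomicRanges::GRangesList(grl), lesionData(ls))
}

# independent recount of the discordant-gene fraction straight from the
# profiles: per gene midpoint, covering-segment copy number minus the
# lesion's ploidy, ternary call, then the discordant/aberrant ratio
recountDiscordant <- function(ls, genes, patient) {
  sel <- which(patientIDs(ls) == patient)
  pl <- ploidies(ls)[sel]
  mids <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(floor((GenomicRanges::start(genes) +
                            GenomicRanges::end(genes)) / 2), width = 1))
  calls <- vapply(seq_along(sel), function(k) {
    g <- profiles(ls)[[sel[k]]]
    hits <- GenomicRanges::findOverlaps(mids, g)
    cn <- rep(NA_real_, length(mids))
    cn[S4Vectors::queryHits(hits)] <- g$copyNumber[S4Vectors::subjectHits(hits)]
    d <- cn - pl[k]
    (d >= 1) - (d <= -1)
  }, numeric(length(mids)))
  calls <- matrix(calls, nrow = length(mids))
  aberrant <- apply(calls, 1, function(v) any(v != 0, na.rm = TRUE))
  if (!any(aberrant)) return(NA_real_)
  disc <- apply(calls[aberrant, , drop = FALSE], 1,
                function(v) length(unique(v[!is.na(v)])) > 1)
  sum(disc) / sum(aberrant)
}
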