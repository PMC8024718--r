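#' Synthetic genome models
#'
#' Chromosome lengths for the 22 autosomes, either at human scale
#' (hg19 assembly lengths, ~2.9e9 bp total) or as a miniature genome
#' (default 1 Mb per chromosome) small enough that tests can enumerate
#' base pairs. An attribute `parm_frac` gives the approximate p-arm
#' fraction per chromosome, used by the arm-level event placement prior.
#'
#' @param model `"mini"` or `"hg19"`.
#' @param chromLength Per-chromosome length for the miniature model.
#' @return Named numeric vector of lengths with attribute `parm_frac`.
#' @export
syntheticGenome <- function(model = c("mini", "hg19"), chromLength = 1e6) {
  model <- match.arg(model)
  parm <- c(0.50, 0.38, 0.46, 0.26, 0.27, 0.36, 0.38, 0.31, 0.35, 0.30,
            0.40, 0.27, 0.15, 0.16, 0.19, 0.41, 0.30, 0.22, 0.42, 0.44,
            0.27, 0.29)
  lens <- if (model == "hg19")
    c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
      159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
      115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
      59128983, 63025520, 48129895, 51304566)
  else rep(chromLength, 22)
  structure(setNames(lens, AUTOSOMES), parm_frac = setNames(parm, AUTOSOMES))
}

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of generated cohorts: multi-lesion
#' copy-number profiles with truncal (shared) and lesion-private
#' aberrations placed with a CRC-typical arm-level prior (recurrent gains
#' on 7p/7q/8q/13q/20q, losses on 1p/4p/4q/8p/17p/18p/18q), occasional
#' injected high-level amplifications, mutually exclusive KRAS/NRAS/BRAF
#' driver mutations plus TP53 at the observed cohort prevalences
#' (0.427/0.047/0.018/0.725), clinical covariates, and exponential
#' cancer-specific survival with stratum-specific hazards plus
#' other-cause and administrative censoring.
#'
#' @param nPatients Number of patients.
#' @param lesionsPerPatient Integer range (default 2-8).
#' @param lesionCountProbs Optional sampling weights over that range.
#' @param genome From [syntheticGenome()].
#' @param truncalEventRate Expected truncal CNA events per patient.
#' @param privateEventRate Expected private CNA events per lesion
#'   (scaled per patient by a lognormal multiplier with
#'   `privateRateSdlog`; 0 disables all intermetastatic divergence,
#'   including amplification amplitude differences).
#' @param eventLengthMeanlog,eventLengthSdlog Lognormal event length as a
#'   fraction of the chromosome.
#' @param gainFraction Probability that an event is a gain.
#' @param gainMagProbs,lossMagProbs Named magnitude distributions
#'   (copies; losses applied negatively, copy number floored at 0).
#' @param armBias,armWeight Use the recurrent-arm prior with this weight
#'   (1 = uniform).
#' @param aneuploidFraction,aneuploidPloidy Fraction of patients at an
#'   elevated baseline ploidy, and that ploidy.
#' @param ampProbability Probability a patient carries high-level
#'   amplification events.
#' @param ampEventsProbs Weights for 1-3 events per amplified patient.
#' @param ampClassProbs Concordance-class mix of injected amplifications.
#' @param ampMaxRange Range of the per-event maximum additional copies.
#' @param mutationPrevalence Named patient-level prevalences (KRAS, NRAS,
#'   BRAF mutually exclusive; TP53 independent).
#' @param msiRate,rStatusProbs,extrahepaticRate,maleFraction Clinical
#'   covariate distributions.
#' @param baseHazard Monthly cancer-death hazard of the reference stratum.
#' @param groupHazardRatios Named hazard ratios per mutation group.
#' @param cnaHighHazardRatio Multiplier for patients with a high latent
#'   CNA-divergence propensity.
#' @param privateRateSdlog Lognormal sd of the per-patient private-rate
#'   multiplier.
#' @param otherCauseRate Monthly other-cause death hazard.
#' @param adminCensorRange Uniform administrative censoring window
#'   (months).
#' @param nGenes,cancerCriticalFraction,geneLength Gene interval model
#'   (default gene length: mean chromosome length / 1000).
#' @return A validated list of class `cohort_config`.
#' @export
cohortConfig <- function(nPatients = 64,
                         lesionsPerPatient = c(2L, 8L),
                         lesionCountProbs = NULL,
                         genome = syntheticGenome("mini"),
                         truncalEventRate = 8,
                         privateEventRate = 3,
                         eventLengthMeanlog = log(0.10),
                         eventLengthSdlog = 0.7,
                         gainFraction = 0.5,
                         gainMagProbs = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                         lossMagProbs = c("1" = 0.85, "2" = 0.15),
                         armBias = TRUE,
                         armWeight = 6,
                         aneuploidFraction = 0.45,
                         aneuploidPloidy = 3.4,
                         ampProbability = 0.34,
                         ampEventsProbs = c(0.5, 0.35, 0.15),
                         ampClassProbs = c(homogeneous = 0.31,
                                           intermediate_concordant = 0.38,
                                           heterogeneous = 0.31),
                         ampMaxRange = c(15, 60),
                         mutationPrevalence = c(KRAS = 0.427, NRAS = 0.047,
                                                BRAF = 0.018, TP53 = 0.725),
                         msiRate = 1 / 171,
                         rStatusProbs = c(R0 = 71, R1 = 95, R2 = 5) / 171,
                         extrahepaticRate = 32 / 171,
                         maleFraction = 106 / 171,
                         baseHazard = log(2) / 48,
                         groupHazardRatios = c(double_wt = 1, tp53_only = 2.3,
                                               ras_braf_only = 2.6,
                                               co_mut = 4.1),
                         cnaHighHazardRatio = 1.6,
                         privateRateSdlog = 0.5,
                         otherCauseRate = 0.002,
                         adminCensorRange = c(24, 120),
                         nGenes = 200,
                         cancerCriticalFraction = 0.15,
                         geneLength = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$geneLength)) cfg$geneLength <- round(mean(genome) / 1000)
  mp <- cfg$mutationPrevalence
  if (any(mp < 0 | mp > 1)) stop("mutation prevalences must be in [0, 1]")
  if (sum(mp[c("KRAS", "NRAS", "BRAF")]) > 1)
    stop("infeasible config: KRAS+NRAS+BRAF prevalence exceeds 1")
  if (cfg$truncalEventRate < 0 || cfg$privateEventRate < 0)
    stop("event rates must be >= 0")
  if (cfg$nPatients < 1) stop("nPatients must be >= 1")
  stopifnot(length(cfg$lesionsPerPatient) == 2L,
            cfg$lesionsPerPatient[1] >= 1,
            cfg$lesionsPerPatient[2] >= cfg$lesionsPerPatient[1])
  structure(cfg, class = "cohort_config")
}

# Arm table with event-placement weights, one row per chromosome arm.
armTable <- function(genome, armWeight, armBias) {
  parm <- attr(genome, "parm_frac")
  gainArms <- c("7p", "7q", "8q", "13q", "20q")
  lossArms <- c("1p", "4p", "4q", "8p", "17p", "18p", "18q")
  rows <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    pend <- max(1, round(L * parm[[ch]]))
    data.frame(chrom = ch, arm = c("p", "q"),
               start = c(1, pend + 1), end = c(pend, L))
  })
  tab <- do.call(rbind, rows)
  tab$name <- paste0(tab$chrom, tab$arm)
  w <- if (armBias) armWeight else 1
  tab$gain_w <- ifelse(tab$name %in% gainArms & armBias, w, 1)
  tab$loss_w <- ifelse(tab$name %in% lossArms & armBias, w, 1)
  tab$len <- tab$end - tab$start + 1
  tab
}

# Draw n CNA events (chrom, start, end, delta) from the arm prior.
drawEvents <- function(n, cfg, arms) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), delta = numeric(0)))
  isGain <- runif(n) < cfg$gainFraction
  armIdx <- integer(n)
  if (any(isGain))
    armIdx[isGain] <- sample.int(nrow(arms), sum(isGain), replace = TRUE,
                                 prob = arms$gain_w * arms$len)
  if (any(!isGain))
    armIdx[!isGain] <- sample.int(nrow(arms), sum(!isGain), replace = TRUE,
                                  prob = arms$loss_w * arms$len)
  a <- arms[armIdx, , drop = FALSE]
  L <- unname(cfg$genome[a$chrom])
  len <- pmax(1, pmin(a$len, round(rlnorm(n, cfg$eventLengthMeanlog,
                                          cfg$eventLengthSdlog) * L)))
  s <- floor(runif(n, a$start, a$end - len + 2))
  mag <- numeric(n)
  if (any(isGain))
    mag[isGain] <- as.numeric(sample(names(cfg$gainMagProbs), sum(isGain),
                                     replace = TRUE, prob = cfg$gainMagProbs))
  if (any(!isGain))
    mag[!isGain] <- -as.numeric(sample(names(cfg$lossMagProbs), sum(!isGain),
                                       replace = TRUE, prob = cfg$lossMagProbs))
  data.frame(chrom = a$chrom, start = s, end = s + len - 1, delta = mag,
             row.names = NULL)
}

# Assemble one lesion profile: constant baseline, additive events,
# absolute-value overrides (amplifications), copy number floored at 0.
# Builds plain vectors per chromosome and constructs a single GRanges.
buildProfile <- function(genome, baseline, events, overrides = NULL) {
  z <- buildProfileCore(genome, baseline, events, overrides)
  GRanges(z$chrom, IRanges(z$start, z$end), copyNumber = z$cn,
          seqinfo = Seqinfo(names(genome)))
}

buildProfileCore <- function(genome, baseline, events, overrides = NULL) {
  chroms <- starts <- ends <- cns <- vector("list", length(genome))
  for (ci in seq_along(genome)) {
    ch <- names(genome)[ci]
    L <- genome[[ci]]
    ev <- events[events$chrom == ch, , drop = FALSE]
    ov <- if (is.null(overrides)) NULL
          else overrides[overrides$chrom == ch, , drop = FALSE]
    breaks <- sort(unique(c(1, L + 1, ev$start, ev$end + 1,
                            ov$start, ov$end + 1)))
    breaks <- breaks[breaks >= 1 & breaks <= L + 1]
    s <- breaks[-length(breaks)]
    e <- breaks[-1] - 1
    mid <- (s + e) / 2
    cn <- rep(baseline, length(s))
    for (k in seq_len(nrow(ev)))
      cn <- cn + ifelse(mid >= ev$start[k] & mid <= ev$end[k], ev$delta[k], 0)
    if (!is.null(ov)) for (k in seq_len(nrow(ov))) {
      inside <- mid >= ov$start[k] & mid <= ov$end[k]
      cn[inside] <- ov$value[k]
    }
    cn <- pmax(cn, 0)
    r <- rle(cn)
    idx <- cumsum(r$lengths)
    first <- idx - r$lengths + 1
    chroms[[ci]] <- rep(ch, length(idx))
    starts[[ci]] <- s[first]
    ends[[ci]] <- e[idx]
    cns[[ci]] <- r$values
  }
  list(chrom = unlist(chroms), start = unlist(starts), end = unlist(ends),
       cn = unlist(cns))
}

drawAmpCopies <- function(nl, class, maxVal, cfg) {
  if (cfg$privateEventRate == 0 || nl == 1L) return(rep(maxVal, nl))
  v <- switch(class,
    homogeneous = runif(nl, cfg$ampMaxRange[1], maxVal),
    intermediate_concordant = runif(nl, cfg$ampConfigIntermediate, maxVal),
    heterogeneous = runif(nl, 0, maxVal))
  v[1L] <- maxVal
  if (class == "intermediate_concordant")
    v[2L] <- runif(1, cfg$ampConfigIntermediate, cfg$ampMaxRange[1])
  if (class == "heterogeneous")
    v[2L] <- runif(1, 0, cfg$ampConfigIntermediate)
  sample(v)
}

#' Generate a synthetic multi-lesion cohort
#'
#' Draws a full cohort (lesion profiles, gene intervals, clinical/
#' mutation table) under a [cohortConfig()] together with a truth record
#' for parameter-recovery tests. Identical `(config, seed)` pairs give
#' identical output.
#'
#' @param config A [cohortConfig()].
#' @param seed Integer RNG seed.
#' @return list with `lesions` ([LesionSet-class]), `genes` (`GRanges`),
#'   `patientTable` (list of `lesions`/`patients` data.frames as
#'   returned by [readPatientTable()]), and `truth` (per-patient event
#'   lists, true discordant-gene fraction, mutation group, latent
#'   CNA-divergence flag, generative hazard, per-lesion ploidy).
#' @export
generateCohort <- function(config = cohortConfig(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  cfg <- config
  cfg$ampConfigIntermediate <- 5  # concordance-class boundary used in drawing
  genome <- cfg$genome
  arms <- armTable(genome, cfg$armWeight, cfg$armBias)

  # gene intervals
  gl <- cfg$geneLength
  chrProb <- genome / sum(genome)
  gchrom <- sample(names(genome), cfg$nGenes, replace = TRUE, prob = chrProb)
  gstart <- floor(runif(cfg$nGenes, 1, pmax(2, genome[gchrom] - gl)))
  genes <- GRanges(gchrom, IRanges(gstart, width = gl),
                   gene_name = sprintf("G%04d", seq_len(cfg$nGenes)),
                   cancer_critical = runif(cfg$nGenes) < cfg$cancerCriticalFraction)
  lv <- AUTOSOMES[AUTOSOMES %in% unique(gchrom)]
  seqlevels(genes) <- lv
  genes <- sort(genes)

  profilesList <- list()
  lesionRows <- list()
  lesTabRows <- list()
  patRows <- list()
  truthPat <- list()
  mp <- cfg$mutationPrevalence

  for (i in seq_len(cfg$nPatients)) {
    pid <- sprintf("P%03d", i)
    rng <- seq(cfg$lesionsPerPatient[1], cfg$lesionsPerPatient[2])
    nl <- if (length(rng) == 1L) rng
          else sample(rng, 1L, prob = cfg$lesionCountProbs)
    ploidy <- if (runif(1) < cfg$aneuploidFraction) cfg$aneuploidPloidy else 2
    privMult <- rlnorm(1, 0, cfg$privateRateSdlog)
    privRate <- cfg$privateEventRate * privMult
    truncal <- drawEvents(rpois(1, cfg$truncalEventRate), cfg, arms)
    private <- lapply(seq_len(nl), function(j)
      drawEvents(rpois(1, privRate), cfg, arms))

    # amplification injection
    amps <- NULL
    if (runif(1) < cfg$ampProbability) {
      nAmp <- sample(seq_along(cfg$ampEventsProbs), 1L,
                     prob = cfg$ampEventsProbs)
      gi <- unique(sample(seq_len(cfg$nGenes), nAmp,
                          prob = ifelse(genes$cancer_critical, 5, 1)))
      amps <- do.call(rbind, lapply(gi, function(k) {
        class <- sample(names(cfg$ampClassProbs), 1L, prob = cfg$ampClassProbs)
        maxVal <- runif(1, cfg$ampMaxRange[1], cfg$ampMaxRange[2])
        copies <- drawAmpCopies(nl, class, maxVal, cfg)
        pad <- cfg$geneLength
        ch <- as.character(seqnames(genes)[k])
        data.frame(chrom = ch,
                   start = max(1, start(genes)[k] - pad),
                   end = min(genome[[ch]], end(genes)[k] + pad),
                   gene = genes$gene_name[k], class = class,
                   copies = I(list(copies)))
      }))
    }

    lids <- sprintf("%s_L%d", pid, seq_len(nl))
    for (j in seq_len(nl)) {
      ov <- if (is.null(amps)) NULL else
        data.frame(chrom = amps$chrom, start = amps$start, end = amps$end,
                   value = ploidy + vapply(amps$copies, `[`, 0, j))
      profilesList[[lids[j]]] <-
        buildProfileCore(genome, ploidy, rbind(truncal, private[[j]]), ov)
      lesionRows[[lids[j]]] <- data.frame(lesion_id = lids[j],
                                          patient_id = pid, ploidy = ploidy)
    }

    # mutations: mutually exclusive RAS/BRAF, independent TP53
    rbGene <- sample(c("KRAS", "NRAS", "BRAF", "none"), 1L,
                     prob = c(mp["KRAS"], mp["NRAS"], mp["BRAF"],
                              1 - sum(mp[c("KRAS", "NRAS", "BRAF")])))
    tp53 <- runif(1) < mp["TP53"]
    status <- setNames(rep("wild-type", 4L), MUTATION_GENES)
    if (rbGene != "none") status[rbGene] <- "mutated"
    if (tp53) status["TP53"] <- "mutated"
    group <- as.character(classifyMutationGroup(
      as.data.frame(as.list(status), stringsAsFactors = FALSE)))

    cnaHigh <- privMult > 1
    hazard <- cfg$baseHazard * cfg$groupHazardRatios[[group]] *
      if (cnaHigh) cfg$cnaHighHazardRatio else 1
    tCrc <- rexp(1, hazard)
    tOther <- rexp(1, cfg$otherCauseRate)
    tAdmin <- runif(1, cfg$adminCensorRange[1], cfg$adminCensorRange[2])
    fu <- min(tCrc, tOther, tAdmin)
    event <- if (fu == tCrc) "CRC death"
             else if (fu == tOther) "other death" else "alive"

    lesTabRows[[pid]] <- data.frame(patient_id = pid, lesion_id = lids,
                                    KRAS = status["KRAS"], NRAS = status["NRAS"],
                                    BRAF = status["BRAF"], TP53 = status["TP53"],
                                    row.names = NULL)
    patRows[[pid]] <- data.frame(
      patient_id = pid,
      msi_status = if (runif(1) < cfg$msiRate) "MSI" else "MSS",
      r_status = sample(names(cfg$rStatusProbs), 1L, prob = cfg$rStatusProbs),
      extrahepatic_disease = runif(1) < cfg$extrahepaticRate,
      sex = if (runif(1) < cfg$maleFraction) "male" else "female",
      age = round(min(85, max(21, rnorm(1, 66, 10)))),
      size_largest_mm = round(rlnorm(1, log(27), 0.5)),
      n_lesions = nl,
      chemo_cycles = rpois(1, 4) + 1L,
      followup_months = round(fu, 1),
      event = event)

    truthPat[[pid]] <- list(
      n_lesions = nl, ploidy = rep(ploidy, nl), private_rate = privRate,
      private_multiplier = privMult, cna_high = cnaHigh, group = group,
      hazard = hazard, truncal = truncal, private = private, amps = amps,
      discordant_fraction = NA_real_)
  }

  u <- GRanges(unlist(lapply(profilesList, `[[`, "chrom")),
               IRanges(unlist(lapply(profilesList, `[[`, "start")),
                       unlist(lapply(profilesList, `[[`, "end"))),
               copyNumber = unlist(lapply(profilesList, `[[`, "cn")),
               seqinfo = Seqinfo(names(genome)))
  part <- PartitioningByEnd(cumsum(vapply(profilesList,
                                          function(z) length(z$cn), 0L)),
                            names = names(profilesList))
  lesionSet <- LesionSet(relist(u, part), do.call(rbind, lesionRows))
  truth <- list(config = config, seed = seed, patients = truthPat)
  for (pid in names(truthPat))
    truth$patients[[pid]]$discordant_fraction <-
      truthDiscordantFraction(truthPat[[pid]], genes)
  list(lesions = lesionSet, genes = genes,
       patientTable = list(lesions = do.call(rbind, lesTabRows),
                           patients = do.call(rbind, patRows)),
       truth = truth)
}

# Generative discordant-gene fraction: gene-wise ternary call per lesion
# from the event bookkeeping (delta at the gene midpoint relative to
# ploidy; amplification overrides take precedence), then the fraction of
# aberrant genes not shared identically by all lesions.
truthDiscordantFraction <- function(tp, genes) {
  if (tp$n_lesions < 2L) return(NA_real_)
  midPos <- floor((start(genes) + end(genes)) / 2)
  midChr <- as.character(seqnames(genes))
  deltaAt <- function(events) {
    d <- numeric(length(midPos))
    for (k in seq_len(NROW(events))) {
      inside <- midChr == events$chrom[k] &
        midPos >= events$start[k] & midPos <= events$end[k]
      d[inside] <- d[inside] + events$delta[k]
    }
    d
  }
  base <- deltaAt(tp$truncal)
  calls <- vapply(seq_len(tp$n_lesions), function(j) {
    d <- base + deltaAt(tp$private[[j]])
    if (!is.null(tp$amps)) for (k in seq_len(nrow(tp$amps))) {
      inside <- midChr == tp$amps$chrom[k] &
        midPos >= tp$amps$start[k] & midPos <= tp$amps$end[k]
      d[inside] <- tp$amps$copies[[k]][j]
    }
    (d >= 1) - (d <= -1)
  }, numeric(length(midPos)))
  calls <- matrix(calls, nrow = length(midPos))
  aberrant <- apply(calls, 1L, function(v) any(v != 0))
  if (!any(aberrant)) return(NA_real_)
  discordant <- apply(calls[aberrant, , drop = FALSE], 1L,
                      function(v) length(unique(v)) > 1L)
  sum(discordant) / sum(aberrant)
}

#' Inject an amplification into a patient's lesion profiles
#'
#' Overwrites the copy number over `region` with ploidy plus the given
#' per-lesion additional copies, leaving the rest of each profile
#' untouched.
#'
#' @param x A [LesionSet-class].
#' @param patient Patient id whose lesions receive the amplification.
#' @param region A length-1 `GRanges` (must lie within the profiles'
#'   chromosomes).
#' @param copies Numeric per-lesion additional copies, in the patient's
#'   lesion order (or named by lesion id).
#' @return The modified [LesionSet-class].
#' @export
injectAmplification <- function(x, patient, region, copies) {
  stopifnot(is(x, "LesionSet"), length(region) == 1L)
  sel <- which(patientIDs(x) == patient)
  if (!length(sel)) stop("unknown patient: ", patient)
  if (length(copies) != length(sel))
    stop("copies must have one value per lesion of the patient")
  if (!is.null(names(copies))) copies <- copies[lesionIDs(x)[sel]]
  pl <- lesionPloidy(x)
  grl <- as.list(profiles(x))
  ch <- as.character(seqnames(region))
  for (k in seq_along(sel)) {
    i <- sel[k]
    g <- grl[[i]]
    if (!ch %in% as.character(seqnames(g)) ||
        end(region) > max(end(g)[as.character(seqnames(g)) == ch]))
      stop("region outside the covered genome")
    keep <- setdiff(granges(g), region)
    hits <- findOverlaps(keep, g, type = "within")
    keep <- keep[queryHits(hits)]
    keep$copyNumber <- g$copyNumber[subjectHits(hits)]
    amp <- region
    amp$copyNumber <- pl[i] + copies[k]
    grl[[i]] <- sort(c(keep, amp))
  }
  LesionSet(GRangesList(grl), lesionData(x))
}

#' Bundled deterministic fixtures
#'
#' Registry of miniature cohorts used throughout the test-suite and in
#' examples:
#' * `"table1"`: six patients with constant diploid genomes (hg19
#'   scale) carrying 15 injected high-level amplification events over
#'   cancer-critical genes whose per-lesion additional-copy ranges span
#'   all three concordance classes.
#' * `"null_survival"`: cohort with all stratum hazards equal (log-rank
#'   null holds by construction).
#' * `"gradient_het"`: eight cohorts over an increasing private-event
#'   rate, all other settings shared.
#' * `"paper_like"`: 64 patients, ~200 lesions, human-scale genome,
#'   defaults otherwise.
#'
#' @param name Fixture name.
#' @param seed Optional seed override (fixtures have fixed defaults).
#' @return For `"gradient_het"` a list of cohorts with their rate levels;
#'   otherwise a cohort list as from [generateCohort()] (the `"table1"`
#'   fixture additionally carries `expected`, the per-event expected
#'   class table).
#' @export
makeFixture <- function(name, seed = NULL) {
  switch(name,
    table1 = makeTable1Fixture(),
    null_survival = generateCohort(
      cohortConfig(nPatients = 150,
                   groupHazardRatios = c(double_wt = 1, tp53_only = 1,
                                         ras_braf_only = 1, co_mut = 1),
                   cnaHighHazardRatio = 1,
                   genome = syntheticGenome("mini", 5e4), nGenes = 60),
      seed = if (is.null(seed)) 11L else seed),
    gradient_het = {
      levels <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
      base <- if (is.null(seed)) 7L else seed
      cohorts <- lapply(seq_along(levels), function(k)
        generateCohort(cohortConfig(nPatients = 8,
                                    privateEventRate = levels[k],
                                    ampProbability = 0,
                                    genome = syntheticGenome("mini", 5e4),
                                    nGenes = 300),
                       seed = base + k))
      list(levels = levels, cohorts = cohorts)
    },
    paper_like = generateCohort(
      cohortConfig(nPatients = 64,
                   genome = syntheticGenome("hg19"),
                   lesionCountProbs = c(0.35, 0.28, 0.15, 0.10,
                                        0.06, 0.04, 0.02),
                   nGenes = 500),
      seed = if (is.null(seed)) 64L else seed),
    stop("unknown fixture: ", name))
}

# The 15 printed amplification events: patient, region, genes,
# per-lesion additional-copy range, expected concordance class.
# Event 13's start is nudged +1 bp so that the two distinct chr17
# amplicons of patient T6 stay separated by a sliver of baseline.
table1Events <- function() {
  df <- read.table(header = TRUE, text = "
patient nl chrom start end genes min max class
T1 7 6 39863162 42671542 CCND3,TFEB 14 16 intermediate_concordant
T2 3 1 65183880 66527443 JAK1 10 15 intermediate_concordant
T2 3 7 54576560 56118007 EGFR 37 58 homogeneous
T2 3 7 90792390 92573683 AKAP9,CDK6 0 22 heterogeneous
T2 3 18 41497284 42716881 SETBP1 18 20 homogeneous
T3 2 12 4279446 4431071 CCND2 29 47 homogeneous
T3 2 16 40873444 53153010 CYLD,TOX3 0 16 heterogeneous
T4 6 13 20528021 21570265 ZMYM2 3 15 heterogeneous
T4 6 13 28302602 28662578 CDX2,FLT3 3 15 heterogeneous
T5 5 17 37604254 37701703 CDK12 16 41 homogeneous
T5 5 17 37704051 38191836 ERBB2 41 55 homogeneous
T6 2 17 36841569 37669141 LASP1,MLLT6 12 18 intermediate_concordant
T6 2 17 37669143 37993556 CDK12,ERBB2 17 18 homogeneous
T6 2 17 53268056 53593625 HLF 14 18 intermediate_concordant
T6 2 17 56250122 57541594 RNF43 14 18 intermediate_concordant
", stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df
}

table1Genes <- function() {
  g <- read.table(header = TRUE, text = "
chrom start end name critical
6 41651000 41703000 TFEB 1
6 41902500 42020000 CCND3 1
1 65298000 65432000 JAK1 1
7 55086714 55324313 EGFR 1
7 91570000 91739000 AKAP9 1
7 92234000 92465000 CDK6 1
18 42260000 42648000 SETBP1 1
12 4382902 4414516 CCND2 1
16 50775000 50835000 CYLD 1
16 52471000 52580000 TOX3 0
13 20532810 20665944 ZMYM2 1
13 28536204 28543505 CDX2 1
13 28577411 28662578 FLT3 1
17 37669200 37690800 CDK12 1
17 37710000 37990000 ERBB2 1
17 37025000 37057000 LASP1 1
17 37205000 37225000 MLLT6 1
17 53342000 53402000 HLF 1
17 56429000 56494000 RNF43 1
", stringsAsFactors = FALSE)
  gr <- GRanges(as.character(g$chrom), IRanges(g$start, g$end),
                gene_name = g$name, cancer_critical = g$critical == 1)
  lv <- AUTOSOMES[AUTOSOMES %in% as.character(g$chrom)]
  seqlevels(gr) <- lv
  sort(gr)
}

makeTable1Fixture <- function() {
  genome <- syntheticGenome("hg19")
  events <- table1Events()
  patients <- unique(events[, c("patient", "nl")])
  profilesList <- list()
  lesionRows <- list()
  for (r in seq_len(nrow(patients))) {
    pid <- patients$patient[r]; nl <- patients$nl[r]
    lids <- sprintf("%s_L%d", pid, seq_len(nl))
    ev <- events[events$patient == pid, , drop = FALSE]
    for (j in seq_len(nl)) {
      ov <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                       value = 2 + vapply(seq_len(nrow(ev)), function(k)
                         seq(ev$min[k], ev$max[k], length.out = nl)[j], 0))
      empty <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), delta = numeric(0))
      profilesList[[lids[j]]] <- buildProfile(genome, 2, empty, ov)
      lesionRows[[lids[j]]] <- data.frame(lesion_id = lids[j],
                                          patient_id = pid, ploidy = 2)
    }
  }
  lesionSet <- LesionSet(GRangesList(profilesList), do.call(rbind, lesionRows))
  ld <- do.call(rbind, lesionRows)
  lesTab <- data.frame(patient_id = ld$patient_id, lesion_id = ld$lesion_id,
                       KRAS = "wild-type", NRAS = "wild-type",
                       BRAF = "wild-type", TP53 = "wild-type")
  patTab <- data.frame(patient_id = patients$patient, msi_status = "MSS",
                       r_status = "R0", extrahepatic_disease = FALSE,
                       sex = "male", age = 66, size_largest_mm = 27,
                       n_lesions = patients$nl, chemo_cycles = 4,
                       followup_months = 60, event = "alive")
  list(lesions = lesionSet, genes = table1Genes(),
       patientTable = list(lesions = lesTab, patients = patTab),
       expected = events)
}
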