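test_that("identical lesions have zero distance for any lesion count", {
  for (k in 2:5) {
    m <- matrix(rep(c(2, 3, 2, 4, 2, 1, 2, 2, 3, 2, 2, 5), k), ncol = k)
    expect_equal(as.numeric(hetEuclidean(m)), 0)
    expect_equal(as.numeric(hetVarianceFiltered(m)), 0)
    expect_equal(attr(hetVarianceFiltered(m), "status"), "no_variable_regions")
  }
})

test_that("two lesions differing by one copy in r regions score sqrt(r)", {
  for (r in c(1, 4, 9, 16)) {
    m <- cbind(rep(2, 20), c(rep(3, r), rep(2, 20 - r)))
    expect_equal(as.numeric(hetEuclidean(m)), sqrt(r))
  }
})

test_that("three lesions average the three pairwise distances", {
  m <- cbind(c(2, 2, 2, 2), c(3, 2, 2, 2), c(2, 4, 4, 2))
  d12 <- sqrt(1)
  d13 <- sqrt(4 + 4)
  d23 <- sqrt(1 + 4 + 4)
  expect_equal(as.numeric(hetEuclidean(m, minSharedRegions = 0)),
               mean(c(d12, d13, d23)))
})

test_that("correlation distance spans [0, 2] and flags constant lesions", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  prop <- cbind(x, 2 * x + 1)
  expect_equal(as.numeric(hetCorrelation(prop)), 0)
  anti <- cbind(x, -x)
  expect_equal(as.numeric(hetCorrelation(anti)), 2)
  const <- cbind(x, rep(2, 10))
  expect_true(is.na(hetCorrelation(const)))
  expect_equal(attr(hetCorrelation(const), "status"), "undefined")
})

test_that("discordant fraction counts aberrant genes not shared by all lesions", {
  # 10 aberrant genes, 3 discordant -> 0.3 (plus neutral genes ignored)
  m <- rbind(matrix(1, 7, 3),                    # concordant gains
             cbind(c(1, -1, 1), c(0, -1, 0), c(1, 0, 1)),  # 3 discordant
             matrix(0, 5, 3))                    # neutral
  expect_equal(as.numeric(hetDiscordantFraction(m)), 0.3)

  concordant <- rbind(matrix(1, 4, 2), matrix(0, 3, 2))
  expect_equal(as.numeric(hetDiscordantFraction(concordant)), 0)

  private <- rbind(diag(3), matrix(0, 2, 3))  # each aberration in one lesion
  expect_equal(as.numeric(hetDiscordantFraction(private)), 1)

  neutral <- matrix(0, 5, 3)
  expect_true(is.na(hetDiscordantFraction(neutral)))
  expect_equal(attr(hetDiscordantFraction(neutral), "status"),
               "no_aberrant_genes")
})

test_that("amplitude differences within a shared call direction are concordant", {
  vals <- cbind(c(4, 2), c(6, 2))  # both lesions gained, amplitudes differ
  ls <- LesionSet(
    GRangesList(A = GRanges("1", IRanges(c(1, 101), c(100, 1000)),
                            copyNumber = vals[, 1]),
                B = GRanges("1", IRanges(c(1, 101), c(100, 1000)),
                            copyNumber = vals[, 2])),
    data.frame(lesion_id = c("A", "B"), patient_id = "P1"))
  cm <- callAberrations(harmonizeLesions(ls))
  genes <- GRanges("1", IRanges(c(10, 500), c(60, 600)),
                   gene_name = c("GAINED", "FLAT"),
                   cancer_critical = FALSE)
  gl <- geneLevelCalls(cm, genes)
  expect_equal(as.numeric(hetDiscordantFraction(gl$calls)), 0)
})

test_that("variance filtering keeps only regions varying across lesions", {
  m <- rbind(c(2, 4), matrix(2, 10, 2))
  expect_equal(var(c(2, 4)), 2)  # survives the 0.03 default
  expect_equal(as.numeric(hetVarianceFiltered(m)), 2)
  expect_equal(as.numeric(hetVarianceFiltered(m, varianceThreshold = Inf)), 0)
  expect_error(hetVarianceFiltered(m, varianceThreshold = -1), "varianceThreshold")
})

test_that("scores are invariant to region and lesion permutations", {
  set.seed(91)
  m <- matrix(sample(0:6, 60, replace = TRUE), ncol = 3)
  for (k in 1:5) {
    rp <- sample(nrow(m))
    cp <- sample(ncol(m))
    expect_equal(as.numeric(hetEuclidean(m[rp, cp])),
                 as.numeric(hetEuclidean(m)))
    expect_equal(as.numeric(hetCorrelation(m[rp, cp])),
                 as.numeric(hetCorrelation(m)))
    expect_equal(as.numeric(hetVarianceFiltered(m[rp, cp])),
                 as.numeric(hetVarianceFiltered(m)))
    expect_equal(as.numeric(hetDiscordantFraction(m[rp, cp])),
                 as.numeric(hetDiscordantFraction(m)))
  }
})

test_that("pairs sharing too few regions are refused, not computed", {
  m <- cbind(c(2, 3, rep(NA, 8)), c(NA, NA, 2, 3, rep(NA, 6)))
  out <- hetEuclidean(m, minSharedRegions = 10)
  expect_true(is.na(out))
  expect_equal(attr(out, "status"), "insufficient_overlap")
})

test_that("length-weighted distances are invariant to segment subdivision", {
  for (seed in c(61, 62)) {
    ls <- randomMiniCohort(seed, gapProb = 0)
    split <- subdivideSegments(ls, seed + 500)
    rm1 <- harmonizeLesions(ls)
    rm2 <- harmonizeLesions(split)
    for (p in unique(patientIDs(rm1))) {
      e1 <- hetEuclidean(rm1, lengthWeighted = TRUE, patient = p,
                         minSharedRegions = 0)
      e2 <- hetEuclidean(rm2, lengthWeighted = TRUE, patient = p,
                         minSharedRegions = 0)
      expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-9)
      v1 <- hetVarianceFiltered(rm1, lengthWeighted = TRUE, patient = p)
      v2 <- hetVarianceFiltered(rm2, lengthWeighted = TRUE, patient = p)
      expect_equal(as.numeric(v1), as.numeric(v2), tolerance = 1e-9)
    }
  }
})

test_that("median dichotomization uses a strict 'high' rule", {
  expect_equal(dichotomizeByMedian(c(1, 2, 3)), c("low", "low", "high"))
  expect_equal(dichotomizeByMedian(c(5, 5, 5)), c("low", "low", "low"))
  expect_equal(dichotomizeByMedian(c(1, NA, 3)), c("low", "missing", "high"))
})

test_that("estimator comparison recovers perfect and inverted dependence", {
  latent <- c(0.1, 0.4, 0.2, 0.9, 0.6, 0.3)
  scores <- data.frame(euclidean = latent * 10, correlation = latent / 2,
                       discordant = latent, variance_filtered = latent^2)
  rho <- compareHetEstimators(scores)
  expect_true(all(rho == 1))
  scores$correlation <- -scores$correlation
  rho2 <- compareHetEstimators(scores)
  expect_equal(unname(rho2["euclidean", "correlation"]), -1)
})

test_that("the four estimators are positively associated across a rate gradient", {
  fx <- makeFixture("gradient_het")
  pooled <- do.call(rbind, lapply(fx$cohorts, function(co) {
    cm <- callAberrations(harmonizeLesions(co$lesions))
    patientHeterogeneity(cm, genes = co$genes)
  }))
  rho <- compareHetEstimators(pooled)
  expect_true(all(rho > 0))
})
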