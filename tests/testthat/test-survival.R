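test_that("eligibility filter removes MSI and R2 patients with counts", {
  pts <- data.frame(patient_id = sprintf("P%03d", 1:171),
                    msi_status = c("MSI", rep("MSS", 170)),
                    r_status = c(rep("R0", 100), rep("R1", 66), rep("R2", 5)))
  out <- survivalEligible(pts, quiet = TRUE)
  expect_equal(nrow(out), 165)
  expect_equal(unname(attr(out, "removed")), c(1, 5))

  clean <- data.frame(msi_status = rep("MSS", 5), r_status = rep("R0", 5))
  expect_equal(nrow(survivalEligible(clean, quiet = TRUE)), 5)
  expect_equal(nrow(survivalEligible(clean[0, ], quiet = TRUE)), 0)
})

test_that("survival encoding censors other-cause deaths", {
  pts <- data.frame(followup_months = c(24, 30, 36),
                    event = c("CRC death", "other death", "alive"))
  enc <- cssEncode(pts)
  expect_equal(enc$time, c(24, 30, 36))
  expect_equal(enc$status, c(1, 0, 0))
})

test_that("KM equals empirical survival without censoring, exactly", {
  t1 <- c(10, 20, 30)
  fit <- kmEstimate(t1, c(1, 1, 1))
  expect_equal(fit$surv, c(2 / 3, 1 / 3, 0))

  allCensored <- kmEstimate(c(5, 10, 20), c(0, 0, 0))
  expect_true(all(allCensored$surv == 1))

  set.seed(17)
  times <- rexp(40, 0.02)
  fit2 <- kmEstimate(times, rep(1, 40))
  emp <- vapply(fit2$time, function(t) mean(times > t), 0)
  expect_equal(fit2$surv, emp)
})

test_that("KM matches a hand-computed product limit on a censored toy", {
  # subjects: death 6, death 6, censor 7, death 10, censor 12, death 15
  time <- c(6, 6, 7, 10, 12, 15)
  status <- c(1, 1, 0, 1, 0, 1)
  fit <- kmEstimate(time, status)
  # S(6) = 4/6; S(10) = 4/6 * 2/3 = 4/9; S(15) = 4/9 * 0 = 0
  expect_equal(fit$surv[fit$time == 6], 4 / 6)
  expect_equal(fit$surv[fit$time == 10], 4 / 9)
  expect_equal(fit$surv[fit$time == 15], 0)
})

test_that("five-year survival reads the curve at 60 months, LVCF", {
  fit <- kmEstimate(c(10, 50, 80, 90), c(1, 1, 0, 1))
  expect_equal(unname(fiveYearCSS(fit)), 0.5)  # last step before 60 is at 50
  # events after 60 months cannot change the 60-month read-out
  fit2 <- kmEstimate(c(10, 50, 70, 95), c(1, 1, 1, 1))
  expect_equal(unname(fiveYearCSS(fit2)), 0.5)
})

test_that("log-rank is null on identical groups and positive under separation", {
  time <- c(5, 10, 15, 20, 5, 10, 15, 20)
  status <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrankTest(time, status, g)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p.value, 1)

  early <- c(1, 2, 3, 4); late <- c(20, 30, 40, 50)
  lr2 <- logrankTest(c(early, late), rep(1, 8), g)
  expect_gt(lr2$chisq, 0)
  expect_lt(lr2$p.value, 0.05)

  expect_error(logrankTest(time, status, rep("a", 8)), "two")
})

test_that("two-group log-rank p matches a permutation null on a small toy", {
  set.seed(23)
  n <- 20
  g <- rep(c("a", "b"), each = n / 2)
  time <- c(rexp(n / 2, 0.05), rexp(n / 2, 0.10))
  status <- rbinom(n, 1, 0.85)
  obs <- logrankTest(time, status, g)
  B <- 2000
  perm <- vapply(seq_len(B), function(b)
    logrankTest(time, status, sample(g))$chisq, 0)
  pPerm <- mean(perm >= obs$chisq)
  se <- sqrt(pPerm * (1 - pPerm) / B)
  # asymptotic chi-square p vs exact permutation p: MC error plus a small
  # allowance for the n = 20 approximation
  expect_lt(abs(pPerm - obs$p.value), 3 * se + 0.02)
})

test_that("trend test is zero on identical groups and antisymmetric in order", {
  time <- rep(c(5, 10, 15, 20), 3)
  status <- rep(1, 12)
  g3 <- factor(rep(c("x", "y", "z"), each = 4), levels = c("x", "y", "z"))
  tr <- logrankTrend(time, status, g3)
  expect_equal(tr$z, 0)

  set.seed(31)
  time2 <- c(rexp(10, 0.02), rexp(10, 0.05), rexp(10, 0.12))
  st2 <- rep(1, 30)
  gf <- factor(rep(c("x", "y", "z"), each = 10), levels = c("x", "y", "z"))
  fwd <- logrankTrend(time2, st2, gf)
  rev <- logrankTrend(time2, st2, factor(gf, levels = c("z", "y", "x")))
  expect_equal(rev$z, -fwd$z)
  expect_equal(rev$p.value, fwd$p.value)

  # with two groups the trend test defers to the ordinary log-rank
  two <- logrankTrend(time, status, rep(c("x", "y"), 6))
  lr <- logrankTest(time, status, rep(c("x", "y"), 6))
  expect_equal(two$p.value, lr$p.value)
})

test_that("Cox recovers a null effect and agrees with log-rank on direction", {
  set.seed(41)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(time = rexp(n, 0.03), status = rbinom(n, 1, 0.9), x = x)
  fit <- coxFit(d, "x", mode = "univariable")
  expect_true(fit$ci_low < 1 && fit$ci_high > 1)  # CI covers HR = 1

  d2 <- data.frame(time = rexp(n, 0.03 * exp(log(3) * x)),
                   status = 1, x = x)
  fit2 <- coxFit(d2, "x", mode = "univariable")
  expect_gt(fit2$HR, 1)
  lr <- logrankTest(d2$time, d2$status, d2$x)
  expect_lt(lr$p.value, 0.05)

  expect_error(coxFit(data.frame(time = 1:5, status = 1, x = 1), "x"),
               "constant")
})

test_that("multivariable mode fits covariates jointly", {
  set.seed(43)
  n <- 300
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  d <- data.frame(time = rexp(n, 0.03 * exp(0.7 * x + 0.3 * z)),
                  status = 1, x = x, z = z)
  fit <- coxFit(d, c("x", "z"), mode = "multivariable")
  expect_equal(nrow(fit), 2)
  expect_true(all(fit$mode == "multivariable"))
  expect_gt(fit$HR[fit$term == "x"], 1)
})

test_that("group-association tests pick rank-sum or exact appropriately", {
  g <- rep(c("a", "b"), each = 10)
  x <- c(rnorm(10), rnorm(10))
  p1 <- groupAssociationTest(x, g)
  expect_equal(attr(p1, "test"), "wilcoxon")
  expect_true(p1 > 0 && p1 <= 1)

  cat2 <- rep(c("yes", "no"), c(10, 10))
  p2 <- groupAssociationTest(cat2, g)
  expect_equal(attr(p2, "test"), "fisher")
  # fully separated 2x2 table (10,0 / 0,10):
  # two-sided hypergeometric tail = 2 / choose(20, 10)
  sep <- c(rep("yes", 10), rep("no", 10))
  p3 <- groupAssociationTest(sep, g)
  expect_equal(as.numeric(p3), 2 / choose(20, 10))
  expect_lt(p3, 0.001)

  expect_true(is.na(groupAssociationTest(rep(1, 20), g)))
  expect_true(is.na(groupAssociationTest(rep("yes", 20), g)))
})

test_that("stratified analysis runs KM, the right test, and a reference Cox", {
  set.seed(53)
  n <- 120
  strata <- factor(sample(c("other", "co_mut_low", "co_mut_high"), n, TRUE),
                   levels = c("other", "co_mut_low", "co_mut_high"))
  haz <- c(other = 0.01, co_mut_low = 0.02, co_mut_high = 0.05)
  time <- rexp(n, haz[as.character(strata)])
  status <- rbinom(n, 1, 0.9)
  out <- stratifiedSurvival(time, status, strata)
  expect_equal(out$cox$term[1], "stratumco_mut_low")  # reference = first level
  expect_equal(length(out$five_year_css), 3)
  expect_false(is.null(out$test$z))

  # relabelling the reference reciprocates the hazard ratio
  two <- droplevels(strata[strata != "co_mut_low"])
  t2 <- time[strata != "co_mut_low"]; s2 <- status[strata != "co_mut_low"]
  a <- stratifiedSurvival(t2, s2, two)
  b <- stratifiedSurvival(t2, s2, factor(two, rev(levels(two))))
  expect_equal(a$cox$HR, 1 / b$cox$HR, tolerance = 1e-6)
  expect_equal(a$test$p.value, b$test$p.value, tolerance = 1e-9)
})
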