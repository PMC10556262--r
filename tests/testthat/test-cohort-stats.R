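test_that("Yates 2x2 test matches its formula and the stats oracle", {
  expect_equal(round(chisqYates(10, 109, 9, 18)$p, 3), 0.002)
  expect_equal(round(chisqYates(12, 56, 29, 49)$p, 3), 0.015)

  prop <- chisqYates(5, 5, 10, 10)
  expect_equal(prop$chisq, 0)
  expect_equal(prop$p, 1)

  set.seed(71)
  for (i in 1:25) {
    m <- matrix(rpois(4, 20) + 1, 2)
    ours <- chisqYates(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    ref <- suppressWarnings(chisq.test(m, correct = TRUE))
    expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    # continuity correction never increases the statistic
    plain <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_lte(ours$chisq, unname(plain$statistic) + 1e-12)
  }
  expect_warning(z <- chisqYates(0, 0, 3, 4), "margin")
  expect_equal(z$p, 1)
  expect_error(chisqYates(-1, 2, 3, 4), "nonnegative")
})

test_that("Pearson r x c test matches brute force", {
  expect_equal(round(chisqRxC(rbind(c(1, 3, 3), c(56, 70, 13)))$p, 3),
               0.018)
  expect_equal(round(chisqRxC(rbind(c(3, 6, 5), c(54, 67, 11)))$p, 3),
               0.007)

  flat <- chisqRxC(rbind(c(10, 20, 30), c(1, 2, 3)))
  expect_equal(flat$chisq, 0, tolerance = 1e-12)
  expect_equal(flat$p, 1)

  set.seed(72)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 15) + 1, 2)
    res <- chisqRxC(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chisq, sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(res$df, 2)
    expect_true(res$p >= 0 && res$p <= 1)
  }
  expect_error(chisqRxC(rbind(c(0, 0, 0), c(1, 2, 3))), "all-zero")
})

test_that("t statistics match published summaries and a permutation oracle", {
  x <- c(1, 2, 3, 4)
  same <- twoSampleT(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # published age comparison from group summaries
  p <- twoSampleT(summary = list(mean = c(43.6, 39.3),
                                 sd = c(14.2, 13.2), n = c(119, 27)))$p
  expect_gt(p, 0.13); expect_lt(p, 0.16)
  pPooled <- twoSampleT(summary = list(mean = c(43.6, 39.3),
                                       sd = c(14.2, 13.2), n = c(119, 27)),
                        pooled = TRUE)$p
  expect_gt(pPooled, 0.13); expect_lt(pPooled, 0.16)

  # raw-data path agrees with stats::t.test
  set.seed(73)
  a <- rnorm(15, 1); b <- rnorm(15)
  ours <- twoSampleT(a, b)
  ref <- t.test(a, b)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  # permutation oracle
  v <- c(a, b); B <- 1e5
  tobs <- abs(ours$t)
  set.seed(74)
  hits <- 0
  for (i in seq_len(B)) {
    idx <- sample.int(30, 15)
    hits <- hits + (abs(twoSampleT(v[idx], v[-idx])$t) >= tobs)
  }
  pperm <- hits / B
  expect_lt(abs(pperm - ours$p),
            3 * sqrt(pperm * (1 - pperm) / B) + 0.01)
  expect_error(twoSampleT(1, c(2, 3)), "two observations")
})

test_that("agreement statistics behave at the anchors and under the null", {
  ident <- agreementStats(letters[1:10], letters[1:10])
  expect_equal(ident$agreement, 1)
  expect_equal(ident$kappa, 1)

  conf <- agreementStats(rep(c("x", "x", "y", "y"), c(45, 5, 5, 45)),
                         rep(c("x", "y", "x", "y"), c(45, 5, 5, 45)))
  expect_equal(conf$agreement, 0.9)
  expect_equal(conf$kappa, 0.8)

  set.seed(75)
  a <- sample(1:8, 1e4, replace = TRUE)
  b <- sample(1:8, 1e4, replace = TRUE)
  nullK <- agreementStats(a, b)$kappa
  expect_lt(abs(nullK), 3 * sqrt((1 / 8) / (7 / 8)) / 100)

  if (requireNamespace("e1071", quietly = TRUE)) {
    ref <- e1071::classAgreement(table(a, b))
    expect_equal(nullK, ref$kappa, tolerance = 1e-12)
  }
  expect_error(agreementStats(1:3, 1:4), "length")
})

test_that("cohort table dispatches the matching test per variable", {
  set.seed(76)
  n <- 120
  d <- data.frame(
    grp2 = rep(c("A", "B"), each = n / 2),
    grp3 = rep(c("low", "medium", "high"), each = n / 3),
    flag = rbinom(n, 1, 0.3),
    ki = sample(c("low", "mid", "high"), n, replace = TRUE),
    age = rnorm(n, 45, 10))
  t2 <- buildCohortTable(d, "grp2", c(flag = "categorical",
                                      age = "continuous"))
  tab <- table(factor(d$flag), factor(d$grp2))
  expect_equal(t2$p[t2$variable == "flag"],
               chisqYates(tab[2, 1], tab[1, 1], tab[2, 2], tab[1, 2])$p)
  expect_equal(t2$p[t2$variable == "age"],
               twoSampleT(d$age[d$grp2 == "A"], d$age[d$grp2 == "B"])$p)

  t3 <- buildCohortTable(d, "grp3", c(flag = "categorical"))
  expect_equal(t3$p[1],
               chisqRxC(table(factor(d$flag), factor(d$grp3)))$p)

  # percent formatting contract
  expect_true(all(grepl("^\\d+ \\(\\d+\\.\\d%\\)",
                        unlist(t2[t2$variable == "flag",
                                  startsWith(names(t2), "g_")]))))
  expect_error(buildCohortTable(d, "grp2", c(nope = "categorical")),
               "unknown variable")
  expect_error(buildCohortTable(d, "grp2", c(age = "ordinal")),
               "unknown variable type")
})

test_that("null continuous p-values are calibrated", {
  set.seed(77)
  ps <- replicate(200, {
    d <- data.frame(g = rep(c("A", "B"), each = 20), v = rnorm(40))
    buildCohortTable(d, "g", c(v = "continuous"))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # the Yates-corrected categorical path is conservative, never anti-
  set.seed(78)
  rej <- mean(replicate(200, {
    d <- data.frame(g = rep(c("A", "B"), each = 30),
                    f = rbinom(60, 1, 0.5))
    buildCohortTable(d, "g", c(f = "categorical"))$p < 0.05
  }))
  expect_lte(rej, 0.06)
})

test_that("reference cohort statistics reproduce the published p-values", {
  stats <- referenceCohortStats()
  getP <- function(grp, var)
    stats$p[stats$grouping == grp & stats$variable == var]
  expect_equal(round(getP("mc", "giant_tumor"), 3), 0.002)
  expect_equal(round(getP("mc", "sphenoidal_clivus"), 3), 0.005)
  expect_lt(getP("mc", "suprasellar"), 0.001)
  expect_lt(getP("ic", "giant_tumor"), 0.001)
  expect_equal(round(getP("ic", "tenacious"), 3), 0.015)
  expect_lt(getP("tier", "giant_tumor"), 0.001)
  expect_lt(getP("tier", "multiple_surgeries"), 0.001)
  expect_lt(getP("tier", "suprasellar"), 0.001)
  expect_equal(round(getP("tier", "sphenoidal_clivus"), 3), 0.007)
  expect_equal(round(getP("tier", "ki67_high"), 3), 0.018)
})
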