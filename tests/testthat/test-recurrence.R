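test_that("biochemical recurrence labeling follows the inclusive 0.2 rule", {
  r <- labelBcr(c(1, 2), c(0.05, 0.25))
  expect_true(r$recurrent); expect_equal(r$time, 2); expect_false(r$censored)
  c1 <- labelBcr(c(1, 3), c(0.05, 0.1))
  expect_false(c1$recurrent); expect_equal(c1$time, 3); expect_true(c1$censored)
  b <- labelBcr(0.5, 0.2)                    # threshold is inclusive
  expect_true(b$recurrent); expect_equal(b$time, 0.5)
  expect_error(labelBcr(numeric(), numeric()), "at least one")
  expect_error(labelBcr(c(2, 1), c(0.1, 0.1)), "nondecreasing")
})

test_that("t test matches the pooled-variance hand computation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  r <- ttestFeature(a, b)
  expect_equal(r$t, -1.0, tolerance = 1e-12)   # sd 1.581, se 1.0
  sw <- ttestFeature(b, a)
  expect_equal(sw$t, 1.0, tolerance = 1e-12)
  expect_equal(sw$p, r$p)
  ident <- ttestFeature(c(3, 3, 3), c(3, 3, 3))
  expect_equal(ident$t, 0); expect_equal(ident$p, 1)
})

test_that("AUC equals pair counting and handles degenerate orderings", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0, 0, 1, 1))$auc, 0.0)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(31)
  for (k in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)             # ties likely
    expect_equal(rocAuc(scores, labels)$auc, aucBruteForce(scores, labels))
  }
})

test_that("DeLong interval covers the AUC and cross-checks pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- rbinom(120, 1, 0.4)
  scores <- rnorm(120) + labels
  mine <- rocAuc(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(mine$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(mine$ci, as.numeric(ref[c(1, 3)]), tolerance = 1e-6)
})

test_that("permutation AUC comparison is smoothed, paired and deterministic", {
  labels <- rep(c(0, 1), 25)
  set.seed(5); s1 <- rnorm(50); s2 <- rnorm(50)
  r <- compareAucPermutation(s1, s2, labels, nPerm = 500, seed = 3)
  expect_gt(r$p, 0); expect_lte(r$p, 1)
  expect_identical(r, compareAucPermutation(s1, s2, labels, nPerm = 500,
                                            seed = 3))
  same <- compareAucPermutation(s1, s1, labels, nPerm = 200, seed = 1)
  expect_equal(same$p, 1)
  # a perfect model against noise at n = 200 is clearly separated
  lab200 <- rep(c(0, 1), 100)
  set.seed(7)
  perfect <- lab200 + 0
  noise <- rnorm(200)
  pw <- compareAucPermutation(perfect, noise, lab200, nPerm = 1000, seed = 2)
  expect_lt(pw$p, 0.01)
})

test_that("Benjamini-Hochberg step-up matches direct enumeration", {
  r <- benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r$rejected))
  expect_false(any(benjaminiHochberg(rep(1, 5), 0.05)$rejected))
  single <- benjaminiHochberg(0.04, 0.05)
  expect_true(single$rejected); expect_equal(single$adjusted, 0.04)
  set.seed(17)
  for (k in 1:50) {
    p <- round(runif(4), 2)
    r <- benjaminiHochberg(p, 0.05)
    expect_identical(r$rejected, bhOracle(p, 0.05))
    expect_true(all(diff(r$adjusted[order(p)]) >= -1e-12))  # monotone
  }
})

test_that("logistic fit reports accuracy, ROC and flags separation", {
  sep <- data.frame(x = c(1, 2, 3, 10, 11, 12, 13))
  labs <- c(0, 0, 0, 1, 1, 1, 1)
  fit <- fitLogistic(sep, labs)
  expect_true(fit@separation)
  expect_equal(modelAuc(fit), 1.0)
  expect_equal(modelAccuracy(fit), 100)
  expect_error(fitLogistic(data.frame(x = 1:5), rep(1, 5)), "both classes")
  roc <- rocPoints(fit)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("Kaplan-Meier estimates match the product-limit oracle", {
  # 10-subject fixture with ties and censoring
  times <- c(1, 2, 2, 3, 4, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 0, 1, 1, 0, 1, 1)
  km <- kmLogrank(times, events, rep("all", 10))
  cv <- survivalCurves(km)
  oracle <- kmOracle(times, events)
  got <- cv[cv$nEvent > 0, c("time", "survival")]
  rownames(got) <- NULL
  expect_equal(got, oracle, tolerance = 1e-12)

  # no censoring, distinct times: steps are 1 - k/n
  t2 <- 1:10; e2 <- rep(1, 10)
  cv2 <- survivalCurves(kmLogrank(t2, e2, rep("g", 10)))
  expect_equal(cv2$survival, 1 - (1:10) / 10)

  ident <- kmLogrank(c(times, times), c(events, events),
                     rep(c("a", "b"), each = 10))
  expect_equal(logrankP(ident), 1, tolerance = 1e-9)
  expect_error(kmLogrank(times, events, factor(rep("a", 10),
                                               levels = c("a", "b"))),
               "group")
})

test_that("log-rank separates exponential groups with rate ratio 3", {
  set.seed(44)
  hits <- 0L
  for (b in 1:20) {
    t1 <- rexp(500, 0.2); t2 <- rexp(500, 0.6)
    km <- kmLogrank(c(t1, t2), rep(1, 1000), rep(c("a", "b"), each = 500))
    if (logrankP(km) < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("Cox regression recovers hazard ratios and rejects zero events", {
  set.seed(9)
  x <- rbinom(2000, 1, 0.5)
  t <- rexp(2000, 0.2 * 2^x)
  cens <- rexp(2000, 0.05)
  fit <- coxPh(pmin(t, cens), as.integer(t <= cens), data.frame(x = x))
  hr <- hazardRatios(fit)
  expect_equal(hr$hr, 2, tolerance = 0.15)
  expect_true(hr$lower < 2 & hr$upper > 2)
  expect_error(coxPh(1:5, rep(0, 5), data.frame(x = 1:5)), "event")
})

test_that("risk stratification schemes bin deterministically", {
  expect_equal(as.character(stratifyRisk(c(0.19, 0.20), "pathomic_0.2")),
               c("low", "high"))
  expect_equal(as.character(stratifyRisk(c(0, 2, 3, 4, 5, 6, 10),
                                         "capra_3bin")),
               c("low", "low", "medium", "medium", "medium", "high", "high"))
  expect_equal(as.character(stratifyRisk(c(1, 2, 3, 4, 5), "gg_3bin")),
               c("low", "low", "medium", "high", "high"))
  expect_equal(as.character(stratifyRisk(c(TRUE, FALSE), "cribriform")),
               c("present", "absent"))
  expect_error(stratifyRisk(11, "capra_3bin"), "CAPRA")
  expect_error(stratifyRisk(6, "gg_3bin"), "Grade Group")
  expect_error(stratifyRisk(1.5, "pathomic_0.2"), "probabilities")
})
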