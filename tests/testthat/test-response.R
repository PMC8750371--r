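test_that("delta change formula and zero-baseline policy", {
  expect_equal(as.numeric(deltaBiomarker(5, 3.4)), -32)
  expect_equal(as.numeric(deltaBiomarker(2.5, 0)), -100)
  expect_equal(as.numeric(deltaBiomarker(7, 7)), 0)
  d0 <- deltaBiomarker(0, 0)
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "undefined"))
  dInf <- deltaBiomarker(0, 3)
  expect_identical(as.numeric(dInf), Inf)
  expect_true(attr(dInf, "undefined"))
  expect_error(deltaBiomarker(-1, 2), "non-negative")
  # vectorised
  dv <- deltaBiomarker(c(5, 0, 4), c(3.4, 2, 4))
  expect_equal(as.numeric(dv), c(-32, Inf, 0))
})

test_that("PERCIST binarization maps CR/PR to responder, SD/PD to non-responder", {
  expect_identical(binarizePercist(c("CR", "PR", "SD", "PD")),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_error(binarizePercist("XX"), "unknown")
})

test_that("ROC on observed thresholds: perfect and hand-counted cases", {
  r <- rocCurve(c(-80, -60, -50, -10, 0, 20),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  # responders {-80,-60}, non-responders {-70,0}: 3/4 concordant pairs
  r2 <- rocCurve(c(-80, -60, -70, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)
  # invariance to record order
  set.seed(9)
  perm <- sample(4)
  r3 <- rocCurve(c(-80, -60, -70, 0)[perm],
                 c(TRUE, TRUE, FALSE, FALSE)[perm])
  expect_equal(r3$auc, r2$auc)
  expect_error(rocCurve(c(-1, -2), c(TRUE, TRUE)), "both")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-count estimator", {
  set.seed(55)
  for (rep in 1:25) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    # mixture of continuous values and deliberate ties
    pool <- c(rnorm(15, 0, 40), round(rnorm(10, 0, 40) / 10) * 10)
    deltas <- sample(pool, n1 + n0, replace = TRUE)
    resp <- c(rep(TRUE, n1), rep(FALSE, n0))
    deltas[resp] <- deltas[resp] - rnorm(1, 10, 20)
    r <- rocCurve(deltas, resp)
    expect_equal(r$auc, pairCountAUC(deltas, resp), tolerance = 1e-12,
                 info = sprintf("rep %d", rep))
  }
})

test_that("AUC agrees with pROC on random data", {
  library(pROC)
  set.seed(17)
  for (rep in 1:10) {
    deltas <- rnorm(30, 0, 50)
    resp <- rbinom(30, 1, 0.5)
    if (sum(resp) == 0 || sum(resp) == 30) next
    r <- rocCurve(deltas, resp == 1)
    pr <- suppressMessages(pROC::roc(resp, deltas, direction = ">"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("Youden cutoff maximises J with ties toward the most negative delta", {
  r <- rocCurve(c(-80, -60, -50, -10, 0, 20),
                c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  y <- youdenCutoff(r)
  expect_equal(y$cutoff, -50)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_equal(y$j, 1)
  # no discrimination: all deltas identical
  rflat <- rocCurve(c(-5, -5, -5, -5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(youdenCutoff(rflat)$j, 0)
  # recomputing sensitivity/specificity at the returned cutoff matches
  set.seed(23)
  deltas <- rnorm(40, -20, 30); resp <- rbinom(40, 1, 0.5) == 1
  if (any(resp) && any(!resp)) {
    y2 <- youdenCutoff(rocCurve(deltas, resp))
    expect_equal(y2$sensitivity, mean(deltas[resp] <= y2$cutoff))
    expect_equal(y2$specificity, mean(deltas[!resp] > y2$cutoff))
    expect_equal(y2$j, y2$sensitivity + y2$specificity - 1)
  }
})

test_that("DeLong self-comparison is exactly null and AUCs match rocCurve", {
  set.seed(41)
  deltas <- rnorm(24, -10, 30); resp <- rep(c(TRUE, FALSE), 12)
  t <- delongTest(deltas, deltas, resp)
  expect_equal(t$z, 0)
  expect_equal(t$p, 1)
  expect_equal(t$aucA, rocCurve(deltas, resp)$auc)
})

test_that("DeLong z and p agree with pROC's paired test", {
  library(pROC)
  set.seed(4)
  for (rep in 1:6) {
    n <- 40
    resp <- rep(c(TRUE, FALSE), n / 2)
    a <- rnorm(n) - resp * 1.2
    b <- 0.6 * a + rnorm(n, 0, 0.8)
    t <- delongTest(a, b, resp)
    ra <- suppressMessages(pROC::roc(resp, a, direction = ">"))
    rb <- suppressMessages(pROC::roc(resp, b, direction = ">"))
    pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(abs(t$z), abs(as.numeric(pt$statistic)), tolerance = 1e-8)
    expect_equal(t$p, pt$p.value, tolerance = 1e-8)
  }
})

test_that("DeLong keeps its nominal size under the null", {
  set.seed(71)
  n <- 30; reps <- 300
  pvals <- replicate(reps, {
    resp <- rep(c(TRUE, FALSE), n / 2)
    a <- rnorm(n); b <- rnorm(n)   # two pure-noise biomarkers
    delongTest(a, b, resp)$p
  })
  rate05 <- mean(pvals <= 0.05)
  expect_gt(rate05, 0.01)
  expect_lt(rate05, 0.12)
  expect_lt(mean(pvals <= 0.001), 0.02)
})

test_that("Lin's CCC: hand examples and relation to Pearson", {
  expect_equal(as.numeric(linCCC(1:5, 1:5)), 1)
  expect_equal(as.numeric(linCCC(c(1, 2, 3), c(2, 3, 4))), 4 / 7)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(as.numeric(linCCC(x, -x)), -1)
  set.seed(15)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12, 0.3 * x, 0.7)
    ccc <- as.numeric(linCCC(x, y))
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
  }
  # equal means and variances: CCC collapses to Pearson
  x <- rnorm(20); y <- rev(x)
  expect_equal(as.numeric(linCCC(x, y)), cor(x, y), tolerance = 1e-12)
  degen <- linCCC(rep(2, 5), rep(2, 5))
  expect_equal(as.numeric(degen), 1)
  expect_true(attr(degen, "degenerate"))
})

test_that("rank statistics wrappers behave on canonical inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanRho(x, exp(x)), 1)        # strictly monotone map
  expect_equal(spearmanRho(x, -x^3), -1)
  mw <- mannWhitneyU(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(mw$p, 0.9)
  w <- wilcoxonSignedRank(x, x)
  expect_true(w$degenerate)
  expect_true(is.na(w$p))
  set.seed(2)
  kn <- ksNormality(rnorm(200))
  expect_gt(kn$p, 0.01)
})

test_that("response classification respects the boundary and new lesions", {
  expect_true(classifyResponse(-61, -32))
  expect_true(classifyResponse(-8, -8))     # boundary inclusive
  expect_false(classifyResponse(20, -32))
  expect_false(classifyResponse(Inf, -32))  # new-lesion sentinel
  expect_identical(classifyResponse(c(-40, -10), -32), c(TRUE, FALSE))
})

test_that("assessResponse composes ROC, cutoff and group testing per biomarker", {
  set.seed(19)
  n <- 40
  resp <- rep(c(TRUE, FALSE), n / 2)
  deltas <- data.frame(
    d_good = ifelse(resp, rnorm(n, -60, 10), rnorm(n, 5, 10)),
    d_noise = rnorm(n, 0, 30))
  out <- assessResponse(deltas, resp)
  tab <- out$table
  expect_equal(tab$biomarker, c("d_good", "d_noise"))
  expect_gt(tab$auc[1], 0.95)
  expect_lt(tab$auc[2], 0.8)
  expect_true(tab$significant[1])
  # delong table compares the pair, AUCs consistent
  expect_equal(out$delong$auc_a, tab$auc[1])
  expect_equal(out$delong$auc_b, tab$auc[2])
  # every reported cutoff is an observed delta
  expect_true(tab$cutoff[1] %in% deltas$d_good)
})
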