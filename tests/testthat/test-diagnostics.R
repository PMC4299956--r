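test_that("confusion counting uses the strict-greater positivity rule", {
  cm <- confusion_counts(c(2, 1, -1, -2), c(1, 1, 0, 0), 0)
  expect_identical(unlist(cm[c("TP", "FN", "FP", "TN")]),
                   c(TP = 2L, FN = 0L, FP = 0L, TN = 2L))
  cm2 <- confusion_counts(c(2, 1, -1, -2), c(1, 1, 0, 0), 10)
  expect_identical(cm2$TP + cm2$FP, 0L)
  # a score tied with the threshold counts as test-negative
  cm3 <- confusion_counts(c(1, 1), c(1, 0), 1)
  expect_identical(c(cm3$TP, cm3$TN), c(0L, 1L))
  expect_error(confusion_counts(numeric(), numeric()), "non-empty")
  expect_error(confusion_counts(1:3, c(0, 1, 2)), "binary")
})

test_that("rates and Wald intervals reproduce the published worked examples", {
  cm <- confusion_matrix(TP = 57, FN = 5, FP = 10, TN = 99)
  r <- rates_with_ci(cm)
  expect_equal(round(r$sensitivity[["est"]], 2), 0.92)
  expect_equal(round(r$specificity[["est"]], 2), 0.91)
  expect_equal(round(r$accuracy[["est"]], 2), 0.91)
  # Wald interval for 156/171 correct
  expect_equal(unname(round(r$accuracy[c("lo", "hi")], 3)), c(0.870, 0.955))

  perfect <- rates_with_ci(confusion_matrix(62, 0, 0, 109))
  expect_equal(unname(c(perfect$sensitivity[["est"]],
                        perfect$specificity[["est"]],
                        perfect$accuracy[["est"]])), c(1, 1, 1))

  cp <- rates_with_ci(cm, method = "clopper_pearson")
  expect_lt(cp$sensitivity[["lo"]], cp$sensitivity[["est"]])
  expect_gt(cp$sensitivity[["hi"]], cp$sensitivity[["est"]])
})

test_that("likelihood ratios and Simel intervals match the published table", {
  cm <- confusion_matrix(57, 5, 10, 99)
  lr <- likelihood_ratios_with_ci(cm)
  expect_equal(round(lr$lr_plus[["est"]], 2), 10.02)
  expect_equal(round(lr$lr_minus[["est"]], 2), 0.09)
  expect_equal(round(lr$lr_plus[["hi"]], 2), 18.17)
  cm90 <- confusion_matrix(56, 6, 11, 98)
  lr90 <- likelihood_ratios_with_ci(cm90)
  expect_equal(round(lr90$lr_plus[["est"]], 2), 8.95)
  expect_equal(round(lr90$lr_minus[["est"]], 2), 0.11)
  # zero cells flag undefined intervals
  z <- likelihood_ratios_with_ci(confusion_matrix(10, 0, 5, 10))
  expect_identical(z$lr_minus[["est"]], 0)
  expect_true(is.na(z$lr_minus[["lo"]]))
  z2 <- likelihood_ratios_with_ci(confusion_matrix(10, 2, 0, 10))
  expect_identical(z2$lr_plus[["est"]], Inf)
})

test_that("odds ratio with log-transform CI matches the published table", {
  or90 <- odds_ratio_with_ci(confusion_matrix(56, 6, 11, 98))
  expect_equal(round(or90[["est"]], 2), 83.15)
  expect_equal(round(or90[["hi"]], 0), 237)
  expect_equal(round(odds_ratio_with_ci(confusion_matrix(57, 5, 10, 99))[["est"]], 1),
               112.9)
  expect_error(odds_ratio_with_ci(confusion_matrix(10, 0, 5, 10)), "zero cell")
  cc <- odds_ratio_with_ci(confusion_matrix(10, 0, 5, 10), continuity = TRUE)
  expect_true(is.finite(cc[["est"]]))
})

test_that("OR equals LR+/LR- on random zero-free tables", {
  set.seed(13)
  for (i in 1:25) {
    cm <- confusion_matrix(sample(1:80, 1), sample(1:80, 1),
                           sample(1:80, 1), sample(1:80, 1))
    lr <- likelihood_ratios_with_ci(cm)
    expect_equal(odds_ratio_with_ci(cm)[["est"]],
                 lr$lr_plus[["est"]] / lr$lr_minus[["est"]],
                 tolerance = 1e-12)
  }
})

test_that("trapezoid AUC equals brute-force pair counting and pROC", {
  a <- roc_auc(c(3, 1, 2, 0), c(1, 1, 0, 0))$auc
  expect_equal(a, 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    l <- rbinom(n, 1, 0.5)
    if (sum(l) %in% c(0, n)) next
    brute <- mean(outer(s[l == 1], s[l == 0], ">") +
                    0.5 * outer(s[l == 1], s[l == 0], "=="))
    expect_equal(roc_auc(s, l)$auc, brute, tolerance = 1e-12)
    p <- suppressMessages(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1))))
    expect_equal(roc_auc(s, l)$auc, as.numeric(p), tolerance = 1e-12)
  }
})

test_that("bootstrap AUC interval contains the point estimate and shrinks with n", {
  set.seed(19)
  s <- c(rnorm(20, 1), rnorm(20))
  l <- rep(c(1, 0), each = 20)
  ci <- bootstrap_auc_ci(s, l, B = 500, seed = 3)
  expect_lte(ci[["lo"]], ci[["est"]])
  expect_gte(ci[["hi"]], ci[["est"]])
  widths <- vapply(1:9, function(sd) {
    set.seed(sd)
    w <- function(n) {
      sc <- c(rnorm(n, 1), rnorm(n))
      lab <- rep(c(1, 0), each = n)
      ci <- bootstrap_auc_ci(sc, lab, B = 300, seed = sd)
      ci[["hi"]] - ci[["lo"]]
    }
    c(w(20), w(200))
  }, c(0, 0))
  expect_gt(median(widths[1, ]), median(widths[2, ]))
})

test_that("paired AUC z-test handles identical, correlated and independent scores", {
  set.seed(23)
  s <- rnorm(40); l <- rep(c(1, 0), 20)
  same <- paired_auc_z(s, s, l)
  expect_identical(same$z, 0)
  expect_equal(same$p, 0.5)
  # sign convention
  sa <- c(rnorm(20, 2), rnorm(20)); sb <- c(rnorm(20, 0.2), rnorm(20))
  lab <- rep(c(1, 0), each = 20)
  cmp <- paired_auc_z(sa, sb, lab)
  expect_identical(sign(cmp$z), sign(cmp$auc_a - cmp$auc_b))
  # independent markers: paired SE close to the unpaired combination
  ratios <- vapply(1:30, function(sd) {
    set.seed(sd)
    n <- 60
    lab <- rep(c(1, 0), each = n / 2)
    a <- rnorm(n) + lab; b <- rnorm(n) + lab
    cmp <- paired_auc_z(a, b, lab)
    va <- function(s) {
      sp <- s[lab == 1]; sn <- s[lab == 0]
      v10 <- vapply(sp, function(x) mean(x > sn) + 0.5 * mean(x == sn), 0)
      v01 <- vapply(sn, function(x) mean(sp > x) + 0.5 * mean(sp == x), 0)
      var(v10) / length(sp) + var(v01) / length(sn)
    }
    cmp$se_diff / sqrt(va(a) + va(b))
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.05)
  expect_error(paired_auc_z(1:3, 1:4, c(1, 0, 1)), "equal length")
})

test_that("paired z agrees with the pROC DeLong test and a bootstrap oracle", {
  set.seed(29)
  n <- 150
  lab <- rep(c(1, 0), c(60, 90))
  base <- rnorm(n)
  a <- base + lab * 1.0 + rnorm(n, 0, 0.8)
  b <- 0.7 * base + lab * 0.6 + rnorm(n, 0, 0.9)
  cmp <- paired_auc_z(a, b, lab)
  pr <- pROC::roc.test(pROC::roc(lab, a, quiet = TRUE),
                       pROC::roc(lab, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(cmp$z, unname(pr$statistic), tolerance = 1e-8)
  # subject-bootstrap SE of the paired AUC difference
  set.seed(31)
  diffs <- vapply(1:400, function(i) {
    idx <- c(sample(which(lab == 1), replace = TRUE),
             sample(which(lab == 0), replace = TRUE))
    roc_auc(a[idx], lab[idx])$auc - roc_auc(b[idx], lab[idx])$auc
  }, 0)
  expect_lt(abs(cmp$se_diff / sd(diffs) - 1), 0.10)
})

test_that("optimal threshold minimizes the distance to the ideal corner", {
  # ROC containing the perfect corner
  s <- c(5, 4, 1, 0); l <- c(1, 1, 0, 0)
  roc <- roc_curve(s, l)
  opt <- optimal_threshold(roc)
  expect_equal(c(opt$fpr, opt$tpr), c(0, 1))
  # tie between symmetric points goes to higher specificity
  roc_tie <- structure(data.frame(threshold = c(2, 1),
                                  fpr = c(0, 0.5), tpr = c(0.5, 1)),
                       class = c("roc_curve", "data.frame"))
  expect_equal(optimal_threshold(roc_tie)$fpr, 0)
  # exhaustive oracle on random score sets
  set.seed(37)
  for (i in 1:15) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.5)
    if (sum(l) %in% c(0, 30)) next
    roc <- roc_curve(s, l)
    opt <- optimal_threshold(roc)
    d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
    expect_equal(opt$distance, min(d), tolerance = 1e-12)
  }
})

test_that("confusion counts are recoverable from printed rates, or flagged ambiguous", {
  cm <- reconstruct_confusion(0.92, 0.91, 62, 109)
  expect_identical(unlist(cm[c("TP", "FN", "FP", "TN")]),
                   c(TP = 57L, FN = 5L, FP = 10L, TN = 99L))
  cm2 <- reconstruct_confusion(0.65, 0.92, 62, 109)
  expect_identical(unlist(cm2[c("TP", "FN", "FP", "TN")]),
                   c(TP = 40L, FN = 22L, FP = 9L, TN = 100L))
  expect_error(reconstruct_confusion(0.90, 0.91, 200, 109), "candidates")
})

test_that("printed rates round-trip through reconstruction for every table column", {
  cols <- list(c(.90, .90), c(.84, .85), c(.74, .88), c(.87, .86),
               c(.92, .91), c(.65, .92), c(.77, .82))
  for (x in cols) {
    cm <- reconstruct_confusion(x[1], x[2], 62, 109)
    r <- rates_with_ci(cm)
    expect_equal(voiclass:::round_half_up(r$sensitivity[["est"]]), x[1])
    expect_equal(voiclass:::round_half_up(r$specificity[["est"]]), x[2])
  }
})

test_that("interval widths shrink as counts grow at fixed rates", {
  w <- vapply(c(1, 2, 4, 8), function(k) {
    r <- rates_with_ci(confusion_matrix(45 * k, 5 * k, 5 * k, 45 * k))
    r$sensitivity[["hi"]] - r$sensitivity[["lo"]]
  }, 0)
  expect_true(all(diff(w) < 0))
})

test_that("diagnostic report fields are mutually consistent", {
  set.seed(41)
  s <- c(rnorm(30, 1.5), rnorm(40))
  l <- rep(c("patient", "control"), c(30, 40))
  rep <- diagnostic_report(s, l, B = 300, seed = 1)
  cm <- rep$confusion
  expect_equal(rep$sensitivity[["est"]], cm$TP / (cm$TP + cm$FN))
  expect_equal(rep$odds_ratio[["est"]],
               rep$lr_plus[["est"]] / rep$lr_minus[["est"]], tolerance = 1e-10)
  expect_true(rep$auc[["lo"]] <= rep$auc[["est"]] &&
                rep$auc[["est"]] <= rep$auc[["hi"]])
  # report confusion equals direct recount at the reported threshold
  cm2 <- confusion_counts(s, l, rep$threshold)
  expect_identical(unlist(cm[c("TP", "FN", "FP", "TN")]),
                   unlist(cm2[c("TP", "FN", "FP", "TN")]))
})
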