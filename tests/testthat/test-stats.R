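test_that("lesion-level cross-tabulation collapses to the remyelination 2x2", {
  # lesion-level reconstruction of the published radiological-pathological
  # comparison: 19 concordant demyelinated, 3 MRI-remyel/histo-demyel,
  # 0 missed, 9 concordant remyelinated
  tb <- data.frame(
    mri_category = c(rep("early_active", 10), rep("chronic_demyelinated", 9),
                     rep("remyelinated", 12)),
    histo_category = c(rep("early_active", 10), rep("chronic_demyelinated", 9),
                       rep("chronic_demyelinated", 3), rep("remyelinated", 9)))
  cm <- binarize_and_tabulate(tb)
  expect_equal(cm[c("tp", "fn", "fp", "tn")],
               list(tp = 9L, fn = 0L, fp = 3L, tn = 19L), ignore_attr = TRUE)

  concordant <- data.frame(mri_category = c("remyelinated", "early_active"),
                           histo_category = c("remyelinated", "early_active"))
  cmc <- binarize_and_tabulate(concordant)
  expect_equal(cmc$fp + cmc$fn, 0)

  # rows without histology are excluded and counted
  tb$histo_category[1:4] <- NA
  expect_message(cm2 <- binarize_and_tabulate(tb), "4 lesion")
  expect_equal(attr(cm2, "excluded"), 4)
  expect_equal(cm2$tp + cm2$fn + cm2$fp + cm2$tn, nrow(tb) - 4)
})

test_that("cross-tabulation equals a brute-force pairwise tally on random tables", {
  set.seed(3)
  classes <- c("early_active", "chronic_demyelinated", "remyelinated")
  for (rep in 1:50) {
    n <- sample(5:40, 1)
    tb <- data.frame(mri_category = sample(classes, n, TRUE),
                     histo_category = sample(classes, n, TRUE))
    cm <- binarize_and_tabulate(tb)
    tally <- c(tp = 0, fn = 0, fp = 0, tn = 0)
    for (i in seq_len(n)) {
      m <- tb$mri_category[i] == "remyelinated"
      h <- tb$histo_category[i] == "remyelinated"
      cell <- if (m && h) "tp" else if (!m && h) "fn" else if (m) "fp" else "tn"
      tally[cell] <- tally[cell] + 1
    }
    expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]), tally)
  }
})

test_that("sensitivity and specificity follow their definitions", {
  cm <- confusion_matrix(tp = 9, fn = 0, fp = 3, tn = 19)
  ss <- sensitivity_specificity(cm)
  expect_equal(ss$sensitivity, 1.0)
  expect_equal(ss$specificity, 19 / 22)

  perfect <- confusion_matrix(tp = 5, fn = 0, fp = 0, tn = 7)
  expect_equal(sensitivity_specificity(perfect),
               list(sensitivity = 1, specificity = 1))
  expect_error(sensitivity_specificity(confusion_matrix(0, 0, 3, 19)),
               "sensitivity")

  # brute-force definition check on random matrices
  set.seed(10)
  for (rep in 1:200) {
    cts <- rpois(4, 6) + c(1, 0, 0, 1)  # keep denominators positive
    cm <- confusion_matrix(cts[1], cts[2], cts[3], cts[4])
    ss <- sensitivity_specificity(cm)
    expect_equal(ss$sensitivity, cts[1] / (cts[1] + cts[2]))
    expect_equal(ss$specificity, cts[4] / (cts[4] + cts[3]))
  }
})

test_that("concordance summary flags the specificity/accuracy discrepancy", {
  cm <- confusion_matrix(tp = 9, fn = 0, fp = 3, tn = 19)
  cs <- concordance_summary(cm, published_specificity_pct = 90)
  expect_equal(cs$sensitivity_pct, 100)
  expect_equal(cs$specificity_pct, 100 * 19 / 22, tolerance = 1e-12)
  expect_equal(cs$accuracy_pct, 100 * 28 / 31, tolerance = 1e-12)
  expect_true(cs$discrepancy)
})

test_that("Cohen's kappa: perfect, chance-level, and hand-computed agreement", {
  expect_equal(cohen_kappa(c("a", "b", "c", "a"), c("a", "b", "c", "a")), 1)

  # independent raters, n = 10,000 -> kappa ~ 0
  set.seed(5)
  a <- sample(letters[1:3], 1e4, TRUE)
  b <- sample(letters[1:3], 1e4, TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.03)

  # 40-item 3-class pair with high raw agreement vs explicit p_o/p_e arithmetic
  set.seed(8)
  x <- sample(c("ea", "cd", "rm"), 40, TRUE, prob = c(0.3, 0.25, 0.45))
  y <- x
  flip <- c(3, 17)  # 38/40 agree
  y[flip] <- ifelse(x[flip] == "ea", "cd", "ea")
  tab <- table(factor(x), factor(y)) / 40
  p_o <- sum(diag(tab)); p_e <- sum(rowSums(tab) * colSums(tab))
  expect_equal(cohen_kappa(x, y), (p_o - p_e) / (1 - p_e))
  expect_equal(p_o, 0.95)

  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  expect_equal(cohen_kappa(x, y),
               e1071::classAgreement(table(x, y))$kappa, tolerance = 1e-12)
  expect_error(cohen_kappa(1:3, 1:4), "length")
})

test_that("kappa stays in [-1, 1] and is 1 only at perfect agreement", {
  set.seed(6)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    a <- sample(1:3, n, TRUE); b <- sample(1:3, n, TRUE)
    k <- cohen_kappa(a, b)
    if (!is.na(k)) {
      expect_gte(k, -1); expect_lte(k, 1)
      if (k == 1) expect_true(all(a == b))
    }
  }
})

test_that("point-biserial correlation matches Pearson and its exact permutation oracle", {
  expect_equal(point_biserial(c(0, 0, 1, 1), c(0, 0, 1, 1))$r, 1)
  expect_error(point_biserial(c(0, 0, 1, 1), c(2, 2, 2, 2)), "variance")
  expect_error(point_biserial(c(0, 0, 0, 0), c(1, 2, 3, 4)), "nonempty")

  # published steroid subgroups: 10/21 treated vs 8/19 untreated remyelinated
  treated <- c(rep(1, 21), rep(0, 19))
  remyel <- c(rep(1, 10), rep(0, 11), rep(1, 8), rep(0, 11))
  pb <- point_biserial(treated, remyel)
  pe <- point_biserial_exact_p(treated, remyel)
  expect_gt(pb$p, 0.05)   # non-significant, as reported (p = 0.8)
  expect_gt(pe, 0.05)
  expect_lt(abs(pb$p - pe), 0.25)  # t approximation near the exact tail

  # the exact oracle agrees with direct enumeration on a small case
  x <- c(1, 1, 1, 0, 0, 0); y <- c(1, 1, 0, 1, 0, 0)
  robs <- abs(cor(x, y))
  perms <- combn(6, 3)
  hits <- mean(apply(perms, 2, function(ix) {
    yy <- numeric(6); yy[ix] <- 1
    abs(cor(x, yy)) >= robs - 1e-12
  }))
  expect_equal(point_biserial_exact_p(x, y), hits)
})

test_that("age-OPC correlation recovers sign and handles degenerate input", {
  tb <- data.frame(lesion_age_weeks = 1:10, opc_count = 20 - (1:10))
  expect_equal(correlate_age_opc(tb)$r, -1)
  expect_error(correlate_age_opc(tb[1:2, ]), "at least 3")

  set.seed(9)
  null_tb <- data.frame(lesion_age_weeks = rnorm(1000), opc_count = rnorm(1000))
  expect_lt(abs(correlate_age_opc(null_tb)$r), 0.1)
})

test_that("negative age-OPC slope in the generator is recovered across seeds", {
  set.seed(123)
  signs <- replicate(100, {
    classes <- sample(c("early_active", "chronic_demyelinated", "remyelinated"),
                      30, TRUE)
    ages <- ifelse(classes == "early_active", runif(30, 2, 9), runif(30, 12, 28))
    tb <- data.frame(lesion_age_weeks = ages,
                     opc_count = vapply(seq_len(30), function(i)
                       histo_truth(classes[i], ages[i])$opc_count, integer(1)))
    correlate_age_opc(tb)$r < 0
  })
  expect_gte(mean(signs), 0.95)
})

test_that("group comparison: t-test and ANOVA behave on null and separated samples", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- group_compare(g, "t_test")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # NAWM vs remyelinated PLP moments at n=30: strongly separated
  set.seed(11)
  sep <- replicate(20, {
    gg <- list(nawm = rnorm(30, 2.6, 0.3), remyel = rnorm(30, 4.5, 1.1))
    group_compare(gg, "t_test")$p < 0.001
  })
  expect_gte(mean(sep), 0.95)

  expect_error(group_compare(list(a = 1:3), "anova"), "2 groups")
  expect_error(group_compare(list(a = 1, b = 1:3), "t_test"), "at least 2 values")
  three <- list(rnorm(10), rnorm(10), rnorm(10))
  expect_true(group_compare(three, "anova")$p > 0)
})
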