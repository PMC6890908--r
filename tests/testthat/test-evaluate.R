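test_that("Mann-Whitney handles identical and fully separated groups", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)
  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / choose(6, 3))
})

test_that("exact Mann-Whitney p matches full enumeration, ties included", {
  set.seed(14)
  for (rep in 1:8) {
    a <- sample(1:6, 4, replace = TRUE)
    b <- sample(1:6, 5, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p, mw_enum_oracle(a, b), tolerance = 1e-12,
                 info = paste("rep", rep))
  }
})

test_that("large-sample Mann-Whitney agrees with wilcox.test", {
  set.seed(15)
  a <- rnorm(25); b <- rnorm(25, 0.7)
  got <- mann_whitney(a, b, exact_limit = 100)
  expect_equal(got$method, "normal_approx")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("ROC AUC covers the degenerate anchors", {
  perfect <- roc_auc(c(1, 2, 3, 10, 11), rep(c("NPS", "PS"), c(3, 2)),
                     direction = "higher")
  expect_equal(perfect$auc, 1)
  tied <- roc_auc(rep(2, 10), rep(c("NPS", "PS"), 5))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_auc(1:5, rep("PS", 5)), "both classes")
})

test_that("AUC equals the brute-force pairwise oracle and the U identity", {
  set.seed(16)
  for (rep in 1:10) {
    scores <- sample(1:8, 14, replace = TRUE)  # force ties
    labels <- rep(c("NPS", "PS"), 7)
    roc <- roc_auc(scores, labels, direction = "higher")
    expect_equal(roc$auc, auc_oracle(scores, labels == "PS"),
                 tolerance = 1e-12)
    u <- mann_whitney(scores[labels == "PS"], scores[labels == "NPS"])$U
    expect_equal(roc$auc, u / (roc$n_pos * roc$n_neg), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  scores <- rnorm(40)
  labels <- rep(c("NPS", "PS"), 20)
  a1 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a1)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels)$auc, a1)
  # direction flip mirrors the AUC
  expect_equal(roc_auc(-scores, labels, direction = "lower")$auc, a1)
})

test_that("AUC and DeLong p agree with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(18)
  lab <- rep(c("NPS", "PS"), c(30, 30))
  s1 <- rnorm(60) + (lab == "PS") * 1.1
  s2 <- rnorm(60) + (lab == "PS") * 0.6
  r1 <- roc_auc(s1, lab); r2 <- roc_auc(s2, lab)
  p1 <- pROC::roc(lab, s1, levels = c("NPS", "PS"), direction = "<",
                  quiet = TRUE)
  p2 <- pROC::roc(lab, s2, levels = c("NPS", "PS"), direction = "<",
                  quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(p1)), tolerance = 1e-12)
  expect_equal(auc_variance(r1), as.numeric(pROC::var(p1, method = "delong")),
               tolerance = 1e-10)
  ours <- delong_compare(r1, r2)
  ref <- pROC::roc.test(p1, p2, method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("DeLong self-comparison is exactly null", {
  set.seed(19)
  roc <- roc_auc(rnorm(30), rep(c("NPS", "PS"), 15))
  self <- delong_compare(roc, roc)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
})

test_that("DeLong p is consistent with a bootstrap difference test", {
  set.seed(20)
  lab <- rep(c("NPS", "PS"), c(15, 15))
  s1 <- rnorm(30) + (lab == "PS") * 1.4
  s2 <- rnorm(30) + (lab == "PS") * 0.5
  r1 <- roc_auc(s1, lab); r2 <- roc_auc(s2, lab)
  dl <- delong_compare(r1, r2)
  pos <- which(lab == "PS"); neg <- which(lab == "NPS")
  boots <- vapply(1:10000, function(i) {
    ip <- sample(pos, replace = TRUE); ineg <- sample(neg, replace = TRUE)
    idx <- c(ineg, ip)
    roc_auc(s1[idx], lab[idx])$auc - roc_auc(s2[idx], lab[idx])$auc
  }, numeric(1))
  p_boot <- 2 * stats::pnorm(-abs((r1$auc - r2$auc) / stats::sd(boots)))
  expect_lt(abs(dl$p - p_boot), 0.05)
})

test_that("DeLong test rejects strongly different AUCs with high power", {
  set.seed(22)
  rejections <- vapply(1:200, function(i) {
    lab <- rep(c("NPS", "PS"), each = 100)
    d1 <- qnorm(0.95) * sqrt(2)  # binormal separation for AUC 0.95
    d2 <- qnorm(0.70) * sqrt(2)
    s1 <- rnorm(200) + (lab == "PS") * d1
    s2 <- rnorm(200) + (lab == "PS") * d2
    delong_compare(roc_auc(s1, lab), roc_auc(s2, lab))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
})

test_that("DeLong variance is Hanley-like for binormal samples", {
  set.seed(23)
  lab <- rep(c("NPS", "PS"), each = 150)
  s <- rnorm(300) + (lab == "PS") * 1.2
  roc <- roc_auc(s, lab)
  a <- roc$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  hanley <- (a * (1 - a) + (roc$n_pos - 1) * (q1 - a^2) +
               (roc$n_neg - 1) * (q2 - a^2)) / (roc$n_pos * roc$n_neg)
  expect_lt(abs(auc_variance(roc) - hanley) / hanley, 0.2)
})

test_that("Youden cutoff matches an exhaustive scan and flips with direction", {
  set.seed(24)
  scores <- c(1, 2, 2, 3, 4, 5, 6, 6, 7, 9)
  labels <- c("NPS", "NPS", "NPS", "PS", "NPS", "PS", "PS", "NPS", "PS", "PS")
  roc <- roc_auc(scores, labels, direction = "higher")
  cut <- optimal_cutoff(roc)
  # oracle: scan a fine threshold grid
  grid <- seq(0, 10, by = 0.01)
  j <- vapply(grid, function(t) {
    mean(scores[labels == "PS"] >= t) + mean(scores[labels == "NPS"] < t) - 1
  }, numeric(1))
  expect_equal(cut$youden_j, max(j), tolerance = 1e-12)
  got <- mean(scores[labels == "PS"] >= cut$cutoff) +
    mean(scores[labels == "NPS"] < cut$cutoff) - 1
  expect_equal(got, max(j))
  # flipped direction mirrors the cutoff
  roc2 <- roc_auc(-scores, labels, direction = "lower")
  cut2 <- optimal_cutoff(roc2)
  expect_equal(cut2$cutoff, -cut$cutoff)
  expect_equal(cut2$sensitivity, cut$sensitivity)
})

test_that("perfectly separated scores produce a perfectly classifying cutoff", {
  roc <- roc_auc(c(1, 2, 3, 8, 9), rep(c("NPS", "PS"), c(3, 2)),
                 direction = "higher")
  cut <- optimal_cutoff(roc)
  expect_gt(cut$cutoff, 3); expect_lt(cut$cutoff, 8)
  expect_equal(cut$sensitivity, 1); expect_equal(cut$specificity, 1)
})

test_that("confusion metrics flag undefined ratios and reject bad counts", {
  m <- confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("report has the expected shape and re-derivable metrics", {
  co <- cohort_spec(n_ps = 40, n_nps = 30, seed = 31)
  tab <- tabular_cohort(co)
  stages <- list(
    svm_q = svm_stage(tab, c("sbr_q", "pcr_q", "ai_q"), split_seed = 3,
                      svm_seed = 3),
    svm_v = svm_stage(tab, c("sbr_v", "fd_v", "ai_v"), split_seed = 3,
                      svm_seed = 3))
  rep <- build_report(tab, stages)
  expect_equal(nrow(rep$table), 8)
  expect_setequal(rep$table$index,
                  c("sbr_q", "pcr_q", "ai_q", "sbr_v", "fd_v", "ai_v",
                    "svm_q", "svm_v"))
  expect_equal(nrow(rep$comparisons), 4)
  # every reported percentage must re-derive from its own counts
  for (i in seq_len(nrow(rep$table))) {
    r <- rep$table[i, ]
    m <- confusion_metrics(r$tp, r$fp, r$fn, r$tn)
    expect_equal(r$sensitivity, m$sensitivity)
    expect_equal(r$specificity, m$specificity)
    expect_equal(r$accuracy, m$accuracy)
  }
  # direction conventions: all AUCs should favour the encoded orientation
  expect_true(all(rep$table$auc > 0.5))
  expect_error(build_report(transform(tab, label = NA)), "labels")
})
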