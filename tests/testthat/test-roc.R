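# Prediction-accuracy evaluation: labels, sensitivity/specificity, ROC.

fake_obs <- function(n_primers = 12, seed = 1, signal = TRUE) {
  set.seed(seed)
  n2 <- n_primers^2
  badness <- matrix(rexp(n2, 1 / 50), n_primers, n_primers)
  badness <- (badness + t(badness)) / 2
  reads <- matrix(0, n_primers, n_primers)
  if (signal) {
    # dimer reads grow with badness plus noise: a learnable signal
    reads[] <- rpois(n2, lambda = pmax(badness - 40, 0))
  } else {
    reads[] <- rpois(n2, lambda = 20)
  }
  pair_observations(badness, reads)
}

test_that("the pair universe covers all ordered pairs including self-pairs", {
  obs <- fake_obs(n_primers = 8)
  expect_equal(nrow(obs), 64)
  expect_true(any(obs$a == obs$b))
  # symmetric duplication: (a,b) and (b,a) carry the same values
  m <- merge(obs, obs, by.x = c("a", "b"), by.y = c("b", "a"))
  expect_equal(m$badness.x, m$badness.y)
  expect_equal(m$dimer_reads.x, m$dimer_reads.y)
})

test_that("observed labels use a strict reads threshold", {
  obs <- data.frame(a = 1, b = 1:3, badness = 1,
                    dimer_reads = c(0, 10, 11))
  expect_equal(label_observed(obs, 10), c(FALSE, FALSE, TRUE))
  expect_equal(label_observed(obs, 0), c(FALSE, TRUE, TRUE))
})

test_that("sensitivity and specificity handle boundary cases", {
  obs <- data.frame(a = 1, b = 1:4, badness = c(1, 2, 3, 4),
                    dimer_reads = c(0, 0, 0, 0))
  expect_warning(ss <- sens_spec(obs, reads_threshold = 10,
                                 badness_threshold = Inf),
                 "undefined")
  expect_true(is.nan(ss[["sensitivity"]]))
  expect_equal(ss[["specificity"]], 1)
  obs2 <- data.frame(a = 1, b = 1:4, badness = c(1, 2, 3, 4),
                     dimer_reads = c(0, 0, 100, 100))
  ss2 <- sens_spec(obs2, reads_threshold = 10, badness_threshold = 2.5)
  expect_equal(unname(ss2), c(1, 1))
})

test_that("perfectly separated scores give AUROC 1 and random scores ~0.5", {
  obs <- data.frame(a = 1, b = 1:100,
                    badness = c(runif(50, 60, 100), runif(50, 0, 40)),
                    dimer_reads = c(rep(100, 50), rep(0, 50)))
  roc <- roc_auc(obs, reads_threshold = 10)
  expect_equal(roc$auroc, 1)
  # null: scores independent of labels -> chance-level discrimination
  set.seed(5)
  obs_null <- data.frame(a = 1, b = 1:400, badness = rexp(400, 1 / 50),
                         dimer_reads = rpois(400, 20))
  roc_null <- roc_auc(obs_null, reads_threshold = 20)
  expect_lt(abs(roc_null$auroc - 0.5), 0.08)
})

test_that("AUROC equals the concordance rank statistic and pROC's value", {
  obs <- fake_obs(seed = 3)
  roc <- roc_auc(obs, reads_threshold = 15)
  truth <- label_observed(obs, 15)
  # Mann-Whitney formulation with tie correction
  r <- rank(obs$badness)
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  auc_rank <- (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  expect_equal(roc$auroc, auc_rank, tolerance = 1e-9)
  skip_if_not_installed("pROC")
  auc_proc <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = obs$badness, quiet = TRUE,
    direction = "<")))
  expect_equal(roc$auroc, auc_proc, tolerance = 1e-9)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  obs <- fake_obs(seed = 9)
  roc1 <- roc_auc(obs, reads_threshold = 15)
  obs2 <- obs
  obs2$badness <- log1p(obs$badness)
  expect_equal(roc_auc(obs2, 15)$auroc, roc1$auroc)
})

test_that("ROC points form a monotone staircase and errors on degenerate classes", {
  obs <- fake_obs(seed = 13)
  roc <- roc_auc(obs, reads_threshold = 15)
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))
  expect_true(all(roc$points$sensitivity >= 0 & roc$points$sensitivity <= 1))
  obs_all_neg <- data.frame(a = 1, b = 1:5, badness = 1:5, dimer_reads = 0)
  expect_error(roc_auc(obs_all_neg, 10), "at least one positive")
})

test_that("the selected threshold maximizes sensitivity + specificity", {
  obs <- fake_obs(seed = 17)
  bt <- best_threshold(obs, reads_threshold = 15)
  got <- suppressWarnings(
    sens_spec(obs, 15, bt$badness_threshold))
  expect_equal(unname(got), c(bt$sensitivity, bt$specificity))
  # exhaustive scan over candidate thresholds cannot do better
  cand <- c(-Inf, sort(unique(obs$badness)), Inf)
  best_scan <- max(vapply(cand, function(th) {
    ss <- sens_spec(obs, 15, th)
    ss[["sensitivity"]] + ss[["specificity"]]
  }, numeric(1)))
  expect_equal(bt$sensitivity + bt$specificity, best_scan, tolerance = 1e-12)
})

test_that("top-k report counts overlap between observed and predicted lists", {
  # identical rankings -> full overlap
  obs <- data.frame(a = 1:6, b = 1:6, badness = 6:1, dimer_reads = 60:55)
  expect_equal(top_k_report(obs, k = 5)$overlap, 5)
  # disjoint rankings -> zero overlap
  obs2 <- data.frame(a = 1:10, b = 1:10, badness = 1:10,
                     dimer_reads = c(rep(100, 5), rep(0, 5)))
  expect_equal(top_k_report(obs2, k = 5)$overlap, 0)
  rep5 <- top_k_report(obs2, k = 5)
  expect_equal(nrow(rep5$observed), 5)
  expect_equal(nrow(rep5$predicted), 5)
})
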