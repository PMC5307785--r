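test_that("tie-averaged ranking matches the published negative-class example", {
  ## Original experiment, negative class: four zeros tie at ranks 3..6
  expect_equal(rank_with_ties(c(0, 0, 1.0, 0.5, 0, 0)),
               c(4.5, 4.5, 1, 2, 4.5, 4.5))
  expect_equal(rank_with_ties(rep(0.7, 6)), rep(3.5, 6))
  expect_equal(rank_with_ties(c(9, 7, 5, 3)), 1:4)
})

test_that("the Iman-Davenport statistic reproduces all four published values", {
  expected <- c(original = 1.956, smote = 12, pca = 4.241, `smote+pca` = 4.602)
  for (exp_name in names(expected)) {
    acc <- reference_accuracies(exp_name)
    rt <- t(apply(acc, 2, rank_with_ties))
    expect_equal(as.numeric(friedman_T1(rt)), unname(expected[exp_name]),
                 tolerance = 5e-4, label = exp_name)
  }
})

test_that("T1 agrees with the rank-sum brute-force formula on random tables", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      N <- sample(3:8, 1); k <- sample(3:8, 1)
      rt <- t(replicate(N, rank(runif(k))))
      expect_equal(as.numeric(friedman_T1(rt)), oracle_friedman_T1(rt),
                   tolerance = 1e-9)
    }
  })
  ## full tie in every problem: chi-square 0, T1 0
  rt0 <- matrix(3.5, 4, 6)
  t0 <- friedman_T1(rt0)
  expect_equal(as.numeric(t0), 0)
  expect_equal(attr(t0, "chisq"), 0)
  ## degenerate denominator reported as +Inf with a flag
  rtmax <- t(replicate(4, 1:6))
  tmax <- friedman_T1(rtmax)
  expect_true(is.infinite(tmax) && attr(tmax, "degenerate"))
  expect_error(friedman_T1(matrix(1, 2, 3)), "sum")
})

test_that("F critical values are correct", {
  expect_equal(round(f_critical(0.05, 5, 15), 2), 2.90)
  q <- f_critical(0.01, 3, 12)
  expect_equal(stats::pf(q, 3, 12), 0.99, tolerance = 1e-8)
  ## asymptotic limit: F(1, inf) crit -> chi-square(1) crit
  expect_equal(f_critical(0.05, 1, 1e7), stats::qchisq(0.95, 1) / 1,
               tolerance = 1e-3)
  expect_error(f_critical(1.5, 5, 15), "invalid")
})

test_that("Bonferroni-Dunn uses the standard critical value and rule", {
  avg <- c(kNN = 5.125, LVQNN = 1.125, MLPI = 3.375, MLPII = 2, RBFNN = 5.25,
           PNN = 4.125)
  bd <- bonferroni_dunn(avg, "kNN", N = 4)
  ## z at alpha/(2(k-1)) = 0.005 is 2.576; CD = 2.576 sqrt(42/24)
  expect_equal(bd$q, stats::qnorm(0.995), tolerance = 1e-12)
  expect_equal(bd$cd, stats::qnorm(0.995) * sqrt(42 / 24), tolerance = 1e-12)
  expect_equal(round(bd$cd, 2), 3.41)
  expect_false(bd$significant["kNN"][[1]])   # baseline vs itself never flags
  expect_error(bonferroni_dunn(avg, "XGB", N = 4), "baseline")
})

test_that("published significance conclusions hold under the printed CD", {
  sig_sets <- list(
    smote = c("LVQNN", "MLPII"),
    pca = c("LVQNN", "MLPI", "MLPII"),
    `smote+pca` = "LVQNN")
  for (exp_name in names(sig_sets)) {
    cmp <- compare_classifiers(reference_accuracies(exp_name),
                               baseline = "kNN", cd_override = 1.92)
    expect_setequal(names(cmp$significant)[cmp$significant],
                    sig_sets[[exp_name]])
    expect_true(cmp$reject_null)
  }
  ## Original experiment: T1 below the critical value, no rejection
  cmp0 <- compare_classifiers(reference_accuracies("original"), "kNN")
  expect_false(cmp0$reject_null)
})

test_that("average ranks recomputed from accuracies match the printed column", {
  printed <- list(
    smote = c(kNN = 5.125, LVQNN = 1.125, MLPI = 3.375, MLPII = 2,
              RBFNN = 5.25, PNN = 4.125),
    pca = c(kNN = 4.625, LVQNN = 2, MLPI = 2.25, MLPII = 2.375,
            RBFNN = 5.125, PNN = 4.625),
    `smote+pca` = c(kNN = 4.125, LVQNN = 1, MLPI = 3.75, MLPII = 2.625,
                    RBFNN = 4.75, PNN = 4.75))
  for (exp_name in names(printed)) {
    cmp <- compare_classifiers(reference_accuracies(exp_name), "kNN")
    expect_equal(cmp$avg_rank, printed[[exp_name]], label = exp_name)
    ## each class's ranks sum to k(k+1)/2 = 21
    expect_equal(unname(rowSums(cmp$rank_table)), rep(21, 4))
  }
})

test_that("configuration selection minimizes mean per-class rank", {
  one <- list(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(select_best_configuration(one)$index, 1L)
  dominated <- list(c(0.9, 0.9, 0.9, 0.9), c(0.5, 0.6, 0.7, 0.8),
                    c(0.1, 0.2, 0.3, 0.4))
  expect_equal(select_best_configuration(dominated)$index, 1L)
  ## mixed wins: hand-computed 3x4 rank table
  mixed <- list(c(1.0, 0.2, 0.2, 0.9),    # ranks 1, 3, 3, 1  mean 2
                c(0.5, 0.9, 0.3, 0.5),    # ranks 2, 1, 2, 3  mean 2
                c(0.3, 0.5, 0.9, 0.7))    # ranks 3, 2, 1, 2  mean 2
  expect_equal(select_best_configuration(mixed)$index, 1L)  # tie -> grid order
  mixed2 <- list(c(0.9, 0.1, 0.5, 0.1), c(0.5, 0.9, 0.9, 0.9),
                 c(0.1, 0.5, 0.1, 0.5))
  expect_equal(select_best_configuration(mixed2)$index, 2L)
  expect_error(select_best_configuration(list()), "no configurations")
})

test_that("LOO bookkeeping is exact on a hand-unrolled toy cohort", {
  ## 12 samples, 2 features, classes 3/3/3/3; kNN(1) with duplicates present
  withr::with_seed(40, {
    base <- matrix(rnorm(12 * 2, rep(c(0, 5, 10, 15), each = 3)), 12, 2)
  })
  y <- factor(rep(response_classes(), each = 3), levels = response_classes())
  acc <- loo_per_class_accuracy(list(family = "kNN", k = 1), base, y,
                                "original", seed = 1)
  ## manual fold enumeration with the same tie rules
  manual <- vapply(seq_len(12), function(i) {
    ztr <- scale(base[-i, ])
    zte <- scale(base[i, , drop = FALSE],
                 center = attr(ztr, "scaled:center"),
                 scale = attr(ztr, "scaled:scale"))
    d <- sqrt(rowSums(sweep(ztr, 2, zte)^2))
    as.character(y[-i][which.min(d)])
  }, "")
  expected <- vapply(levels(y), function(cl) {
    mean(manual[y == cl] == cl)
  }, 0)
  expect_equal(as.numeric(acc), unname(expected))
  ## each sample appears exactly once as the test singleton
  expect_length(attr(acc, "predictions"), 12L)
})

test_that("duplicated samples give a perfect kNN(1) LOO score", {
  withr::with_seed(50, {
    X0 <- matrix(rnorm(16), 8, 2)
  })
  X <- rbind(X0, X0 + 1e-9)
  y <- factor(rep(rep(response_classes(), each = 2), 2),
              levels = response_classes())
  acc <- loo_per_class_accuracy(list(family = "kNN", k = 1), X, y, "original")
  expect_equal(as.numeric(acc), rep(1, 4))
})

test_that("run_experiment assembles a consistent accuracy table and comparison", {
  d <- withr::with_seed(60, {
    X <- do.call(rbind, lapply(1:4, function(k) matrix(rnorm(12, 4 * k), 6, 2)))
    list(X = X, y = factor(rep(response_classes(), each = 6),
                           levels = response_classes()))
  })
  grids <- list(kNN = classifier_grid("kNN")[1:2],
                PNN = classifier_grid("PNN")[5:6])
  res <- run_experiment(d$X, d$y, "original", c("kNN", "PNN"), seed = 2,
                        grids = grids)
  expect_equal(dim(res$accuracy_table), c(2L, 4L))
  expect_equal(rownames(res$accuracy_table), c("kNN", "PNN"))
  expect_equal(colnames(res$accuracy_table), response_classes())
  expect_true(all(res$accuracy_table >= 0 & res$accuracy_table <= 1))
  expect_s3_class(res$comparison, "comparison_result")
  expect_equal(unname(rowSums(res$comparison$rank_table)), rep(3, 4))
})
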