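test_that("stratified folds partition the sample with near-equal sizes", {
  y <- rep(c(0, 1), each = 114)
  folds <- kfold_split(228, 10, seed = 3, stratify_by = y)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(22L, 23L)))
  expect_identical(sort(unlist(folds)), 1:228)
  # class balance holds within every fold
  for (f in folds) expect_lte(abs(sum(y[f] == 0) - sum(y[f] == 1)), 1)

  expect_identical(kfold_split(228, 10, seed = 3, stratify_by = y), folds)
  expect_false(identical(kfold_split(228, 10, seed = 4, stratify_by = y),
                         folds))

  singletons <- kfold_split(10, 10, seed = 1)
  expect_true(all(lengths(singletons) == 1))
  expect_error(kfold_split(5, 10), "n >= k")
})

test_that("trapezoid AUC equals the Mann-Whitney rank statistic", {
  # perfect ranking and chance level
  expect_equal(attr(roc_and_auc(c(1, 2, 3, 10, 11, 12),
                                rep(0:1, each = 3)), "auc"), 1)
  set.seed(1)
  sc <- rnorm(2000)
  tr <- rep(0:1, 1000)
  expect_lt(abs(attr(roc_and_auc(sc, tr), "auc") - 0.5), 0.05)

  # oracle identity, including heavily tied scores
  for (i in 1:20) {
    set.seed(i)
    n0 <- sample(10:80, 1)
    n1 <- sample(10:80, 1)
    s <- round(c(rnorm(n0), rnorm(n1, mean = 0.4)), sample(0:1, 1))
    y <- rep(0:1, c(n0, n1))
    auc <- attr(roc_and_auc(s, y), "auc")
    r <- rank(s)   # midranks
    u <- sum(r[y == 1]) - n1 * (n1 + 1) / 2
    expect_equal(auc, u / (n0 * n1), tolerance = 1e-12)
  }
  expect_error(roc_and_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  sc <- round(rnorm(300), 1)
  y <- rep(0:1, 150)
  ours <- attr(roc_and_auc(sc, y), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(3)
  rc <- roc_and_auc(sample(seq(-2, 2, 0.5), 60, replace = TRUE),
                    rbinom(60, 1, 0.5))
  expect_equal(unlist(rc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rc[nrow(rc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("complete mode keeps all 132 columns; runs are deterministic", {
  cf <- fitted_cohort(n_per_group = 6)
  res <- run_cv(cf$fm, mode = "complete", k = 4, seed = 5)
  expect_true(all(vapply(res, function(f) length(f$selected), 0) == 132))
  # held-out folds partition the cohort
  test_idx <- sort(unlist(lapply(res, `[[`, "test_idx")))
  expect_identical(test_idx, seq_len(nrow(cf$fm$x)))
  for (f in res) expect_length(intersect(f$train_idx, f$test_idx), 0)
  expect_true(all(vapply(res, `[[`, 0, "acc") >= 0 &
                    vapply(res, `[[`, 0, "acc") <= 1))

  res2 <- run_cv(cf$fm, mode = "complete", k = 4, seed = 5)
  expect_identical(res, res2)
})

test_that("reduced mode concentrates on the informative columns", {
  set.seed(6)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(rexp(n * 132) + 0.1, n, 132)
  colnames(x) <- sprintf("c%03d", 1:132)
  support <- 1:30
  x[, support] <- x[, support] + 1.2 * y
  res <- run_cv(x, labels = y, mode = "reduced", k = 5, seed = 7)
  counts <- vapply(res, function(f) length(f$selected), 0)
  expect_true(all(counts < 132))
  frac_true <- vapply(res, function(f) {
    mean(f$selected %in% colnames(x)[support])
  }, 0)
  # 30 informative columns pass almost surely; of the 102 noise columns
  # ~14% clear |r| >= 0.15 at n_train = 96, so the informative fraction
  # concentrates near 30 / (30 + 102 * 0.14) ~ 0.67
  expect_gt(mean(frac_true), 0.55)
  expect_gt(mean(vapply(res, function(f) {
    sum(f$selected %in% colnames(x)[support])
  }, 0)), 25)
  # fold-wise screening differs across folds
  expect_gt(length(unique(lapply(res, `[[`, "selected"))), 1)
})

test_that("screening decisions ignore mutated held-out rows", {
  cf <- fitted_cohort(n_per_group = 6)
  res <- run_cv(cf$fm, mode = "reduced", k = 4, seed = 11)
  # mutate each fold's test rows: per-fold train-side decisions identical
  for (f in res) {
    x_one <- cf$fm$x
    x_one[f$test_idx, ] <- x_one[f$test_idx, ] * 7 + 3
    res_mut <- run_cv(x_one, labels = cf$fm$labels, mode = "reduced",
                      k = 4, seed = 11)
    expect_identical(res_mut[[f$fold]]$selected, f$selected)
  }
})

test_that("repeated CV summarizes over fold permutations", {
  cf <- fitted_cohort(n_per_group = 6)
  rep3 <- repeat_cv(cf$fm, mode = "complete", n_repeats = 3, seed = 2,
                    k = 4)
  expect_equal(nrow(rep3$per_repeat), 3)
  expect_gte(rep3$sem_auc, 0)
  expect_equal(rep3$roc$fpr, seq(0, 1, 0.01))
  expect_true(all(rep3$roc$mean_tpr >= 0 & rep3$roc$mean_tpr <= 1))

  # degenerate repeats: same fold seed everywhere -> zero spread
  same <- repeat_cv(cf$fm, mode = "complete", n_repeats = 3, k = 4,
                    repeat_seeds = rep(17L, 3))
  expect_equal(same$sem_auc, 0)
  expect_equal(same$sem_cv_acc, 0)

  again <- repeat_cv(cf$fm, mode = "complete", n_repeats = 3, seed = 2,
                     k = 4)
  expect_identical(rep3$per_repeat, again$per_repeat)
})

test_that("the four contrasts pool groups with the right arithmetic", {
  set.seed(8)
  fits <- lapply(1:18, function(i) {
    ft <- data.frame(channel = montage_channels(),
                     S = rexp(22) + 1, k = runif(22, 0.5, 2),
                     A = rexp(22) + 1, c = runif(22, 8, 12),
                     w = runif(22, 0.5, 3), b = rexp(22) + 0.2)
    ft
  })
  names(fits) <- sprintf("s%02d", 1:18)
  fm <- build_feature_matrix(fits, labels = rep(c("HC", "AD", "VaD"),
                                                each = 6))
  ms <- summarize_models(fm, modes = "complete", n_repeats = 2, seed = 3,
                         k = 3, boxcox = "none")
  expect_equal(nrow(ms$table), 4)
  expect_equal(ms$table$contrast,
               c("HC vs AD", "HC vs VaD", "AD vs VaD", "HC vs AD&VaD"))
  expect_equal(ms$table$n_neg, c(6L, 6L, 6L, 6L))
  expect_equal(ms$table$n_pos, c(6L, 6L, 6L, 12L))

  fm_2g <- fm
  fm_2g$labels <- replace(as.character(fm$labels),
                          fm$labels == "VaD", "AD")
  expect_error(summarize_models(fm_2g, n_repeats = 1), "missing group")
})
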