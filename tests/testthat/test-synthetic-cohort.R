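test_that("zero effect scale makes all three group profiles identical", {
  profs <- lapply(c("HC", "AD", "VaD"), make_group_profile, effect_scale = 0)
  expect_identical(profs[[1]]$params, profs[[2]]$params)
  expect_identical(profs[[1]]$params, profs[[3]]$params)
})

test_that("group deviations follow the clinical contrast directions", {
  hc <- make_group_profile("HC", 1)
  ad <- make_group_profile("AD", 1)
  vad <- make_group_profile("VaD", 1)
  # AD: posterior alpha lower and slower than HC
  expect_lt(ad$params["O1", "A"], hc$params["O1", "A"])
  expect_lt(ad$params["O1", "c"], hc$params["O1", "c"])
  # VaD: low-frequency scale at least AD's on every channel
  expect_true(all(vad$params[, "S"] >= ad$params[, "S"]))
  # both dementias raise S over HC; deviations scale with effect_scale
  expect_true(all(ad$params[, "S"] > hc$params[, "S"]))
  half <- make_group_profile("AD", 0.5)
  expect_equal(half$params[, "S"] - hc$params[, "S"],
               (ad$params[, "S"] - hc$params[, "S"]) / 2)
})

test_that("profile construction rejects invalid input", {
  expect_error(make_group_profile("MCI"), "unknown group")
  expect_error(make_group_profile("AD", -1), "non-negative")
  expect_error(make_group_profile("AD", 1,
                                  base_config = list(jitter = list(S = -2))),
               "jitter")
})

test_that("subject draws are reproducible and respect degenerate jitter", {
  prof <- exact_profile("AD")
  tr <- sample_subject(prof, seed = 7)
  expect_identical(tr$params, prof$params)

  prof2 <- make_group_profile("HC", 1)
  a <- sample_subject(prof2, seed = 123, id = "x")
  b <- sample_subject(prof2, seed = 123, id = "x")
  expect_identical(a, b)
  expect_false(identical(a$params,
                         sample_subject(prof2, seed = 124)$params))
})

test_that("subject draws are unbiased around the profile (Monte Carlo)", {
  prof <- make_group_profile("HC", 1)
  n <- 1000
  cs <- vapply(seq_len(n), function(i) {
    sample_subject(prof, seed = 5000 + i)$params["Pz", "c"]
  }, 0)
  se <- prof$jitter[["c"]] / sqrt(n)
  expect_lt(abs(mean(cs) - prof$params["Pz", "c"]), 3 * se)
  # jitter SD is realized too (clipping at [6,14] is negligible here)
  expect_lt(abs(stats::sd(cs) - prof$jitter[["c"]]), 0.15)
})

test_that("parameter draws never leave the physical bounds", {
  prof <- make_group_profile("VaD", 1,
                             base_config = list(jitter = list(c = 4, w = 3)))
  for (i in 1:20) {
    p <- sample_subject(prof, seed = i)$params
    expect_true(all(p[, c("S", "A", "b")] >= 0))
    expect_true(all(p[, "c"] >= 6 & p[, "c"] <= 14))
    expect_true(all(p[, "k"] >= 0 & p[, "k"] <= 5))
    expect_true(all(p[, "w"] >= 0.3 & p[, "w"] <= 5))
  }
})

test_that("null spectrum parameters synthesize an all-zero signal", {
  prof <- exact_profile("HC", base = list(S = 0, A_posterior = 0,
                                          A_central = 0, A_frontal = 0,
                                          b = 0))
  tr <- sample_subject(prof, 1)
  sig <- synthesize_timeseries(tr, duration_s = 4, fs = 128,
                               artifact_rate = 0, seed = 2)
  expect_equal(max(abs(sig$data)), 0)
})

test_that("synthesized time series matches its analytic target spectrum", {
  tr <- sample_subject(make_group_profile("HC", 1), seed = 31)
  sig <- synthesize_timeseries(tr, duration_s = 335, fs = 256,
                               artifact_rate = 0, seed = 8)
  sp <- average_spectrum(segment_epochs(sig), id = tr$id)
  expect_equal(sp$n_epochs, 334)
  sel <- sp$freq >= 1 & sp$freq <= 30
  rel_err <- vapply(rownames(sp$power), function(ch) {
    target <- model_curve(tr$params[ch, ], sp$freq)
    abs(sum(sp$power[ch, sel]) - sum(target[sel])) / sum(target[sel])
  }, 0)
  expect_lt(max(rel_err), 0.05)
})

test_that("welch averaging error shrinks as epoch count grows", {
  tr <- sample_subject(make_group_profile("HC", 1), seed = 31)
  err_at <- function(dur, seed) {
    sig <- synthesize_timeseries(tr, duration_s = dur, fs = 256,
                                 artifact_rate = 0, seed = seed)
    sp <- average_spectrum(segment_epochs(sig))
    target <- model_curve(tr$params["O1", ], sp$freq)
    sel <- sp$freq >= 1 & sp$freq <= 30
    mean(abs(sp$power["O1", sel] - target[sel]) / target[sel])
  }
  short <- mean(vapply(1:3, function(s) err_at(35, s), 0))
  long <- mean(vapply(1:3, function(s) err_at(335, s), 0))
  expect_lt(long, short)
})

test_that("artifact injection rate matches the binomial contract", {
  tr <- sample_subject(make_group_profile("HC", 1), seed = 3)
  sig <- synthesize_timeseries(tr, duration_s = 540, fs = 128,
                               artifact_rate = 0.02, seed = 99)
  n_art <- length(sig$artifact_times)
  expected <- 540 * 0.02
  sdev <- sqrt(540 * 0.02 * 0.98)
  expect_gt(n_art, expected - 3 * sdev)
  expect_lt(n_art, expected + 3 * sdev)
  # transients reach the amplitude the rejection stage screens for
  expect_gt(max(abs(sig$data)), 500)
})

test_that("synthesize_timeseries validates its inputs", {
  tr <- sample_subject(make_group_profile("HC", 1), seed = 3)
  expect_error(synthesize_timeseries(tr, fs = 200), "sampling rate")
  expect_error(synthesize_timeseries(tr, duration_s = 0), "positive")
  expect_error(synthesize_timeseries(tr, artifact_rate = 2), "artifact_rate")
})

test_that("cohorts are labeled, sized and reproducible", {
  coh <- synthesize_cohort(cohort_config(groups = c("HC", "AD"),
                                         n_per_group = 114), seed = 1)
  expect_equal(nrow(coh$manifest), 228)
  expect_equal(as.vector(table(coh$manifest$group)[c("HC", "AD")]),
               c(114L, 114L))

  small <- cohort_config(groups = c("HC", "AD"), n_per_group = 2)
  c1 <- synthesize_cohort(small, seed = 5)
  expect_length(c1$spectra, 4)
  expect_identical(names(c1$spectra), c1$manifest$id)
  expect_identical(vapply(c1$truths, `[[`, "", "group"),
                   stats::setNames(c1$manifest$group, c1$manifest$id))

  c2 <- synthesize_cohort(small, seed = 5)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$spectra[[1]]$power, c2$spectra[[1]]$power)

  ts_cfg <- cohort_config(groups = "HC", n_per_group = 2,
                          mode = "timeseries", duration_s = 5, fs = 128,
                          artifact_rate = 0)
  t1 <- synthesize_cohort(ts_cfg, seed = 9)
  t2 <- synthesize_cohort(ts_cfg, seed = 9)
  expect_identical(t1$signals[[1]]$data, t2$signals[[1]]$data)

  expect_error(synthesize_cohort(cohort_config(n_per_group = 1), seed = 1),
               "at least 2")
})

test_that("direct-spectra mode is mean-unbiased for the model curve", {
  tr <- sample_subject(make_group_profile("HC", 1), seed = 11)
  mu <- model_curve(tr$params["O1", ], seq(0.5, 50, by = 0.5))
  acc <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    acc <- acc + synthesize_spectra(tr, seed = i)$power["O1", ]
  }
  expect_lt(max(abs(acc / n_rep - mu) / mu), 0.05)
})
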