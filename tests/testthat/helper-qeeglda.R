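# shared fixtures, built in code

# a bare eeg_signal from a data matrix
make_signal <- function(data, fs = 256) {
  if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  chans <- montage_channels()[seq_len(ncol(data))]
  structure(list(data = data, fs = fs, channels = chans,
                 duration_s = nrow(data) / fs),
            class = "eeg_signal")
}

# a profile whose subjects are exact copies of the profile (no jitter)
exact_profile <- function(group = "HC", effect_scale = 1, ...) {
  make_group_profile(group, effect_scale,
                     base_config = list(jitter = as.list(
                       c(S = 0, k = 0, A = 0, c = 0, w = 0, b = 0)), ...))
}

# small fitted cohort in direct-spectra mode; cached per arg set so several
# tests can share one
.fit_cache <- new.env(parent = emptyenv())
fitted_cohort <- function(groups = c("HC", "AD"), n_per_group = 6,
                          effect_scale = 1, seed = 42, n_epochs = 334) {
  key <- paste(c(groups, n_per_group, effect_scale, seed, n_epochs),
               collapse = "_")
  if (is.null(.fit_cache[[key]])) {
    coh <- synthesize_cohort(
      cohort_config(groups = groups, n_per_group = n_per_group,
                    effect_scale = effect_scale, n_epochs = n_epochs),
      seed = seed)
    fits <- lapply(coh$spectra, fit_subject)
    .fit_cache[[key]] <- list(cohort = coh, fits = fits,
                              fm = build_feature_matrix(
                                fits, labels = coh$manifest$group))
  }
  .fit_cache[[key]]
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# amplitude of a sinusoid at frequency f in a (trimmed) signal
sine_amplitude <- function(x, f, fs, trim_s = 1) {
  n <- length(x)
  keep <- (trim_s * fs):(n - trim_s * fs)
  t <- keep / fs
  fit <- stats::lm(x[keep] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
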