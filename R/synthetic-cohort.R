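#' Ground-truth spectral profile for a diagnostic group
#'
#' Builds the per-channel true parameter table for one of the three
#' groups. The healthy-control (HC) profile is the base; the dementia
#' profiles deviate from it in the directions the qEEG literature reports:
#'
#' * AD: posterior alpha amplitude `A` reduced and alpha center `c` slowed
#'   at the parieto-occipital channels; low-frequency scale `S` raised
#'   globally.
#' * VaD: `S` raised globally more strongly than in AD; `A` reduced at all
#'   channels; posterior `c` slowed as in AD (a slowed posterior dominant
#'   rhythm is common to both dementias, so it separates either group
#'   from HC but not the two dementias from each other).
#'
#' Every deviation scales linearly with `effect_scale`; at 0 the three
#' profiles are identical (the null cohort used for calibration tests).
#' Default effect sizes at `effect_scale = 1`: AD multiplies posterior `A`
#' by 0.7, subtracts 1 Hz from posterior `c`, and multiplies `S` by 1.3;
#' VaD multiplies `S` by 1.8, multiplies `A` by 0.8, and subtracts 1 Hz
#' from posterior `c`.
#'
#' @param group_label `"HC"`, `"AD"` or `"VaD"`.
#' @param effect_scale non-negative multiplier on all group deviations.
#' @param base_config optional list overriding base parameter levels,
#'   jitter scales and jitter correlations; see [cohort_config()] fields
#'   `base`, `jitter`, `kb_cor`, `ch_cor`.
#' @return A `group_profile` object: list with `group`, `params`
#'   (22 x 6 matrix of true parameter values, channels in montage order),
#'   `jitter` (named per-parameter between-subject SDs; defaults
#'   `S = 8, k = 0.3, A = 6, c = 1.2, w = 0.4, b = 0.5`, i.e.
#'   between-subject spread comparable to the group effects, as in real
#'   qEEG cohorts), `kb_cor` (correlation of the `k` and `b` jitter),
#'   `ch_cor` (across-channel correlation of the jitter, default 0.7),
#'   `effect_scale`.
#' @export
#' @examples
#' prof <- make_group_profile("AD", effect_scale = 1)
#' prof$params["O1", ]
make_group_profile <- function(group_label, effect_scale = 1,
                               base_config = list()) {
  if (!group_label %in% c("HC", "AD", "VaD")) {
    stop("unknown group label: ", group_label)
  }
  if (!is.finite(effect_scale) || effect_scale < 0) {
    stop("effect_scale must be non-negative")
  }
  ch <- montage_channels()
  post <- posterior_channels()

  base <- list(
    S = 15, k = 1.2, A_posterior = 18, A_central = 10, A_frontal = 6,
    c = 10, w = 1.5, b = 1
  )
  jitter <- c(S = 8, k = 0.3, A = 6, c = 1.2, w = 0.4, b = 0.5)
  kb_cor <- 0
  ch_cor <- 0.7
  if (!is.null(base_config$base)) base[names(base_config$base)] <- base_config$base
  if (!is.null(base_config$jitter)) {
    j <- unlist(base_config$jitter)
    jitter[names(j)] <- j
  }
  if (!is.null(base_config$kb_cor)) kb_cor <- base_config$kb_cor
  if (!is.null(base_config$ch_cor)) ch_cor <- base_config$ch_cor
  if (any(jitter < 0) || any(!is.finite(jitter))) {
    stop("jitter scales must be finite and non-negative")
  }
  stopifnot(ch_cor >= 0, ch_cor <= 1)

  A <- rep(base$A_central, length(ch))
  names(A) <- ch
  A[post] <- base$A_posterior
  A[c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8")] <- base$A_frontal

  params <- cbind(S = rep(base$S, length(ch)), k = base$k, A = A,
                  c = base$c, w = base$w, b = base$b)
  rownames(params) <- ch

  es <- effect_scale
  if (group_label == "AD") {
    params[, "S"] <- params[, "S"] * (1 + es * 0.3)
    params[post, "A"] <- params[post, "A"] * (1 - es * 0.3)
    params[post, "c"] <- pmax(params[post, "c"] - es * 1.0, 6)
  } else if (group_label == "VaD") {
    params[, "S"] <- params[, "S"] * (1 + es * 0.8)
    params[, "A"] <- params[, "A"] * (1 - es * 0.2)
    # slowing of the posterior dominant rhythm is common to both dementias
    params[post, "c"] <- pmax(params[post, "c"] - es * 1.0, 6)
  }

  structure(list(group = group_label, params = params, jitter = jitter,
                 kb_cor = kb_cor, ch_cor = ch_cor,
                 effect_scale = effect_scale),
            class = "group_profile")
}

#' Draw one subject's true parameters from a group profile
#'
#' Each parameter is drawn per channel as a normal deviate around the
#' profile value with the profile's per-parameter jitter SD, then clipped
#' to the physical bounds (`S, A, b >= 0`, `k` in \[0,5\], `c` in
#' \[6,14\] Hz, `w` in \[0.3,5\] Hz). The deviate mixes a subject-level
#' component shared by all channels with an independent per-channel
#' component, with `ch_cor` (default 0.7) the across-channel correlation:
#' real between-subject spectral variability is largely global (skull
#' conductivity, vigilance, individual alpha level shift whole-head
#' spectra coherently), and without the shared component a multivariate
#' classifier could average per-channel noise away and separate groups
#' far too easily. If the profile sets a nonzero `kb_cor`, the `k` and
#' `b` deviates additionally share a component making their
#' between-subject correlation equal to it (the coupling fitted
#' parameters show in real cohorts). The draw is fully reproducible from
#' `(profile, seed)`.
#'
#' @param profile a `group_profile`.
#' @param seed integer seed for this subject.
#' @param id subject identifier stored in the result.
#' @return A `subject_truth` object: list with `id`, `group`, `params`
#'   (22 x 6 matrix), `seed`.
#' @export
sample_subject <- function(profile, seed, id = "s1") {
  stopifnot(inherits(profile, "group_profile"))
  pm <- profile$params
  jit <- profile$jitter
  rho <- profile$kb_cor
  cc <- profile$ch_cor
  nch <- nrow(pm)
  draw <- with_seed(as.integer(seed), {
    kb_couple <- function(z, shared) {
      # shared component across k and b makes cor(k_jit, b_jit) = rho
      z[, "k"] <- sqrt(abs(rho)) * shared + sqrt(1 - abs(rho)) * z[, "k"]
      z[, "b"] <- sign(rho) * sqrt(abs(rho)) * shared +
        sqrt(1 - abs(rho)) * z[, "b"]
      z
    }
    zch <- matrix(stats::rnorm(nch * 6), nch, 6,
                  dimnames = list(rownames(pm), param_names()))
    zsub <- matrix(stats::rnorm(6), 1, 6,
                   dimnames = list(NULL, param_names()))
    if (rho != 0) {
      zch <- kb_couple(zch, stats::rnorm(nch))
      zsub <- kb_couple(zsub, stats::rnorm(1))
    }
    # mix subject-level (shared across channels) and channel-level parts
    sqrt(cc) * zsub[rep(1, nch), ] + sqrt(1 - cc) * zch
  })
  out <- pm + sweep(draw, 2, jit[param_names()], `*`)
  out <- pmin(pmax(out, rep(.param_lower, each = nch)),
              rep(.param_upper, each = nch))
  structure(list(id = id, group = profile$group, params = out,
                 seed = as.integer(seed)),
            class = "subject_truth")
}

#' Synthesize a multi-channel EEG time series from true parameters
#'
#' Per channel, colored noise whose expected power spectrum equals the
#' six-parameter model curve of the subject's true parameters: the model
#' curve (power per 0.5-Hz bin) is converted to a power spectral density,
#' amplitudes are placed on the full-length FFT grid between 0.5 and 50 Hz
#' with independent uniform random phases, and the signal is the real
#' inverse FFT. With probability `artifact_rate` per second, a
#' high-amplitude transient (a 0.25-s Gaussian-windowed 4-Hz wave, at
#' least 500 uV peak, applied to all channels with random polarity) is
#' added, emulating movement artifacts that amplitude thresholding should
#' remove. Deterministic given `seed`.
#'
#' @param truth a `subject_truth`.
#' @param duration_s recording length in seconds (> 0).
#' @param fs sampling rate; one of 128, 256, 500 Hz.
#' @param artifact_rate per-second probability of an injected transient,
#'   in \[0, 1\].
#' @param seed integer seed.
#' @return An `eeg_signal` object: list with `data` (time x 22 matrix,
#'   uV), `fs`, `channels`, `duration_s`, and `artifact_times` (seconds at
#'   which transients were injected).
#' @export
synthesize_timeseries <- function(truth, duration_s = 540, fs = 256,
                                  artifact_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "subject_truth"))
  if (!fs %in% c(128, 256, 500)) stop("unsupported sampling rate: ", fs)
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("duration must be positive")
  }
  if (artifact_rate < 0 || artifact_rate > 1) {
    stop("artifact_rate must be in [0, 1]")
  }
  n <- round(duration_s * fs)
  nch <- nrow(truth$params)
  df <- fs / n
  k_idx <- seq_len(floor(n / 2) - 1)       # positive non-Nyquist bins
  fgrid <- k_idx * df
  inband <- fgrid >= 0.5 & fgrid <= min(50, fs / 2 - 1)

  with_seed(as.integer(seed), {
    x <- matrix(0, n, nch)
    for (j in seq_len(nch)) {
      p <- truth$params[j, ]
      if (p[["S"]] == 0 && p[["A"]] == 0 && p[["b"]] == 0) next
      psd <- numeric(length(fgrid))
      psd[inband] <- model_curve(p, fgrid[inband]) / 0.5  # uV^2/Hz
      amp <- sqrt(2 * psd * df)
      phi <- stats::runif(length(fgrid), 0, 2 * pi)
      Z <- complex(modulus = 0.5 * n * amp, argument = phi)
      spec <- complex(real = numeric(n))
      spec[1 + k_idx] <- Z
      spec[1 + n - k_idx] <- Conj(Z)
      x[, j] <- Re(stats::fft(spec, inverse = TRUE)) / n
    }
    art_sec <- which(stats::runif(floor(duration_s)) < artifact_rate)
    for (s in art_sec) {
      len <- round(0.25 * fs)
      i0 <- (s - 1) * fs + sample.int(fs - len, 1)
      t <- seq_len(len) / fs
      burst <- 800 * exp(-((t - 0.125) / 0.06)^2) * cospi(8 * t)
      pol <- sample(c(-1, 1), nch, replace = TRUE)
      x[i0 + seq_len(len), ] <- x[i0 + seq_len(len), ] + outer(burst, pol)
    }
    structure(list(data = x, fs = fs, channels = rownames(truth$params),
                   duration_s = n / fs,
                   artifact_times = (art_sec - 1) + 0.5),
              class = "eeg_signal")
  })
}

#' Draw a subject's average spectra directly (no time series)
#'
#' Fast alternative to full time-series synthesis: the Welch-averaged
#' spectrum of `n_epochs` overlapping epochs is emulated by multiplying
#' the model curve by per-bin Gamma noise with shape equal to the
#' effective number of independent epochs (`n_epochs / 1.5` for 50%
#' overlap with rectangular windows), which matches the first two moments
#' of an averaged periodogram.
#'
#' @param truth a `subject_truth`.
#' @param n_epochs nominal number of 2-s epochs averaged.
#' @param seed integer seed.
#' @return A `subject_spectra` object (see [average_spectrum()]).
#' @export
synthesize_spectra <- function(truth, n_epochs = 334, seed = 1) {
  stopifnot(inherits(truth, "subject_truth"))
  freqs <- seq(0.5, 50, by = 0.5)
  mu <- t(apply(truth$params, 1, model_curve, freqs = freqs))
  n_eff <- max(n_epochs / 1.5, 1)
  noise <- with_seed(as.integer(seed), {
    matrix(stats::rgamma(length(mu), shape = n_eff, rate = n_eff),
           nrow(mu), ncol(mu))
  })
  structure(list(freq = freqs, power = mu * noise, n_epochs = n_epochs,
                 id = truth$id),
            class = "subject_spectra")
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_per_group` subjects for each requested group from its
#' ground-truth profile. In `"spectra"` mode (the default, fast) each
#' subject's Welch-averaged spectra are drawn directly via
#' [synthesize_spectra()]; in `"timeseries"` mode full multi-channel
#' recordings are synthesized and must be run through the spectra
#' pipeline. Groups are balanced by construction, emulating the
#' age-gender-balanced design of a matched clinical cohort. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config a [cohort_config()] list (or arguments overriding its
#'   defaults).
#' @param seed master seed for the cohort; per-subject seeds are derived
#'   from it.
#' @return A `cohort` object: list with `manifest` (data.frame: `id`,
#'   `group`, `seed`), `truths` (list of `subject_truth`), and either
#'   `spectra` (list of `subject_spectra`) or `signals` (list of
#'   `eeg_signal`), plus the `config` used.
#' @export
#' @examples
#' coh <- synthesize_cohort(cohort_config(groups = c("HC", "AD"),
#'                                        n_per_group = 3), seed = 1)
#' coh$manifest
synthesize_cohort <- function(config = cohort_config(), seed = 1) {
  cfg <- do.call(cohort_config, config[setdiff(names(config), "")])
  if (cfg$n_per_group < 2) stop("need at least 2 subjects per group")
  profiles <- lapply(cfg$groups, make_group_profile,
                     effect_scale = cfg$effect_scale,
                     base_config = cfg[c("base", "jitter", "kb_cor",
                                         "ch_cor")])
  names(profiles) <- cfg$groups

  manifest <- do.call(rbind, lapply(cfg$groups, function(g) {
    idx <- seq_len(cfg$n_per_group)
    data.frame(id = sprintf("%s_%03d", g, idx), group = g,
               seed = vapply(idx, function(i) {
                 derive_seed(seed, paste0("subject_", g, "_", i))
               }, integer(1)))
  }))
  rownames(manifest) <- NULL

  truths <- lapply(seq_len(nrow(manifest)), function(i) {
    sample_subject(profiles[[manifest$group[i]]], manifest$seed[i],
                   id = manifest$id[i])
  })
  names(truths) <- manifest$id

  out <- list(manifest = manifest, truths = truths, config = cfg)
  if (cfg$mode == "spectra") {
    out$spectra <- lapply(truths, function(tr) {
      synthesize_spectra(tr, n_epochs = cfg$n_epochs,
                         seed = derive_seed(tr$seed, "spectra"))
    })
  } else {
    out$signals <- lapply(truths, function(tr) {
      synthesize_timeseries(tr, duration_s = cfg$duration_s, fs = cfg$fs,
                            artifact_rate = cfg$artifact_rate,
                            seed = derive_seed(tr$seed, "signal"))
    })
  }
  class(out) <- "cohort"
  out
}

#' Cohort generator configuration
#'
#' Defaults emulate the matched clinical design the pipeline targets:
#' three balanced groups of 114 subjects, 22 channels at 256 Hz, 9-minute
#' resting recordings, and occasional high-amplitude artifacts.
#'
#' @param groups groups to generate, subset of `c("HC", "AD", "VaD")`.
#' @param n_per_group subjects per group (default 114).
#' @param effect_scale multiplier on group spectral differences
#'   (default 1; 0 gives exchangeable null groups).
#' @param mode `"spectra"` (draw averaged spectra directly) or
#'   `"timeseries"` (full synthesis).
#' @param n_epochs epochs emulated per subject in spectra mode.
#' @param duration_s,fs,artifact_rate time-series mode: recording length
#'   (default 540 s = 9 min), sampling rate, per-second artifact
#'   probability (default 0.02).
#' @param base,jitter,kb_cor,ch_cor overrides forwarded to
#'   [make_group_profile()].
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(groups = c("HC", "AD", "VaD"), n_per_group = 114,
                          effect_scale = 1, mode = c("spectra", "timeseries"),
                          n_epochs = 334, duration_s = 540, fs = 256,
                          artifact_rate = 0.02, base = NULL, jitter = NULL,
                          kb_cor = 0, ch_cor = 0.7) {
  structure(list(groups = match.arg(groups, several.ok = TRUE),
                 n_per_group = n_per_group, effect_scale = effect_scale,
                 mode = match.arg(mode), n_epochs = n_epochs,
                 duration_s = duration_s, fs = fs,
                 artifact_rate = artifact_rate, base = base,
                 jitter = jitter, kb_cor = kb_cor, ch_cor = ch_cor),
            class = c("cohort_config", "list"))
}
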