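#' Read (or build) a run configuration
#'
#' A run configuration holds everything a reproducible run needs: the
#' output directory, cohort parameters, preprocessing thresholds, fit and
#' screening options, CV settings, and the mandatory master seed. It can
#' be read from a YAML file or built programmatically; unspecified fields
#' take the documented defaults.
#'
#' @param path optional YAML file.
#' @param ... named overrides applied on top of the file/defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, ...) {
  cfg <- list(
    out_dir = "qeeglda_run",
    cohort = list(groups = c("HC", "AD", "VaD"), n_per_group = 114,
                  effect_scale = 1, mode = "spectra", n_epochs = 334,
                  duration_s = 540, fs = 256, artifact_rate = 0.02,
                  kb_cor = 0, ch_cor = 0.7),
    reject = list(amp_uv = 100, power_z = 4, sstd_z = 3),
    fit = list(log_space = FALSE, n_restarts = 4),
    screen = list(r_min = 0.15, alpha = 0.01, rule = "magnitude"),
    cv = list(k = 10, n_repeats = 20, boxcox = "fold",
              modes = c("complete", "reduced")),
    truncate_to = NULL,
    seed = NULL)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  if (is.null(cfg$seed)) stop("a master seed is mandatory in the run config")
  class(cfg) <- c("run_config", "list")
  cfg
}

config_hash <- function(cfg) {
  sprintf("%08x", fnv1a32(paste(deparse(unclass(cfg)), collapse = "")))
}

log_msg <- function(...) message("[qeeglda] ", sprintf(...))

write_signal_csv <- function(signal, path) {
  df <- as.data.frame(signal$data)
  names(df) <- signal$channels
  con <- file(path, "w")
  writeLines(sprintf("# fs_hz=%g n_channels=%d duration_s=%g",
                     signal$fs, ncol(signal$data), signal$duration_s), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

#' Read a signal CSV written by the simulate command
#'
#' Layout: one comment header line `# fs_hz=... n_channels=...
#' duration_s=...`, then a CSV of time x channels with channel-name
#' headers.
#'
#' @param path file path.
#' @return An `eeg_signal`.
#' @export
read_signal_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs_hz=([0-9.]+).*", "\\1", hdr))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(data = as.matrix(df), fs = fs, channels = names(df),
                 duration_s = nrow(df) / fs),
            class = "eeg_signal")
}

spectra_to_df <- function(sp) {
  data.frame(subject = sp$id,
             channel = rep(rownames(sp$power), times = length(sp$freq)),
             frequency_hz = rep(sp$freq, each = nrow(sp$power)),
             power_uv2 = as.vector(sp$power))
}

df_to_spectra <- function(df, id) {
  d <- df[df$subject == id, ]
  ch <- montage_channels()
  freq <- sort(unique(d$frequency_hz))
  pow <- matrix(NA_real_, length(ch), length(freq),
                dimnames = list(ch, NULL))
  for (cc in ch) {
    dc <- d[d$channel == cc, ]
    pow[cc, ] <- dc$power_uv2[order(dc$frequency_hz)]
  }
  structure(list(freq = freq, power = pow, n_epochs = NA_integer_,
                 id = id), class = "subject_spectra")
}

#' Simulate a cohort and write it to disk
#'
#' Generates the synthetic cohort of the run config and writes: the
#' cohort manifest (`manifest.csv`: subject id, group, seed), the
#' ground-truth parameters (`truth.csv`), and either per-subject spectra
#' (`spectra.csv`, long format) or per-subject signal CSVs under
#' `signals/`.
#'
#' @param config a `run_config`.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("simulate: config %s, seed %d", config_hash(config), config$seed)
  coh <- synthesize_cohort(config$cohort,
                           seed = derive_seed(config$seed, "cohort"))
  utils::write.csv(coh$manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  truth <- do.call(rbind, lapply(coh$truths, function(tr) {
    cbind(data.frame(subject = tr$id, group = tr$group,
                     channel = rownames(tr$params)),
          as.data.frame(tr$params))
  }))
  rownames(truth) <- NULL
  utils::write.csv(truth, file.path(config$out_dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(coh$spectra)) {
    sp <- do.call(rbind, lapply(coh$spectra, spectra_to_df))
    utils::write.csv(sp, file.path(config$out_dir, "spectra.csv"),
                     row.names = FALSE)
  } else {
    sig_dir <- file.path(config$out_dir, "signals")
    dir.create(sig_dir, showWarnings = FALSE)
    for (id in names(coh$signals)) {
      write_signal_csv(coh$signals[[id]],
                       file.path(sig_dir, paste0(id, ".csv")))
    }
  }
  log_msg("simulate: wrote %d subjects to %s", nrow(coh$manifest),
          config$out_dir)
  invisible(config$out_dir)
}

#' Run the analysis pipeline on a simulated (or provided) cohort
#'
#' Stages: spectra (skipped when the cohort was written in direct-spectra
#' mode), per-channel six-parameter fits (`fits.csv`), feature matrix
#' (`features.csv`), the four discrimination models under the configured
#' feature-set modes (`results.csv`, `results.json`, `roc.csv`), and a
#' screening report for the reduced mode (`screening.csv`). Each stage
#' failure aborts with a stage-labeled error. A run log with the config
#' hash and seed is written to `run_log.txt`.
#'
#' @param config a `run_config` whose `out_dir` contains a simulated
#'   cohort (`manifest.csv` plus `spectra.csv` or `signals/`).
#' @return The results table, invisibly.
#' @export
cmd_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  od <- config$out_dir
  stage <- function(name, expr) {
    log_msg("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  manifest <- stage("load", {
    mp <- file.path(od, "manifest.csv")
    if (!file.exists(mp)) stop("no cohort manifest at ", mp)
    utils::read.csv(mp)
  })

  spectra <- stage("spectra", {
    sp_path <- file.path(od, "spectra.csv")
    if (file.exists(sp_path)) {
      df <- utils::read.csv(sp_path)
      lapply(manifest$id, function(id) df_to_spectra(df, id))
    } else {
      lapply(manifest$id, function(id) {
        sig <- read_signal_csv(file.path(od, "signals", paste0(id, ".csv")))
        subject_spectra(sig, truncate_to = config$truncate_to, id = id,
                        amp_uv = config$reject$amp_uv,
                        power_z = config$reject$power_z,
                        sstd_z = config$reject$sstd_z)
      })
    }
  })

  fits <- stage("fit", {
    out <- lapply(spectra, function(sp) {
      fit_subject(sp, log_space = config$fit$log_space,
                  n_restarts = config$fit$n_restarts)
    })
    names(out) <- manifest$id
    flat <- do.call(rbind, Map(function(ft, id) {
      cbind(subject = id, ft)
    }, out, manifest$id))
    rownames(flat) <- NULL
    utils::write.csv(flat, file.path(od, "fits.csv"), row.names = FALSE)
    out
  })

  fm <- stage("features", {
    fm <- build_feature_matrix(fits, labels = manifest$group)
    feat <- cbind(data.frame(subject = manifest$id, label = manifest$group),
                  as.data.frame(fm$x))
    utils::write.csv(feat, file.path(od, "features.csv"), row.names = FALSE)
    fm
  })

  results <- stage("classify", {
    res <- summarize_models(fm, modes = config$cv$modes,
                            n_repeats = config$cv$n_repeats,
                            k = config$cv$k, boxcox = config$cv$boxcox,
                            r_min = config$screen$r_min,
                            alpha = config$screen$alpha,
                            rule = config$screen$rule,
                            seed = derive_seed(config$seed, "classify"))
    utils::write.csv(res$table, file.path(od, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(res$table, file.path(od, "results.json"),
                         digits = NA, dataframe = "rows")
    roc <- do.call(rbind, lapply(names(res$details), function(nm) {
      cbind(model_mode = nm, res$details[[nm]]$roc)
    }))
    utils::write.csv(roc, file.path(od, "roc.csv"), row.names = FALSE)
    if ("reduced" %in% config$cv$modes) {
      scr <- screen_features(boxcox_transform(fm$x)$x,
                             labels = manifest$group != "HC",
                             r_min = config$screen$r_min,
                             alpha = config$screen$alpha,
                             rule = config$screen$rule)
      utils::write.csv(scr, file.path(od, "screening.csv"),
                       row.names = FALSE)
    }
    res
  })

  writeLines(c(sprintf("qeeglda %s", as.character(utils::packageVersion("qeeglda"))),
               sprintf("config_hash %s", config_hash(config)),
               sprintf("seed %d", config$seed),
               sprintf("date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(od, "run_log.txt"))
  log_msg("pipeline complete: %s", od)
  invisible(results$table)
}

#' Simulate and analyze in one call
#'
#' @param config a `run_config`.
#' @return The results table, invisibly.
#' @export
cmd_all <- function(config) {
  cmd_simulate(config)
  cmd_pipeline(config)
}
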