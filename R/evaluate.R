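#' Random k-fold split
#'
#' Random partition of `n` samples into `k` folds of near-equal size
#' (differing by at most one). With `stratify_by`, the split balances
#' class counts across folds (each class is dealt as evenly as possible,
#' remainders going to the currently smallest folds), which prevents
#' single-class training folds at small sample sizes.
#'
#' @param n number of samples.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param stratify_by optional label vector of length `n`.
#' @return List of `k` integer index vectors (the test sets; they
#'   partition `1:n`).
#' @export
kfold_split <- function(n, k = 10, seed = 1, stratify_by = NULL) {
  if (k < 2 || n < k) stop("need n >= k >= 2")
  with_seed(as.integer(seed), {
    folds <- vector("list", k)
    if (is.null(stratify_by)) {
      perm <- sample.int(n)
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
      folds <- split(perm, rep(seq_len(k), times = sizes))
    } else {
      stopifnot(length(stratify_by) == n)
      counts <- integer(k)
      for (cls in sample(unique(as.character(stratify_by)))) {
        idx <- sample(which(stratify_by == cls))
        base <- length(idx) %/% k
        extra <- length(idx) %% k
        take <- rep(base, k)
        if (extra > 0) {
          take[order(counts, stats::runif(k))[seq_len(extra)]] <- base + 1
        }
        pos <- 1
        for (f in seq_len(k)) {
          if (take[f] > 0) {
            folds[[f]] <- c(folds[[f]], idx[pos:(pos + take[f] - 1)])
            pos <- pos + take[f]
          }
        }
        counts <- counts + take
      }
      folds <- lapply(folds, sort)
    }
    unname(folds)
  })
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the unique scores, from (0,0) to (1,1), with AUC
#' by the trapezoidal rule. Tied scores are grouped into single operating
#' points, so the trapezoid AUC equals the Mann-Whitney statistic
#' `U / (n0 n1)` computed with midranks.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param truth binary truth labels (positive class = second level /
#'   larger value).
#' @return A `roc_curve` object: data.frame of ordered `(fpr, tpr)`
#'   points with the `auc` as attribute.
#' @export
roc_and_auc <- function(scores, truth) {
  f <- as.factor(truth)
  if (nlevels(f) != 2) stop("truth must contain both classes")
  pos <- f == levels(f)[2]
  n1 <- sum(pos)
  n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group ties: cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  curve <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- trapz(curve$fpr, curve$tpr)
  attr(curve, "auc") <- auc
  class(curve) <- c("roc_curve", class(curve))
  curve
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x), "points, AUC =",
      format(attr(x, "auc"), digits = 4), "\n")
  invisible(x)
}

#' One pass of k-fold cross-validated RLDA
#'
#' For each fold: (optionally) fit the Box-Cox transform on the training
#' rows, (in `"reduced"` mode) screen columns on the training rows, fit
#' the regularized discriminant on the training rows, and score the
#' held-out fold. Nothing about the transform or the screen ever sees the
#' held-out rows. `"complete"` mode uses all 132 columns.
#'
#' @param fm a `feature_matrix` with labels, or a plain matrix.
#' @param labels binary labels (needed if `fm` is a matrix or has none).
#' @param mode `"complete"` or `"reduced"` feature set.
#' @param k folds (default 10).
#' @param seed fold-permutation seed.
#' @param boxcox `"fold"` (fit per training fold; default), `"global"`
#'   (fit once on all rows before splitting), or `"none"`.
#' @param r_min,alpha,rule screening settings, see [screen_features()].
#' @param stratified stratify folds by class (default `TRUE`).
#' @return List of per-fold results: `fold`, `train_idx`, `test_idx`,
#'   `selected` (column names), `acc`, `tpr`, `fpr`, `scores`
#'   (data.frame `score`, `truth`).
#' @export
run_cv <- function(fm, labels = NULL, mode = c("complete", "reduced"),
                   k = 10, seed = 1, boxcox = c("fold", "global", "none"),
                   r_min = 0.15, alpha = 0.01, rule = "magnitude",
                   stratified = TRUE) {
  mode <- match.arg(mode)
  boxcox <- match.arg(boxcox)
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  labels <- labels %||% (if (inherits(fm, "feature_matrix")) fm$labels)
  stopifnot(!is.null(labels), length(labels) == nrow(x))
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must be binary")

  if (boxcox == "global") {
    x <- boxcox_transform(x)$x
  }
  folds <- kfold_split(nrow(x), k = k, seed = seed,
                       stratify_by = if (stratified) y)
  pos_level <- levels(y)[2]
  lapply(seq_along(folds), function(fi) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_len(nrow(x)), test_idx)
    if (length(unique(y[train_idx])) < 2) {
      stop("training fold ", fi, " lost a class")
    }
    xf <- x
    if (boxcox == "fold") {
      xf <- boxcox_transform(x, train_rows = train_idx)$x
    }
    sel <- colnames(xf) %||% as.character(seq_len(ncol(xf)))
    if (mode == "reduced") {
      scr <- screen_features(xf, y, train_rows = train_idx, r_min = r_min,
                             alpha = alpha, rule = rule)
      sel <- scr$column[scr$keep]
      if (length(sel) == 0) {           # never run a zero-column model
        sel <- scr$column[which.max(abs(scr$r))]
      }
    }
    model <- fit_rlda(xf[train_idx, sel, drop = FALSE], y[train_idx])
    sc <- decision_scores(model, xf[test_idx, sel, drop = FALSE])
    truth_pos <- y[test_idx] == pos_level
    pred_pos <- sc > 0
    list(fold = fi, train_idx = train_idx, test_idx = test_idx,
         selected = sel,
         acc = mean(pred_pos == truth_pos),
         tpr = if (any(truth_pos)) mean(pred_pos[truth_pos]) else NA_real_,
         fpr = if (any(!truth_pos)) mean(pred_pos[!truth_pos]) else NA_real_,
         scores = data.frame(score = sc, truth = y[test_idx]))
  })
}

#' Repeated cross-validation with ROC/AUC summary
#'
#' Repeats the full k-fold pass `n_repeats` times (default 20), each with
#' a different random fold assignment, and summarizes: `cv_acc` per
#' repeat is the mean of the fold accuracies, `auc` per repeat comes from
#' that repeat's pooled held-out scores, and the summary reports the mean
#' and standard error (SEM) of both over the repeats, together with a
#' vertically averaged ROC curve (mean and SEM of TPR at a fixed
#' 101-point FPR grid).
#'
#' @param fm,labels,mode,... as in [run_cv()].
#' @param n_repeats number of repeated CV passes (default 20).
#' @param seed master seed; per-repeat fold seeds are derived from it.
#' @param repeat_seeds optional explicit per-repeat seeds overriding the
#'   derivation.
#' @return A `cv_summary` list: `per_repeat` (data.frame `repeat_`,
#'   `cv_acc`, `auc`), `mean_cv_acc`, `sem_cv_acc`, `mean_auc`,
#'   `sem_auc`, `roc` (data.frame `fpr`, `mean_tpr`, `sem_tpr`),
#'   `fold_operating_points` (per-fold mean TPR/FPR across repeats).
#' @export
repeat_cv <- function(fm, labels = NULL, mode = "complete", n_repeats = 20,
                      seed = 1, repeat_seeds = NULL, ...) {
  seeds <- repeat_seeds %||% vapply(seq_len(n_repeats), function(i) {
    derive_seed(seed, paste0("cv_repeat_", i))
  }, integer(1))
  stopifnot(length(seeds) == n_repeats)
  grid <- seq(0, 1, by = 0.01)
  per <- vector("list", n_repeats)
  tpr_mat <- matrix(0, n_repeats, length(grid))
  op <- matrix(0, n_repeats, 2)
  for (i in seq_len(n_repeats)) {
    res <- run_cv(fm, labels, mode = mode, seed = seeds[i], ...)
    sc <- do.call(rbind, lapply(res, `[[`, "scores"))
    roc <- roc_and_auc(sc$score, sc$truth)
    per[[i]] <- data.frame(repeat_ = i,
                           cv_acc = mean(vapply(res, `[[`, 0, "acc")),
                           auc = attr(roc, "auc"))
    tpr_mat[i, ] <- stats::approx(roc$fpr, roc$tpr, xout = grid,
                                  ties = max, rule = 2)$y
    op[i, ] <- c(mean(vapply(res, `[[`, 0, "fpr"), na.rm = TRUE),
                 mean(vapply(res, `[[`, 0, "tpr"), na.rm = TRUE))
  }
  per <- do.call(rbind, per)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  structure(list(
    per_repeat = per,
    mean_cv_acc = mean(per$cv_acc), sem_cv_acc = sem(per$cv_acc),
    mean_auc = mean(per$auc), sem_auc = sem(per$auc),
    roc = data.frame(fpr = grid, mean_tpr = colMeans(tpr_mat),
                     sem_tpr = apply(tpr_mat, 2, sem)),
    fold_operating_points = data.frame(mean_fpr = mean(op[, 1]),
                                       mean_tpr = mean(op[, 2]))),
    class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("repeated CV: cv-ACC %.3f (SEM %.3f), AUC %.3f (SEM %.3f)\n",
              x$mean_cv_acc, x$sem_cv_acc, x$mean_auc, x$sem_auc))
  invisible(x)
}

#' The four binary contrasts of a three-group cohort
#'
#' @return data.frame with `model`, `contrast`, `neg` (negative-class
#'   groups), `pos` (positive-class groups). The patient group is the
#'   positive class in Models 1, 2 and 4; VaD is positive in Model 3.
#' @export
model_contrasts <- function() {
  data.frame(
    model = 1:4,
    contrast = c("HC vs AD", "HC vs VaD", "AD vs VaD", "HC vs AD&VaD"),
    neg = c("HC", "HC", "AD", "HC"),
    pos = c("AD", "VaD", "VaD", "AD|VaD"))
}

#' Run all four discrimination models on a fitted cohort
#'
#' Builds the four binary contrasts from the per-group fitted features —
#' HC vs AD (Model 1), HC vs VaD (Model 2), AD vs VaD (Model 3), and HC
#' vs the pooled dementia groups (Model 4) — and evaluates each with
#' repeated cross-validation under the requested feature-set modes.
#'
#' @param fm a `feature_matrix` whose `labels` are the group names
#'   (`HC`/`AD`/`VaD`).
#' @param modes feature-set modes to run (default both).
#' @param n_repeats,seed,... forwarded to [repeat_cv()].
#' @return A `model_summary` list: `table` (data.frame: `model`,
#'   `contrast`, `feature_set`, `mean_cv_acc`, `sem_cv_acc`, `mean_auc`,
#'   `sem_auc`) and `details` (named list of `cv_summary` objects keyed
#'   `model<i>_<mode>`).
#' @export
summarize_models <- function(fm, modes = c("complete", "reduced"),
                             n_repeats = 20, seed = 1, ...) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  groups <- as.character(fm$labels)
  missing <- setdiff(c("HC", "AD", "VaD"), unique(groups))
  if (length(missing)) stop("missing group(s): ", paste(missing, collapse = ", "))
  contrasts <- model_contrasts()
  details <- list()
  rows <- list()
  for (mi in seq_len(nrow(contrasts))) {
    neg <- strsplit(contrasts$neg[mi], "|", fixed = TRUE)[[1]]
    pos <- strsplit(contrasts$pos[mi], "|", fixed = TRUE)[[1]]
    sel <- groups %in% c(neg, pos)
    sub <- fm
    sub$x <- fm$x[sel, , drop = FALSE]
    sub$labels <- factor(ifelse(groups[sel] %in% pos, "pos", "neg"),
                         levels = c("neg", "pos"))
    for (mode in modes) {
      res <- repeat_cv(sub, mode = mode, n_repeats = n_repeats,
                       seed = derive_seed(seed, paste0("model", mi, mode)),
                       ...)
      details[[paste0("model", mi, "_", mode)]] <- res
      rows[[length(rows) + 1]] <- data.frame(
        model = contrasts$model[mi], contrast = contrasts$contrast[mi],
        feature_set = mode, n_neg = sum(sub$labels == "neg"),
        n_pos = sum(sub$labels == "pos"), mean_cv_acc = res$mean_cv_acc,
        sem_cv_acc = res$sem_cv_acc, mean_auc = res$mean_auc,
        sem_auc = res$sem_auc)
    }
  }
  structure(list(table = do.call(rbind, rows), details = details),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  print(x$table, digits = 3)
  invisible(x)
}
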