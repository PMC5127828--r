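#' Assemble the subjects-by-parameters predictor matrix
#'
#' Stacks per-subject channel fits into the predictor matrix for
#' discrimination: one row per subject, 6 x 22 = 132 columns in
#' channel-major, parameter-minor order (`S, k, A, c, w, b` for channel 1,
#' then channel 2, ...). Column names are `<channel>_<parameter>`.
#'
#' @param fits named list (one entry per subject, in cohort-manifest
#'   order) of per-channel fit tables as returned by [fit_subject()].
#' @param labels optional vector of group labels, same length/order.
#' @return A `feature_matrix` object: list with `x` (subjects x 132
#'   matrix), `labels`, `meta` (data.frame: `column`, `channel`,
#'   `parameter`), `transform` (`NULL` until [boxcox_transform()]).
#' @export
build_feature_matrix <- function(fits, labels = NULL) {
  ch <- montage_channels()
  pn <- param_names()
  cols <- as.vector(t(outer(ch, pn, paste, sep = "_")))
  rows <- lapply(fits, function(ft) {
    if (!all(ch %in% ft$channel)) {
      stop("missing channel fits for a subject: ",
           paste(setdiff(ch, ft$channel), collapse = ", "))
    }
    ft <- ft[match(ch, ft$channel), ]
    as.vector(t(as.matrix(ft[, pn])))
  })
  x <- do.call(rbind, rows)
  colnames(x) <- cols
  rownames(x) <- names(fits)
  if (!is.null(labels)) stopifnot(length(labels) == nrow(x))
  structure(list(
    x = x, labels = labels,
    meta = data.frame(column = cols,
                      channel = rep(ch, each = length(pn)),
                      parameter = rep(pn, times = length(ch))),
    transform = NULL), class = "feature_matrix")
}

# profile log-likelihood of the Box-Cox parameter for one positive sample
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-9) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * sum(log(x))
}

boxcox_apply <- function(x, lambda, shift, floor = 0) {
  # rows outside the training range can fall at or below zero after the
  # training-derived shift; clamp to the floor so the power is defined
  x <- pmax(x + shift, floor)
  if (abs(lambda) < 1e-9) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox normalization of the predictor matrix
#'
#' Per-column power transform toward normality. For each column, a shift
#' is chosen so that all training values are strictly positive (zero when
#' they already are), the Box-Cox exponent `lambda` is estimated by
#' maximum likelihood on the training rows only, and the same
#' `(lambda, shift)` is applied to every row. `lambda = 0` is the natural
#' log. Columns with zero training variance are passed through unchanged
#' and flagged.
#'
#' @param fm a `feature_matrix` (or plain numeric matrix).
#' @param train_rows integer indices of the rows the transform may learn
#'   from (default all rows).
#' @param lambda_grid search interval for `lambda`.
#' @param forced_lambda optional fixed `lambda` applied to every column
#'   (skips estimation).
#' @return The `feature_matrix` with transformed `x` and a `transform`
#'   record (data.frame: `column`, `lambda`, `shift`, `floor`, `flagged`),
#'   where `floor` is the positive clamp (half the smallest shifted
#'   training value) applied to rows that fall below the training range.
#'   For a plain matrix input, a list `(x, record)`.
#' @export
boxcox_transform <- function(fm, train_rows = NULL,
                             lambda_grid = c(-3, 3), forced_lambda = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  train_rows <- train_rows %||% seq_len(nrow(x))
  p <- ncol(x)
  lambda <- numeric(p)
  shift <- numeric(p)
  floor_ <- numeric(p)
  flagged <- logical(p)
  out <- x
  for (j in seq_len(p)) {
    tr <- x[train_rows, j]
    if (any(!is.finite(tr))) stop("non-finite training values in column ", j)
    if (stats::var(tr) == 0) {
      flagged[j] <- TRUE
      lambda[j] <- 1
      next
    }
    if (min(tr) <= 0) shift[j] <- 1e-3 * stats::sd(tr) - min(tr)
    floor_[j] <- 0.5 * min(tr + shift[j])
    if (is.null(forced_lambda)) {
      opt <- stats::optimize(function(l) boxcox_loglik(tr + shift[j], l),
                             interval = lambda_grid, maximum = TRUE)
      lambda[j] <- opt$maximum
    } else {
      lambda[j] <- forced_lambda
    }
    out[, j] <- boxcox_apply(x[, j], lambda[j], shift[j], floor_[j])
  }
  record <- data.frame(column = colnames(x) %||% as.character(seq_len(p)),
                       lambda = lambda, shift = shift, floor = floor_,
                       flagged = flagged)
  if (inherits(fm, "feature_matrix")) {
    fm$x <- out
    fm$transform <- record
    fm
  } else {
    list(x = out, record = record)
  }
}

#' Correlation screening of predictors against class labels
#'
#' Computes, on the training rows only, the Pearson (point-biserial)
#' correlation `r` of each column with the binary labels and its
#' two-tailed p-value from `t = r * sqrt((n-2) / (1-r^2))` on `n - 2`
#' degrees of freedom. The default rule rejects columns with
#' `|r| < r_min`; the alternative `"conjunction"` rule additionally
#' requires `p <= alpha` for a column to be kept (so columns are rejected
#' for either a small or a non-significant correlation).
#'
#' @param fm a `feature_matrix` or numeric matrix.
#' @param labels binary labels (0/1 or a 2-level factor).
#' @param train_rows rows visible to the screen (default all).
#' @param r_min magnitude threshold (default 0.15).
#' @param alpha significance threshold (default 0.01).
#' @param rule `"magnitude"` (default) or `"conjunction"`.
#' @return A `screen_result` data.frame: `column`, `r`, `p`, `keep`, with
#'   the thresholds as attributes.
#' @export
screen_features <- function(fm, labels, train_rows = NULL, r_min = 0.15,
                            alpha = 0.01, rule = c("magnitude", "conjunction")) {
  rule <- match.arg(rule)
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  train_rows <- train_rows %||% seq_len(nrow(x))
  y <- as.numeric(as.factor(labels))[train_rows] - 1
  if (length(unique(y)) < 2) stop("training rows contain a single class")
  xt <- x[train_rows, , drop = FALSE]
  n <- length(y)
  r <- suppressWarnings(as.vector(stats::cor(xt, y)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- abs(r) >= r_min
  if (rule == "conjunction") keep <- keep & p <= alpha
  keep[is.na(r)] <- FALSE
  out <- data.frame(column = colnames(x) %||% as.character(seq_len(ncol(x))),
                    r = r, p = p, keep = keep)
  attr(out, "r_min") <- r_min
  attr(out, "alpha") <- alpha
  attr(out, "rule") <- rule
  class(out) <- c("screen_result", class(out))
  out
}
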