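# internal helpers: seed fan-out, local RNG scope, small hash

# FNV-1a 32-bit hash of a string, reduced below 2^31 so it is a valid R seed
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # modular multiply in split halves to stay within double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 2^32
  }
  as.integer(h %% .Machine$integer.max)
}

#' Derive a child seed from a master seed and a stage label
#'
#' One master seed reproduces a whole run: each pipeline stage (and each
#' subject, repeat, fold permutation) draws its own seed deterministically
#' from the master seed and a short text label, so stages can be re-run in
#' isolation without disturbing each other's random streams.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"subject_17"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  as.integer((as.numeric(master) %% 65536 * 65537 + fnv1a32(label)) %%
               .Machine$integer.max)
}

# evaluate `expr` under `seed` without touching the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
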