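#' @keywords internal
"_PACKAGE"

# Deterministic per-entity substream seed derived from one global seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Interquartile range with linear-interpolation (type 7) quantiles.
iqr_type7 <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  q[2] - q[1]
}

mx_log <- function(fmt, ...) {
  message(sprintf(paste0("[mxprox] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
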