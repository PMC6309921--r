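# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

opposite_strand <- function(s) chartr("+-", "-+", s)

# Smallest positive value divided by two: the pseudo-value used wherever a
# nonpositive quantity must be imputed before taking a log or a ratio.
half_min_positive <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0L) return(NA_real_)
  min(pos) / 2
}
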