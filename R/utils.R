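`%||%` <- function(a, b) if (is.null(a)) b else a

# Clip to [lo, hi]; one warning summarising how many values fell outside.
clip_warn <- function(x, lo, hi, what = "value") {
  out_n <- sum(x < lo | x > hi, na.rm = TRUE)
  if (out_n > 0L) {
    warning(sprintf("%d %s value(s) outside [%g, %g] clipped", out_n, what, lo, hi),
            call. = FALSE)
  }
  pmin(pmax(x, lo), hi)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Formats doubles so that read-back reproduces the exact binary value.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

# Evaluate expr under a fixed seed, restoring the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}
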