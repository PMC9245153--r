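# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# clamp to [-1, 1] preserving names/dims (pmin/pmax would take the
# attributes of their first argument)
clamp1 <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

# z-score a numeric vector (population of the sample, sd with n-1)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant column")
  (x - mean(x)) / s
}
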