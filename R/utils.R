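# Run `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed uses (and advances) the current stream.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# clamp to the unit interval
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# assay censoring: values below the detection threshold report as 0
censor_below <- function(x, detection_threshold) {
  x[x < detection_threshold] <- 0
  x
}

fmt_pct <- function(x, digits = 1) sprintf("%.*f%%", digits, 100 * x)
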