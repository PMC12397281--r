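#' @importFrom stats prcomp rnbinom rnorm rlnorm runif p.adjust ks.test dist var sd quantile
#' @importFrom utils read.delim write.table head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library functions do not perturb user scripts.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, field, min = -Inf, max = Inf,
                              strict_min = FALSE, strict_max = FALSE,
                              integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", field)
  if (integer && x != round(x))
    stopf("'%s' must be an integer", field)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %s is outside its allowed range", field, format(x))
  invisible(x)
}
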