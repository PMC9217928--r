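# Internal helpers shared across modules.

# Stop with a consistent message naming the offending argument/field.
bad_field <- function(field, why) {
  stop(sprintf("invalid `%s`: %s", field, why), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    bad_field(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    bad_field(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && if (strict) all(x > 0) else all(x >= 0)
  if (!ok) bad_field(field, if (strict) "must be finite and > 0" else "must be finite and >= 0")
  invisible(x)
}

#' @noRd
# Derive a reproducible substream seed from a global seed and a stream name so
# that, e.g., enlarging the gene panel never perturbs the cohort stream.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((seed %% 2147483647 + h * 10007) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Lognormal (meanlog, sdlog) matching a given arithmetic mean and SD.
lnorm_params <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(mean) - sdlog^2 / 2
  c(meanlog = meanlog, sdlog = sdlog)
}

geomean <- function(x) exp(mean(log(x)))
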