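# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit child seed, kept below 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483629)
}

# sample() treats a length-one numeric vector as 1:x; this does not.
resample <- function(x, size = 1L) x[sample.int(length(x), size)]

# Cheap provenance hash (polynomial rolling hash of the deparsed object).
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_cogload <- function(kind, msg) {
  stop(sprintf("[%s] %s", kind, msg), call. = FALSE)
}

# Indices of timestamps falling in the half-open interval [start, end).
in_interval <- function(ts, start, end) which(ts >= start & ts < end)
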