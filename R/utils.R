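# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed fans out to per-unit,
# per-stage streams so any single well is reproducible in isolation.
# All arithmetic stays below 2^53 (exact in doubles) and the result below 2^31.
derive_seed <- function(master, index = 0L, stage = 0L) {
  m <- 2147483629
  (((master %% m) * 1009 + index * 101 + stage * 7919) %% m) + 1
}

# Trapezoid integral of y over x (diagnostic/empirical AUC).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# Welch t-test p-value that degrades gracefully when one or both groups are
# (numerically) constant, where stats::t.test() errors out.
welch_p <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(NA_real_)
  }
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  scale <- max(1e-10, abs(mean(x)), abs(mean(y)))
  if (se < 1e-10 * scale) {
    d <- mean(x) - mean(y)
    tol <- 1e-10 * scale
    p <- switch(alternative,
      two.sided = if (abs(d) > tol) 0 else 1,
      greater   = if (d > tol) 0 else 1,
      less      = if (d < -tol) 0 else 1
    )
    return(p)
  }
  t.test(x, y, alternative = alternative)$p.value
}

# MD5 of a deterministically serialized R object (used for config/run hashes).
object_hash <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
  }
  dput(x, file = f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
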