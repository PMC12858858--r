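# Internal helpers: seed derivation, numerics.

# Deterministic child seed from a root seed and a stream name, so that the
# split / init / shuffle / sampling streams are independent but reproducible
# from one root. Kept below 2^31 - 1 (R integer range).
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483629
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m + 1)
}

# Numerically stable softplus and its derivative (the logistic function).
softplus <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) {
  z[z < 0] <- 0
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column variances without forming an apply() loop per gene.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

# paste0(prefix, seq_len(0)) yields "prefix", not character(0); guard that
default_ids <- function(n, prefix) {
  if (n == 0L) character(0) else paste0(prefix, seq_len(n))
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
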