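# small shared helpers; no exports except the logit pair documented in
# methylation.R

colMedians <- function(x) apply(x, 2, stats::median)
rowMedians <- function(x) apply(x, 1, stats::median)

# log2 counts-per-million; prior damps low-count variance (limma-style).
# All-zero libraries map to log2(prior), not NaN.
log2cpm <- function(counts, prior = 1) {
  libsize <- pmax(colSums(counts), 1)
  log2(sweep(counts, 2, libsize, "/") * 1e6 + prior)
}

# child seed derivation: keeps every derived seed a valid 32-bit integer
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
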