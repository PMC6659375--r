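# Internal numerical and bookkeeping helpers.

# log(sum(exp(x))) with max-shift; empty or all -Inf input gives -Inf.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Watson-Crick complement of allele strings.
complement_alleles <- function(x) chartr("ACGT", "TGCA", toupper(x))

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & complement_alleles(a1) == a2
}

# Deterministic sub-stream seeds derived from one master seed, so that
# cohorts drawn under different masters never share a stream.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate expr with a locally-seeded RNG, leaving the caller's stream alone.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_epimr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "epimr_error")))
}
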