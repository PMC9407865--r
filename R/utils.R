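# Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` is its own complement.
#'
#' @param x Character vector of DNA sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# round-half-up: report dialect for tables (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derived per-stage seed; stays well below 2^31 so set.seed() is safe.
substream_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 104729L
  (abs(as.integer(seed)) %% 1000003L) * 2011L + h
}

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitution matrix for ACGTN alignments: N never rewards a match
dna_submat <- function(match = 2, mismatch = -3) {
  b <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

fmt_num <- function(x, digits) formatC(round_half_up(x, digits), format = "f", digits = digits)
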