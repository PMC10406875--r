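#' @importFrom data.table data.table as.data.table setkey setorder := .N %chin% chmatch dcast rbindlist
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()],
#' used throughout the package where sequences travel as plain strings.
#'
#' @param x Character vector of A/C/G/T(/N) sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement. Used by the assembly graph, where the
#' two strands must merge; the screening module deliberately does NOT
#' canonicalise (its AG-prefix filter is orientation-specific).
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Round half away from zero to `digits` decimals (so 96.875 -> 96.88),
# unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Uniform i.i.d. random DNA string(s); uses the current RNG stream.
random_dna <- function(n_bases, n_seqs = 1L) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
  }, character(1))
}

# Deterministic per-stage seed fan-out from one global seed: a small
# polynomial hash of the stage name mixed with the seed, kept inside the
# 32-bit integer range that set.seed() accepts.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(seed) * 747796405 + h * 2891336453) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sexmark <- function(...) stop(..., call. = FALSE)

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_sexmark(sprintf("'%s' must be a single probability in [0, 1]", name))
  x
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_sexmark(sprintf("'%s' must be a single integer >= %s", name, min))
  as.integer(x)
}
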