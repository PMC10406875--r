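# Independent brute-force oracles and small fixture builders shared by the
# suite. Oracles are deliberately written as plain position-by-position
# scans, independent of the package's indexed implementations.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Oracle: all prefixed k-mers of one sequence by scanning every start.
naive_prefixed_kmers <- function(seq, k, prefix) {
  n <- nchar(seq)
  out <- character(0)
  if (n < k) return(out)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (startsWith(w, prefix) && !grepl("N", w, fixed = TRUE))
      out <- c(out, w)
  }
  out
}

# Oracle: pooled per-k-mer counts over two read sets.
naive_pool_counts <- function(male_seqs, female_seqs, k, prefix) {
  cnt <- function(seqs) {
    km <- unlist(lapply(seqs, naive_prefixed_kmers, k = k, prefix = prefix))
    table(km)
  }
  m <- cnt(male_seqs); f <- cnt(female_seqs)
  keys <- sort(union(names(m), names(f)))
  data.frame(kmer = keys,
             male_count = as.integer(ifelse(keys %in% names(m),
                                            m[keys], 0)),
             female_count = as.integer(ifelse(keys %in% names(f),
                                              f[keys], 0)))
}

# Oracle: exact substring hits of one read (both strands) on one scaffold.
naive_map_one <- function(read, scaffold) {
  hits <- data.frame(start = integer(0), strand = character(0))
  for (q in list(c(read, "+"), c(rc_chr(read), "-"))) {
    n <- nchar(scaffold); m <- nchar(q[1])
    if (m <= n) for (i in seq_len(n - m + 1)) {
      if (substr(scaffold, i, i + m - 1) == q[1])
        hits <- rbind(hits, data.frame(start = i, strand = q[2]))
    }
  }
  hits
}

# Oracle: primer sites with mismatch budget and exact 3'-terminal match.
naive_primer_sites <- function(template, primer, max_mm) {
  out <- data.frame(start = integer(0), strand = character(0))
  tc <- strsplit(template, "")[[1]]
  scan <- function(pat, strand, anchor_pos) {
    pc <- strsplit(pat, "")[[1]]
    m <- length(pc); n <- length(tc)
    if (m > n) return()
    for (i in seq_len(n - m + 1)) {
      w <- tc[i:(i + m - 1)]
      if (sum(w != pc) <= max_mm && w[anchor_pos] == pc[anchor_pos])
        out <<- rbind(out, data.frame(start = i, strand = strand))
    }
  }
  scan(primer, "+", nchar(primer))
  scan(rc_chr(primer), "-", 1L)
  out
}

# Quick read_pairs from parallel sequence vectors; constant Q37 qualities.
make_rp <- function(seq1, seq2 = seq1, qual1 = NULL, qual2 = NULL) {
  q1 <- qual1 %||% strrep("F", nchar(seq1))
  q2 <- qual2 %||% strrep("F", nchar(seq2))
  read_pairs(sprintf("p%03d", seq_along(seq1)), seq1, q1, seq2, q2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reads tiling `seq` at every `step` offsets (error-free, both mates equal
# windows) — deterministic high coverage for assembly tests.
tiling_reads <- function(seq, read_len = 100, step = 3) {
  n <- nchar(seq)
  starts <- seq(1, n - read_len + 1, by = step)
  windows <- substring(seq, starts, starts + read_len - 1)
  make_rp(windows)
}

# Fraction of `target` bases covered by exact hits of `seqs` (either
# strand), by brute substring location.
covered_fraction <- function(target, seqs) {
  cov <- logical(nchar(target))
  t_dna <- Biostrings::DNAString(target)
  for (s in as.character(seqs)) for (q in c(s, rc_chr(s))) {
    m <- Biostrings::matchPattern(q, t_dna)
    if (length(m)) for (i in seq_along(m)) {
      cov[IRanges::start(m)[i]:IRanges::end(m)[i]] <- TRUE
    }
  }
  mean(cov)
}

# Study-condition pipeline config at reduced genome scale for unit tests.
small_run_config <- function(seed, autosome = 20000, x = 5000, y = 3000,
                             coverage = 30) {
  run_config(
    genome = genome_model(autosome, x, y, seed = seed),
    reads = read_sim_config(coverage = coverage, seed = seed),
    seed = seed
  )
}
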