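#' K-mer screening parameters
#'
#' Settings for the pooled sex-specific k-mer screen: only k-mers of length
#' `k` that start with `prefix` are counted (the prefix restriction keeps
#' roughly 1/16 of all k-mers for a dinucleotide, cutting memory and time
#' without affecting which loci can be detected), and only k-mers whose
#' total (male + female) count lies in `[min_total, max_total]` are
#' retained — the lower bound removes singleton sequencing-error k-mers,
#' the upper bound removes high-copy repeats.
#'
#' @param k K-mer length in bases (default 35).
#' @param prefix Required leading oligonucleotide (default `"AG"`; `""`
#'   disables the restriction).
#' @param min_total,max_total Inclusive bounds on male + female count
#'   (defaults 2 and 200).
#' @return An object of class `kmer_screen_params`.
#' @export
kmer_screen_params <- function(k = 35, prefix = "AG", min_total = 2,
                               max_total = 200) {
  k <- check_count(k, "k", min = 1)
  stopifnot(is.character(prefix), length(prefix) == 1L)
  prefix <- toupper(prefix)
  if (nchar(prefix) >= k) stop_sexmark("k must exceed the prefix length")
  min_total <- check_count(min_total, "min_total", min = 1)
  max_total <- check_count(max_total, "max_total", min = 1)
  if (min_total > max_total) stop_sexmark("min_total must not exceed max_total")
  structure(list(k = k, prefix = prefix, min_total = min_total,
                 max_total = max_total),
            class = "kmer_screen_params")
}

#' Quality-trimming parameters
#'
#' 3'-end sliding-window trimming: scanning 5'→3', the read is cut at the
#' first window whose mean Phred quality drops below `min_mean_quality`,
#' then extended base-by-base while individual base qualities still pass.
#' A pair is dropped when either trimmed mate is shorter than `min_length`.
#'
#' @param window Window width in bases (default 4).
#' @param min_mean_quality Minimum window mean Phred score (default 20).
#' @param min_length Minimum surviving mate length (default 50).
#' @return An object of class `trim_params`.
#' @export
trim_params <- function(window = 4, min_mean_quality = 20, min_length = 50) {
  structure(list(window = check_count(window, "window", min = 1),
                 min_mean_quality = min_mean_quality,
                 min_length = check_count(min_length, "min_length", min = 1)),
            class = "trim_params")
}

# Trimmed length of one read given integer Phred scores.
trimmed_length <- function(q, w, minq) {
  n <- length(q)
  if (n < w) return(if (mean(q) >= minq) n else 0L)
  cs <- cumsum(as.numeric(q))
  ms <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w  # mean of window starting i
  fail <- which(ms < minq)
  if (!length(fail)) return(n)
  end <- fail[1] - 1L
  while (end < n && q[end + 1L] >= minq) end <- end + 1L
  end
}

#' Quality-trim a paired read set
#'
#' Applies 3' sliding-window trimming (see [trim_params]) to both mates;
#' pairs where either trimmed mate falls below `min_length` are dropped
#' whole. Identical quality strings are trimmed once, so uniform-quality
#' simulated data costs almost nothing.
#'
#' @param rp A [read_pairs] object.
#' @param params A [trim_params].
#' @return A trimmed [read_pairs] object.
#' @export
quality_trim <- function(rp, params = trim_params()) {
  stopifnot(inherits(rp, "read_pairs"), inherits(params, "trim_params"))
  if (params$min_length < 35)
    warning("min_length below typical screening k-mer length (35)")
  if (length(rp) == 0L) return(rp)
  len_for_qual <- function(quals) {
    uq <- unique(quals)
    ul <- vapply(uq, function(q) {
      as.integer(trimmed_length(utf8ToInt(q) - 33L, params$window,
                                params$min_mean_quality))
    }, integer(1))
    ul[match(quals, uq)]
  }
  l1 <- len_for_qual(rp$qual1)
  l2 <- len_for_qual(rp$qual2)
  keep <- l1 >= params$min_length & l2 >= params$min_length
  out <- rp[keep]
  out$seq1 <- substr(out$seq1, 1L, l1[keep])
  out$qual1 <- substr(out$qual1, 1L, l1[keep])
  out$seq2 <- substr(out$seq2, 1L, l2[keep])
  out$qual2 <- substr(out$qual2, 1L, l2[keep])
  out
}

# Extract prefixed k-mers from a character vector of sequences, pooled.
# Sequences are joined with a single 'N' separator; any window containing
# an N (including windows spanning the separator) is discarded, so the
# result equals the union of per-sequence scans, in order.
extract_kmers_pooled <- function(seqs, params) {
  seqs <- toupper(seqs[nchar(seqs) >= params$k])
  if (!length(seqs)) return(character(0))
  big <- Biostrings::DNAString(paste(seqs, collapse = "N"))
  k <- params$k
  if (nchar(params$prefix) > 0) {
    starts <- IRanges::start(
      Biostrings::matchPattern(params$prefix, big))
  } else {
    starts <- seq_len(max(0L, length(big)))
  }
  starts <- starts[starts + k - 1L <= length(big)]
  if (!length(starts)) return(character(0))
  kmers <- as.character(Biostrings::extractAt(
    big, IRanges::IRanges(starts, width = k)))
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

#' Extract prefix-restricted k-mers from one sequence
#'
#' Returns every length-`k` window that starts with the required prefix and
#' contains no N, in left-to-right order of start position. Overlapping
#' occurrences are all reported.
#'
#' @param sequence A single character string over A/C/G/T/N.
#' @param params A [kmer_screen_params].
#' @return Character vector of k-mers (possibly empty).
#' @export
extract_prefixed_kmers <- function(sequence, params = kmer_screen_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(params, "kmer_screen_params"))
  extract_kmers_pooled(sequence, params)
}

#' Count prefixed k-mers per pool
#'
#' Counts every prefixed k-mer occurrence across all mates of the male and
#' female pools, as sequenced — there is deliberately no reverse-complement
#' canonicalisation, because the prefix restriction is orientation-specific
#' and both strands are sampled by sequencing anyway. Occurrences within a
#' single read each count.
#'
#' @param male_reads,female_reads [read_pairs] objects (quality-trimmed).
#' @param params A [kmer_screen_params].
#' @return A `data.table` with columns `kmer`, `male_count`, `female_count`
#'   (unfiltered; one row per distinct k-mer observed in either pool),
#'   sorted by `kmer`.
#' @export
count_pool_kmers <- function(male_reads, female_reads,
                             params = kmer_screen_params()) {
  km <- extract_kmers_pooled(all_mates(male_reads), params)
  kf <- extract_kmers_pooled(all_mates(female_reads), params)
  tab_m <- data.table(kmer = km)[, .(male_count = .N), by = kmer]
  tab_f <- data.table(kmer = kf)[, .(female_count = .N), by = kmer]
  tab <- merge(tab_m, tab_f, by = "kmer", all = TRUE)
  for (col in c("male_count", "female_count"))
    data.table::set(tab, which(is.na(tab[[col]])), col, 0L)
  setorder(tab, kmer)
  tab[]
}

#' Filter a k-mer table and select pure male-specific k-mers
#'
#' Retains k-mers whose total (male + female) count lies within
#' `[min_total, max_total]`, then defines the MSK set as the retained
#' k-mers with a female count of exactly zero.
#'
#' @param table A k-mer count table from [count_pool_kmers()].
#' @param params A [kmer_screen_params].
#' @return A list with `table` (the filtered `data.table`) and `msks`
#'   (character vector of pure male-specific k-mers).
#' @export
filter_and_select_msks <- function(table, params = kmer_screen_params()) {
  total <- table$male_count + table$female_count
  keep <- total >= params$min_total & total <= params$max_total
  filtered <- table[keep]
  list(table = filtered, msks = filtered$kmer[filtered$female_count == 0L])
}

#' Extract candidate (male-biased) read pairs
#'
#' A pair is retained iff at least one mate contains at least one MSK as a
#' literal substring (same orientation as sequenced, matching how the MSKs
#' were counted). Retained pairs keep their ids and both mates.
#'
#' @param rp A [read_pairs] object (the quality-trimmed male pool).
#' @param msks Character vector of MSKs (all the same length).
#' @param params A [kmer_screen_params] (unused beyond validation; kept so
#'   call sites document which screen produced `msks`).
#' @return The retained subset of `rp`.
#' @export
extract_candidate_read_pairs <- function(rp, msks,
                                         params = kmer_screen_params()) {
  stopifnot(inherits(rp, "read_pairs"))
  if (length(msks) == 0L || length(rp) == 0L) return(rp[integer(0)])
  pd <- Biostrings::PDict(msks)
  has_hit <- function(seqs) {
    lengths(Biostrings::vwhichPDict(pd, Biostrings::DNAStringSet(seqs))) > 0L
  }
  rp[has_hit(rp$seq1) | has_hit(rp$seq2)]
}
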