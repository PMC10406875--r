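#' Paired-end read set
#'
#' Container for a paired-end read pool: parallel character vectors of ids,
#' mate sequences and Phred quality strings, plus an optional `info`
#' data.frame of simulator truth (source sequence and fragment coordinates)
#' carried along for ground-truth checks.
#'
#' @param id Character vector of pair ids (no mate suffix).
#' @param seq1,seq2 Character vectors of mate-1 / mate-2 sequences.
#' @param qual1,qual2 Phred+33 quality strings, same lengths as the mates.
#' @param info Optional data.frame with one row per pair (simulation truth).
#' @return An object of class `read_pairs`.
#' @export
read_pairs <- function(id, seq1, qual1, seq2, qual2, info = NULL) {
  n <- length(id)
  stopifnot(
    length(seq1) == n, length(seq2) == n,
    length(qual1) == n, length(qual2) == n,
    nchar(seq1) == nchar(qual1), nchar(seq2) == nchar(qual2)
  )
  if (!is.null(info)) stopifnot(nrow(info) == n)
  structure(
    list(id = as.character(id), seq1 = seq1, qual1 = qual1,
         seq2 = seq2, qual2 = qual2, info = info),
    class = "read_pairs"
  )
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs", length(x)))
  if (length(x)) {
    cat(sprintf(", mate lengths %d-%d bp",
                min(nchar(c(x$seq1, x$seq2))), max(nchar(c(x$seq1, x$seq2)))))
  }
  cat("\n")
  invisible(x)
}

#' @export
`[.read_pairs` <- function(x, i) {
  read_pairs(x$id[i], x$seq1[i], x$qual1[i], x$seq2[i], x$qual2[i],
             info = if (!is.null(x$info)) x$info[i, , drop = FALSE])
}

#' Concatenate read pair sets
#' @param ... `read_pairs` objects.
#' @export
c.read_pairs <- function(...) {
  xs <- list(...)
  infos <- lapply(xs, `[[`, "info")
  info <- if (all(!vapply(infos, is.null, logical(1)))) do.call(rbind, infos)
  read_pairs(
    unlist(lapply(xs, `[[`, "id")),
    unlist(lapply(xs, `[[`, "seq1")), unlist(lapply(xs, `[[`, "qual1")),
    unlist(lapply(xs, `[[`, "seq2")), unlist(lapply(xs, `[[`, "qual2")),
    info = info
  )
}

# All individual mates of a pair set as one character vector (mate 1 block
# then mate 2 block).
all_mates <- function(rp) c(rp$seq1, rp$seq2)

#' Write paired reads as two FASTQ files
#'
#' Standard 4-line FASTQ, mate files suffixed `/1` and `/2` in the record
#' ids. Paths ending in `.gz` are written gzip-compressed.
#'
#' @param rp A [read_pairs] object.
#' @param r1_path,r2_path Output paths for mate 1 and mate 2.
#' @return Invisibly, the two paths.
#' @export
write_read_pairs <- function(rp, r1_path, r2_path) {
  write_one <- function(ids, seqs, quals, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, filepath = path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path)
    )
  }
  write_one(paste0(rp$id, "/1"), rp$seq1, rp$qual1, r1_path)
  write_one(paste0(rp$id, "/2"), rp$seq2, rp$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read_pairs object
#'
#' Accepts plain or gzip FASTQ. Mate ids must agree pairwise after
#' stripping a trailing `/1` / `/2`; a truncated final record or a
#' sequence/quality length mismatch is reported with its record index.
#'
#' @param r1_path,r2_path FASTQ paths for mate 1 and mate 2.
#' @return A [read_pairs] object.
#' @export
read_read_pairs <- function(r1_path, r2_path) {
  # Parsed from lines rather than via readQualityScaledDNAStringSet(): a
  # truncated or quality-less record must fail with its record index, which
  # the stream parser does not report.
  read_one <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- readLines(con)
    close(con)
    if (length(lines) %% 4L != 0L)
      stop_sexmark(sprintf(
        "'%s': truncated FASTQ, record %d is incomplete (%d trailing lines)",
        path, length(lines) %/% 4L + 1L, length(lines) %% 4L))
    rec <- matrix(lines, nrow = 4L)
    bad <- which(substr(rec[1L, ], 1L, 1L) != "@" |
                   substr(rec[3L, ], 1L, 1L) != "+")
    if (length(bad))
      stop_sexmark(sprintf("'%s': malformed FASTQ record %d near line %d",
                           path, bad[1], (bad[1] - 1L) * 4L + 1L))
    bad <- which(nchar(rec[2L, ]) != nchar(rec[4L, ]))
    if (length(bad))
      stop_sexmark(sprintf(
        "'%s': sequence/quality length mismatch in record %d (line %d)",
        path, bad[1], (bad[1] - 1L) * 4L + 2L))
    list(id = sub("/[12]$", "", sub("^@", "", sub("\\s.*$", "", rec[1L, ]))),
         seq = toupper(rec[2L, ]), qual = rec[4L, ])
  }
  m1 <- read_one(r1_path)
  m2 <- read_one(r2_path)
  if (length(m1$id) != length(m2$id))
    stop_sexmark(sprintf("mate files differ in record count: %d vs %d",
                         length(m1$id), length(m2$id)))
  bad <- which(m1$id != m2$id)
  if (length(bad))
    stop_sexmark(sprintf("mate id mismatch at record %d: '%s' vs '%s'",
                         bad[1], m1$id[bad[1]], m2$id[bad[1]]))
  read_pairs(m1$id, m1$seq, m1$qual, m2$seq, m2$qual)
}

#' Read / write FASTA sequence sets
#'
#' Wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()]; line-wrapped and gzip inputs are
#' handled by Biostrings.
#'
#' @param path FASTA file path.
#' @return `read_fasta()` returns a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# TSV helpers: header always written, tab-separated, no quoting surprises.
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

read_tsv <- function(path, required = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing))
      stop_sexmark(sprintf("'%s' lacks required column(s): %s",
                           path, paste(missing, collapse = ", ")))
  }
  df
}
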