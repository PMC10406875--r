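#' Map reads to scaffolds with zero mismatches
#'
#' Reports a hit at every position where a read, or its reverse complement,
#' is an exact substring of a scaffold — the semantics of an
#' ungapped 0-mismatch aligner, with all multi-mapping hits kept.
#'
#' @param reads Character vector of read sequences (A/C/G/T).
#' @param scaffolds A named [Biostrings::DNAStringSet] or named character
#'   vector.
#' @return A data.frame with one row per hit: `read` (index into `reads`),
#'   `scaffold_id`, `start` (1-based), `strand` (`"+"` / `"-"`).
#' @export
map_exact <- function(reads, scaffolds) {
  if (is.character(scaffolds)) scaffolds <- Biostrings::DNAStringSet(scaffolds)
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  empty <- data.frame(read = integer(0), scaffold_id = character(0),
                      start = integer(0), strand = character(0))
  if (length(reads) == 0L || length(scaffolds) == 0L) return(empty)

  hits_for <- function(patterns, strand) {
    res <- vector("list", length(scaffolds))
    for (g in split(seq_along(patterns), nchar(patterns))) {
      pd <- Biostrings::PDict(patterns[g])
      for (s in seq_along(scaffolds)) {
        m <- Biostrings::matchPDict(pd, scaffolds[[s]])
        cnt <- S4Vectors::elementNROWS(m)
        hit <- which(cnt > 0L)
        if (length(hit)) {
          res[[s]] <- rbind(res[[s]], data.frame(
            read = rep(g[hit], cnt[hit]),
            scaffold_id = names(scaffolds)[s],
            start = unlist(lapply(hit, function(i) IRanges::start(m[[i]]))),
            strand = strand))
        }
      }
    }
    do.call(rbind, c(res, list(empty)))
  }
  out <- rbind(hits_for(toupper(reads), "+"),
               hits_for(revcomp(toupper(reads)), "-"))
  out <- out[order(out$read, out$scaffold_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Per-read x per-scaffold exact-hit indicator (either strand), as a list of
# read-index vectors per scaffold. Used by profile_coverage; one PDict per
# read width keeps Biostrings' constant-width requirement satisfied.
exact_hit_sets <- function(reads, scaffolds) {
  hits <- rep(list(integer(0)), length(scaffolds))
  if (length(reads) == 0L) return(hits)
  reads <- toupper(reads)
  both <- c(reads, revcomp(reads))
  idx <- rep(seq_along(reads), 2L)
  for (g in split(seq_along(both), nchar(both))) {
    pd <- Biostrings::PDict(both[g])
    wh <- Biostrings::vwhichPDict(pd, scaffolds)
    for (s in seq_along(scaffolds))
      if (length(wh[[s]]))
        hits[[s]] <- c(hits[[s]], idx[g[wh[[s]]]])
  }
  lapply(hits, function(x) sort(unique(x)))
}

#' Per-scaffold pool coverage profiles
#'
#' Maps every mate of both pools back to the scaffolds with zero
#' mismatches and summarises, per scaffold and pool, the mapped-read count
#' and the mean per-base depth (sum of mapped read lengths divided by
#' scaffold length). A multi-mapping read contributes to every scaffold it
#' hits — conservative for the female-zero rule, where any female evidence
#' disqualifies a scaffold; within one scaffold a read is counted once.
#'
#' @param male_reads,female_reads [read_pairs] objects (the original
#'   quality-trimmed pools).
#' @param scaffolds A named [Biostrings::DNAStringSet].
#' @return A data.frame with one row per scaffold: `scaffold_id`, `length`,
#'   `male_mapped_reads`, `female_mapped_reads`, `male_mean_depth`,
#'   `female_mean_depth`.
#' @export
profile_coverage <- function(male_reads, female_reads, scaffolds) {
  if (length(scaffolds) == 0L) stop_sexmark("scaffold set is empty")
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%d", seq_along(scaffolds))
  slen <- Biostrings::width(scaffolds)
  pool_stats <- function(rp) {
    mates <- all_mates(rp)
    hs <- exact_hit_sets(mates, scaffolds)
    data.frame(
      mapped = vapply(hs, length, integer(1)),
      depth = vapply(seq_along(hs), function(s) {
        sum(nchar(mates[hs[[s]]])) / slen[s]
      }, numeric(1))
    )
  }
  m <- pool_stats(male_reads)
  f <- pool_stats(female_reads)
  data.frame(scaffold_id = names(scaffolds), length = slen,
             male_mapped_reads = m$mapped, female_mapped_reads = f$mapped,
             male_mean_depth = m$depth, female_mean_depth = f$depth,
             row.names = NULL)
}

#' Classify scaffolds by pooled coverage
#'
#' Applies the depth-based decision rules for a male-limited region:
#' \describe{
#'   \item{MALE_SPECIFIC}{male reads map, zero female reads map — depth
#'     only in the male pool.}
#'   \item{RESCUED_MALE_SPECIFIC}{some female depth, but male mean depth is
#'     at least `rescue_ratio` (default 2) times the female mean depth.}
#'   \item{PENDING}{everything else.}
#' }
#' The rescue comparison is inclusive (`>=`) by default; set
#' `inclusive = FALSE` for a strict `>`.
#'
#' @param profiles Data.frame from [profile_coverage()].
#' @param rescue_ratio Male:female mean-depth ratio for rescue (default 2).
#' @param inclusive Whether the ratio threshold is inclusive (default TRUE).
#' @return `profiles` with an added `label` factor column; every scaffold
#'   receives exactly one label.
#' @export
classify_scaffolds <- function(profiles, rescue_ratio = 2,
                               inclusive = TRUE) {
  stopifnot(rescue_ratio > 0)
  ms <- profiles$female_mapped_reads == 0L & profiles$male_mapped_reads > 0L
  thr <- rescue_ratio * profiles$female_mean_depth
  rescued <- !ms & profiles$female_mean_depth > 0 &
    (if (inclusive) profiles$male_mean_depth >= thr
     else profiles$male_mean_depth > thr)
  label <- rep("PENDING", nrow(profiles))
  label[rescued] <- "RESCUED_MALE_SPECIFIC"
  label[ms] <- "MALE_SPECIFIC"
  profiles$label <- factor(label, levels = c("MALE_SPECIFIC",
                                             "RESCUED_MALE_SPECIFIC",
                                             "PENDING"))
  profiles
}

#' Select candidate male-specific scaffolds
#'
#' Returns the MALE_SPECIFIC and RESCUED_MALE_SPECIFIC scaffolds at least
#' `min_length` long, sorted by decreasing length. The length filter
#' stands in for downstream gene-level screening of candidates.
#'
#' @param reports Labelled data.frame from [classify_scaffolds()].
#' @param scaffolds The [Biostrings::DNAStringSet] the reports describe.
#' @param min_length Minimum candidate length in bases (default 100).
#' @return A [Biostrings::DNAStringSet] of candidate scaffolds.
#' @export
filter_candidates <- function(reports, scaffolds, min_length = 100) {
  keep <- reports$label %in% c("MALE_SPECIFIC", "RESCUED_MALE_SPECIFIC") &
    reports$length >= min_length
  ids <- reports$scaffold_id[keep][order(-reports$length[keep])]
  scaffolds[ids]
}
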