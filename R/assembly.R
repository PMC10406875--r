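#' Unitig assembly parameters
#'
#' Settings for the minimal de Bruijn unitig assembler that turns candidate
#' male-biased read pairs into scaffolds. Nodes are canonical `graph_k`-mers
#' (lexicographic minimum of a k-mer and its reverse complement); nodes
#' seen fewer than `min_kmer_count` times are dropped before unitig
#' extraction, and unitigs shorter than `min_unitig_length` are discarded
#' from the output.
#'
#' @param graph_k Odd de Bruijn k-mer size, `15 <= graph_k` and below the
#'   read length (default 31).
#' @param min_kmer_count Minimum k-mer multiplicity to keep a node
#'   (default 2).
#' @param min_unitig_length Minimum reported unitig length in bases
#'   (default 100).
#' @param clip_tips Remove dead-end unitigs shorter than `2 * graph_k`
#'   whose every node was seen exactly once (only relevant when
#'   `min_kmer_count = 1`; default `TRUE`).
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(graph_k = 31, min_kmer_count = 2,
                            min_unitig_length = 100, clip_tips = TRUE) {
  graph_k <- check_count(graph_k, "graph_k", min = 15)
  if (graph_k %% 2 == 0) stop_sexmark("graph_k must be odd")
  structure(
    list(graph_k = graph_k,
         min_kmer_count = check_count(min_kmer_count, "min_kmer_count", 1),
         min_unitig_length = check_count(min_unitig_length,
                                         "min_unitig_length"),
         clip_tips = isTRUE(clip_tips)),
    class = "assembly_params"
  )
}

#' Build a de Bruijn graph from reads
#'
#' Nodes are the canonical `graph_k`-mers of the reads with their
#' multiplicities; edges are implicit (two nodes are adjacent when some
#' orientation of one extends some orientation of the other by one base,
#' which is exactly the (k+1)-mer overlaps observable in the reads, since
#' every adjacent node pair here comes from consecutive read positions).
#' Windows containing N are skipped.
#'
#' @param reads A [read_pairs] object or character vector of sequences.
#' @param params An [assembly_params].
#' @return An object of class `debruijn_graph`: a list with `nodes`
#'   (data.table: kmer, count; canonical, sorted) and `k`.
#' @export
build_graph <- function(reads, params = assembly_params()) {
  seqs <- if (inherits(reads, "read_pairs")) all_mates(reads) else reads
  if (length(seqs) == 0L) stop_sexmark("read collection is empty")
  if (all(nchar(seqs) < params$graph_k))
    stop_sexmark("graph_k is not below any read length")
  k <- params$graph_k
  kmers <- all_kmers_pooled(seqs, k)
  nodes <- data.table(kmer = canonical_kmer(kmers))[, .(count = .N), by = kmer]
  nodes <- nodes[nodes$count >= params$min_kmer_count]
  setorder(nodes, kmer)
  structure(list(nodes = nodes[], k = k), class = "debruijn_graph")
}

# Every k-window of every sequence (not prefix-restricted), N-windows
# dropped; pooled via single-'N' joins as in the screening module.
all_kmers_pooled <- function(seqs, k) {
  seqs <- toupper(seqs[nchar(seqs) >= k])
  if (!length(seqs)) return(character(0))
  big <- paste(seqs, collapse = "N")
  n <- nchar(big)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(big, starts, starts + k - 1L)
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("debruijn_graph: %d canonical %d-mer nodes\n",
              nrow(x$nodes), x$k))
  invisible(x)
}

#' Extract unitigs (maximal non-branching paths) from a de Bruijn graph
#'
#' Walks the bidirected graph: an edge is absorbed into a unitig iff it is
#' the unique outgoing extension of its source side and the unique incoming
#' extension of its target side. Every surviving node lands in exactly one
#' unitig. Each unitig is reported in its lexicographically smaller
#' orientation; output is sorted by decreasing length, ties by sequence,
#' and is therefore deterministic for a given graph. Isolated cycles are
#' broken at their lexicographically smallest node.
#'
#' @param graph A `debruijn_graph` from [build_graph()].
#' @param params An [assembly_params]; `min_unitig_length` and `clip_tips`
#'   apply here.
#' @return A named [Biostrings::DNAStringSet] of scaffolds
#'   (`scaffold_1`, `scaffold_2`, ...).
#' @export
extract_unitigs <- function(graph, params = assembly_params()) {
  stopifnot(inherits(graph, "debruijn_graph"))
  uni <- walk_unitigs(graph$nodes, graph$k)
  if (params$clip_tips && nrow(uni)) {
    # Tips: dead-ended short unitigs made entirely of singleton k-mers.
    tip <- uni$dead_end & uni$min_count == 1L &
      nchar(uni$seq) < 2L * graph$k
    if (any(tip)) {
      keep_nodes <- graph$nodes[!graph$nodes$kmer %chin%
                                  unlist(uni$node_kmers[tip])]
      uni <- walk_unitigs(keep_nodes, graph$k)
    }
  }
  seqs <- uni$seq[nchar(uni$seq) >= params$min_unitig_length]
  if (length(seqs)) {
    rc <- revcomp(seqs)
    seqs <- ifelse(seqs <= rc, seqs, rc)
    seqs <- seqs[order(-nchar(seqs), seqs)]
  }
  out <- Biostrings::DNAStringSet(seqs)
  if (length(out)) names(out) <- sprintf("scaffold_%d", seq_along(out))
  out
}

#' Assemble reads into scaffolds
#'
#' Convenience wrapper: [build_graph()] then [extract_unitigs()].
#'
#' @inheritParams build_graph
#' @return A named [Biostrings::DNAStringSet] of scaffolds.
#' @export
assemble_reads <- function(reads, params = assembly_params()) {
  extract_unitigs(build_graph(reads, params), params)
}

# Core unitig walker over a canonical node table. Returns a data.frame
# with one row per unitig: seq, min_count, dead_end (either end had no
# extension), node_kmers (list of member canonical k-mers).
walk_unitigs <- function(nodes, k) {
  empty <- data.frame(seq = character(0), min_count = integer(0),
                      dead_end = logical(0))
  empty$node_kmers <- list()
  if (nrow(nodes) == 0L) return(empty)
  kmer <- nodes$kmer
  count <- nodes$count
  n <- length(kmer)
  rc <- revcomp(kmer)

  # For node i in orientation o (1 = canonical/forward, 2 = reverse), the
  # oriented sequence:
  oriented <- function(i, o) if (o == 1L) kmer[i] else rc[i]

  # Successor table: for each node and orientation, which of the 4 one-base
  # extensions exist, and what they are (node index + orientation entered).
  succ_of <- function(strings) {
    suf <- substr(strings, 2L, k)
    idx <- matrix(0L, n, 4L)
    ori <- matrix(0L, n, 4L)
    for (b in 1:4) {
      cand <- paste0(suf, DNA_BASES[b])
      crc <- revcomp(cand)
      canon <- ifelse(cand <= crc, cand, crc)
      m <- chmatch(canon, kmer)
      idx[, b] <- ifelse(is.na(m), 0L, m)
      ori[, b] <- ifelse(cand <= crc, 1L, 2L)
    }
    list(idx = idx, ori = ori, deg = rowSums(idx > 0L))
  }
  fw <- succ_of(kmer)  # extensions leaving the forward orientation
  bw <- succ_of(rc)    # extensions leaving the reverse orientation

  deg <- function(i, o) if (o == 1L) fw$deg[i] else bw$deg[i]
  next_step <- function(i, o) {
    s <- if (o == 1L) fw else bw
    b <- which(s$idx[i, ] > 0L)
    c(s$idx[i, b], s$ori[i, b], b)
  }

  visited <- logical(n)
  out_seq <- character(0)
  out_min <- integer(0)
  out_dead <- logical(0)
  out_nodes <- list()

  emit <- function(path_idx, path_ori, dead_end) {
    s <- oriented(path_idx[1], path_ori[1])
    if (length(path_idx) > 1L) {
      last <- vapply(seq_along(path_idx)[-1], function(j) {
        substr(oriented(path_idx[j], path_ori[j]), k, k)
      }, character(1))
      s <- paste0(s, paste(last, collapse = ""))
    }
    out_seq[length(out_seq) + 1L] <<- s
    out_min[length(out_min) + 1L] <<- min(count[path_idx])
    out_dead[length(out_dead) + 1L] <<- dead_end
    out_nodes[[length(out_nodes) + 1L]] <<- kmer[path_idx]
  }

  # Walk forward from (i, o) while the current side has out-degree 1 and
  # the entered side of the successor has in-degree 1 (i.e. the successor's
  # opposite orientation has out-degree 1 back).
  walk_from <- function(i, o) {
    path_idx <- integer(n); path_ori <- integer(n)
    path_idx[1L] <- i; path_ori[1L] <- o
    len <- 1L
    visited[i] <<- TRUE
    repeat {
      cur <- path_idx[len]; co <- path_ori[len]
      if (deg(cur, co) != 1L) break
      st <- next_step(cur, co)
      ni <- st[1]; no <- st[2]
      # in-degree at the entered side = out-degree of its opposite side
      if (deg(ni, 3L - no) != 1L) break
      if (visited[ni]) break  # cycle closure
      visited[ni] <<- TRUE
      len <- len + 1L
      path_idx[len] <- ni; path_ori[len] <- no
    }
    list(idx = path_idx[seq_len(len)], ori = path_ori[seq_len(len)])
  }

  # Path starts: any side that is not the unique continuation of a unique
  # predecessor — i.e. orientation o of node i starts a unitig when the
  # incoming side (out-degree of orientation 3-o) is not a simple edge
  # into it.
  is_start <- function(i, o) {
    if (deg(i, 3L - o) != 1L) return(TRUE)     # 0 or >1 predecessors
    st <- next_step(i, 3L - o)                 # the unique predecessor
    deg(st[1], 3L - st[2]) != 1L               # which must also leave
  }                                            # uniquely to be internal

  for (i in seq_len(n)) {
    if (visited[i]) next
    for (o in 1:2) {
      if (!visited[i] && is_start(i, o)) {
        p <- walk_from(i, o)
        emit(p$idx, p$ori, dead_end = deg(i, 3L - o) == 0L ||
               deg(p$idx[length(p$idx)], p$ori[length(p$ori)]) == 0L)
      }
    }
  }
  # Remaining nodes are in isolated cycles; break each at its smallest node.
  while (any(!visited)) {
    i <- which(!visited)
    i <- i[which.min(kmer[i])]
    p <- walk_from(i, 1L)
    emit(p$idx, p$ori, dead_end = FALSE)
  }
  res <- data.frame(seq = out_seq, min_count = out_min, dead_end = out_dead)
  res$node_kmers <- out_nodes
  res
}

#' Assembly summary statistics
#'
#' @param scaffolds A [Biostrings::DNAStringSet].
#' @return A one-row data.frame: n, total_bp, n50.
#' @export
assembly_stats <- function(scaffolds) {
  w <- sort(Biostrings::width(scaffolds), decreasing = TRUE)
  n50 <- if (length(w)) w[which(cumsum(w) >= sum(w) / 2)[1]] else 0L
  data.frame(n = length(w), total_bp = sum(w), n50 = n50)
}
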