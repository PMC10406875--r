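#' Dioecious genome model
#'
#' Parameters for a minimal XX/XY genome pair: a shared autosome, a shared
#' X region, and a hemizygous Y male-specific region (Y-MSR) present only
#' in males. With `divergence_xy = 1` (default) the Y-MSR is generated
#' independently of the X, so for regions of a few kilobases or more no
#' 35-mer of the Y-MSR is expected to occur in the female genome; with
#' `divergence_xy < 1` the Y-MSR is a gametolog, i.e. a copy of the start
#' of the X region with that fraction of sites substituted.
#'
#' @param autosome_length,x_region_length,y_msr_length Lengths in bases.
#' @param divergence_xy Fraction of substituted sites between the X and Y
#'   gametologs, in `[0, 1]`; `1` means an independent random Y-MSR.
#' @param seed Integer seed; identical models yield byte-identical genomes.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(autosome_length = 100000, x_region_length = 20000,
                         y_msr_length = 10000, divergence_xy = 1, seed = 1) {
  autosome_length <- check_count(autosome_length, "autosome_length")
  x_region_length <- check_count(x_region_length, "x_region_length")
  y_msr_length <- check_count(y_msr_length, "y_msr_length")
  check_probability(divergence_xy, "divergence_xy")
  if (autosome_length + x_region_length + y_msr_length <= 0)
    stop_sexmark("total genome length must be positive")
  if (divergence_xy < 1 && y_msr_length > x_region_length)
    stop_sexmark("a gametolog Y-MSR (divergence_xy < 1) cannot be longer than the X region")
  structure(
    list(autosome_length = autosome_length,
         x_region_length = x_region_length,
         y_msr_length = y_msr_length,
         divergence_xy = divergence_xy,
         seed = as.integer(seed)),
    class = "genome_model"
  )
}

#' Simulate a female/male genome pair
#'
#' The female genome is \{autosome, X region\}; the male genome is the same
#' two sequences (base-identical) plus the Y-MSR. Sequences are uniform
#' i.i.d. A/C/G/T with no Ns.
#'
#' @param model A [genome_model].
#' @return A list with `female` and `male` [Biostrings::DNAStringSet]s;
#'   sequence names are `autosome`, `x_region`, `y_msr`.
#' @export
simulate_genomes <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  withr::with_seed(model$seed, {
    shared <- character(0)
    if (model$autosome_length > 0)
      shared <- c(autosome = random_dna(model$autosome_length))
    if (model$x_region_length > 0)
      shared <- c(shared, x_region = random_dna(model$x_region_length))
    male <- shared
    if (model$y_msr_length > 0) {
      y <- if (model$divergence_xy >= 1) {
        random_dna(model$y_msr_length)
      } else {
        mutate_sequence(substr(shared[["x_region"]], 1, model$y_msr_length),
                        model$divergence_xy)
      }
      male <- c(male, y_msr = y)
    }
  })
  list(female = Biostrings::DNAStringSet(shared),
       male = Biostrings::DNAStringSet(male))
}

# Substitute each base independently with probability `rate`, always to a
# different base.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Pooled read simulation settings
#'
#' Illumina-style paired-end sampling: fragment lengths are normal with the
#' given mean and sd, truncated below at `read_length`; both strands are
#' sampled with equal probability; sequencing errors are i.i.d. per-base
#' substitutions. Quality strings are constant Q37 unless `degrade_3prime`
#' marks that many 3' bases as Q2, to exercise the trimming stage.
#'
#' @param read_length Mate length in bases (default 150).
#' @param fragment_mean,fragment_sd Insert-size distribution in bases.
#' @param coverage Fold depth per pool over the (dosage-weighted) genome.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param degrade_3prime Number of 3' bases written at Q2 instead of Q37.
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 150, fragment_mean = 400,
                            fragment_sd = 40, coverage = 30,
                            error_rate = 0, degrade_3prime = 0, seed = 1) {
  read_length <- check_count(read_length, "read_length", min = 1)
  if (read_length > fragment_mean)
    stop_sexmark("read_length must not exceed fragment_mean")
  if (coverage <= 0) stop_sexmark("coverage must be positive")
  check_probability(error_rate, "error_rate")
  if (error_rate >= 1) stop_sexmark("error_rate must be < 1")
  structure(
    list(read_length = read_length, fragment_mean = fragment_mean,
         fragment_sd = fragment_sd, coverage = coverage,
         error_rate = error_rate,
         degrade_3prime = check_count(degrade_3prime, "degrade_3prime"),
         seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' Simulate a pooled paired-end read set from a genome
#'
#' The number of pairs is `round(coverage * effective_length /
#' (2 * read_length))`, where `effective_length` weights each sequence by
#' its `dosage` (hemizygous sequence such as the Y-MSR in a male pool is
#' typically given dosage 0.5, half the autosomal copy number). Fragments
#' land uniformly within each sequence; mate 2 is the reverse complement of
#' the fragment's 3' end (standard FR orientation).
#'
#' @param genomes A named [Biostrings::DNAStringSet] (or named character
#'   vector) of template sequences.
#' @param cfg A [read_sim_config].
#' @param dosage Named numeric vector of per-sequence copy-number weights;
#'   sequences not named get weight 1.
#' @param id_prefix Prefix for read ids.
#' @return A [read_pairs] object whose `info` data.frame records, per pair,
#'   the source sequence name, fragment start/end (1-based, on the source)
#'   and strand — the simulator's ground truth.
#' @export
simulate_pool_reads <- function(genomes, cfg, dosage = NULL,
                                id_prefix = "read") {
  stopifnot(inherits(cfg, "read_sim_config"))
  seqs <- if (is.character(genomes)) genomes else
    setNames(as.character(genomes), names(genomes))
  if (length(seqs) == 0L) stop_sexmark("genome set is empty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_sexmark("genome sequences must be named")
  lens <- nchar(seqs)
  if (all(lens < cfg$read_length))
    stop_sexmark("read_length exceeds every sequence length")
  usable <- lens >= cfg$read_length
  seqs <- seqs[usable]; lens <- lens[usable]

  w <- rep(1, length(seqs))
  if (!is.null(dosage)) {
    hit <- names(seqs) %in% names(dosage)
    w[hit] <- dosage[names(seqs)[hit]]
  }
  eff_len <- sum(lens * w)
  n_pairs <- round(cfg$coverage * eff_len / (2 * cfg$read_length))
  rl <- cfg$read_length

  withr::with_seed(cfg$seed, {
    src <- sample(seq_along(seqs), n_pairs, replace = TRUE, prob = lens * w)
    frag <- pmax(rl, round(rnorm(n_pairs, cfg$fragment_mean, cfg$fragment_sd)))
    frag <- pmin(frag, lens[src])
    start <- floor(runif(n_pairs) * (lens[src] - frag + 1)) + 1
    minus <- runif(n_pairs) < 0.5

    frags <- substring(seqs[src], start, start + frag - 1)
    frags[minus] <- revcomp(frags[minus])
    r1 <- substr(frags, 1L, rl)
    r2 <- revcomp(substring(frags, frag - rl + 1, frag))
    if (cfg$error_rate > 0) {
      r1 <- add_read_errors(r1, cfg$error_rate)
      r2 <- add_read_errors(r2, cfg$error_rate)
    }
  })

  qual <- strrep("F", rl)  # Phred+33 'F' = Q37
  if (cfg$degrade_3prime > 0) {
    keep <- max(0L, rl - cfg$degrade_3prime)
    qual <- paste0(strrep("F", keep), strrep("#", rl - keep))  # '#' = Q2
  }
  read_pairs(
    id = sprintf("%s_%06d", id_prefix, seq_len(n_pairs)),
    seq1 = unname(r1), qual1 = rep(qual, n_pairs),
    seq2 = unname(r2), qual2 = rep(qual, n_pairs),
    info = data.frame(source = names(seqs)[src], frag_start = start,
                      frag_end = start + frag - 1,
                      strand = ifelse(minus, "-", "+"))
  )
}

# Vectorised i.i.d. substitution errors over a character vector of reads.
add_read_errors <- function(reads, rate) {
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    flat[hit] <- vapply(flat[hit],
                        function(b) sample(setdiff(DNA_BASES, b), 1L),
                        character(1))
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)),
         paste, character(1), collapse = "")
}

#' Validation-panel composition
#'
#' Mirrors a field validation panel of sexed individuals for a dominant
#' marker: males carry the marker site unless dropout removes it; females
#' lack it unless leakage (e.g. an imperfect paralog) adds it.
#'
#' @param n_males,n_females Individual counts.
#' @param male_dropout Probability a male individual lacks the marker site.
#' @param female_leakage Probability a female individual carries it.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_males, n_females, male_dropout = 0,
                       female_leakage = 0, seed = 1) {
  structure(
    list(n_males = check_count(n_males, "n_males"),
         n_females = check_count(n_females, "n_females"),
         male_dropout = check_probability(male_dropout, "male_dropout"),
         female_leakage = check_probability(female_leakage, "female_leakage"),
         seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' Simulate a marker-validation panel
#'
#' Every individual receives the background template; carriers additionally
#' receive the marker template. Carrier status is Bernoulli per the
#' [panel_spec] probabilities.
#'
#' @param marker_template Character scalar, the marker-bearing sequence.
#' @param background Character scalar, sequence shared by all individuals.
#' @param spec A [panel_spec].
#' @param subpopulation Optional label recorded for every individual.
#' @return A list with `templates` (named list of
#'   [Biostrings::DNAStringSet], one per individual) and `truth`
#'   (data.frame: individual_id, sex, carries_marker, subpopulation).
#' @export
simulate_panel <- function(marker_template, background, spec,
                           subpopulation = "panel") {
  stopifnot(inherits(spec, "panel_spec"))
  if (!nzchar(marker_template)) stop_sexmark("marker_template is empty")
  n <- spec$n_males + spec$n_females
  sex <- rep(c("male", "female"), c(spec$n_males, spec$n_females))
  id <- sprintf("%s_%s_%03d", substr(sex, 1, 1), subpopulation, c(
    seq_len(spec$n_males), seq_len(spec$n_females)))
  withr::with_seed(spec$seed, {
    carries <- ifelse(sex == "male",
                      runif(n) >= spec$male_dropout,
                      runif(n) < spec$female_leakage)
  })
  templates <- lapply(seq_len(n), function(i) {
    s <- c(background = background)
    if (carries[i]) s <- c(s, marker = marker_template)
    Biostrings::DNAStringSet(s)
  })
  names(templates) <- id
  list(templates = templates,
       truth = data.frame(individual_id = id, sex = sex,
                          carries_marker = carries,
                          subpopulation = subpopulation))
}

#' Write a simulated panel to disk
#'
#' One multi-FASTA per individual plus a tab-separated truth table
#' (individual_id, sex, carries_marker, subpopulation).
#'
#' @param panel Result of [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the truth-table path.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(panel$templates))
    write_fasta(panel$templates[[id]], file.path(dir, paste0(id, ".fasta")))
  write_tsv(panel$truth, file.path(dir, "truth.tsv"))
}
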