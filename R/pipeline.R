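#' Pipeline run configuration
#'
#' Bundles the per-stage parameters of the full discovery run
#' (simulate -> trim -> k-mer screen -> assemble -> classify -> in-silico
#' PCR) plus a single global seed that is fanned out deterministically to
#' the stages, so any stage can be rerun in isolation and reproduce its
#' part of a full run.
#'
#' @param genome A [genome_model] (used when simulation is enabled).
#' @param reads A [read_sim_config].
#' @param trim A [trim_params].
#' @param screen A [kmer_screen_params].
#' @param assembly An [assembly_params].
#' @param rescue_ratio Male:female depth ratio for scaffold rescue.
#' @param min_candidate_length Minimum candidate scaffold length in bases.
#' @param pcr A [pcr_params].
#' @param y_dosage Copy-number weight of the hemizygous Y-MSR in the male
#'   pool (default 0.5: half the autosomal copy number).
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genome = genome_model(), reads = read_sim_config(),
                       trim = trim_params(), screen = kmer_screen_params(),
                       assembly = assembly_params(), rescue_ratio = 2,
                       min_candidate_length = 100, pcr = pcr_params(),
                       y_dosage = 0.5, seed = 1) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(reads, "read_sim_config"),
            inherits(trim, "trim_params"),
            inherits(screen, "kmer_screen_params"),
            inherits(assembly, "assembly_params"),
            inherits(pcr, "pcr_params"))
  if (rescue_ratio <= 0) stop_sexmark("rescue_ratio must be positive")
  structure(list(genome = genome, reads = reads, trim = trim,
                 screen = screen, assembly = assembly,
                 rescue_ratio = rescue_ratio,
                 min_candidate_length = check_count(min_candidate_length,
                                                    "min_candidate_length"),
                 pcr = pcr, y_dosage = y_dosage, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Every key is optional and defaults to the [run_config()] defaults; keys
#' are grouped by stage (`genome:`, `reads:`, `trim:`, `screen:`,
#' `assembly:`, `pcr:`) with scalars (`seed`, `rescue_ratio`,
#' `min_candidate_length`, `y_dosage`) at the top level. Unknown keys are
#' rejected, so typos fail loudly.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path) %||% list()
  known <- c("genome", "reads", "trim", "screen", "assembly", "pcr",
             "rescue_ratio", "min_candidate_length", "y_dosage", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop_sexmark("unknown config key(s): ", paste(bad, collapse = ", "))
  build <- function(fn, args) do.call(fn, args %||% list())
  gseed <- as.integer(seed %||% y$seed %||% 1L)
  run_config(
    genome = build(genome_model,
                   c(y$genome, list(seed = stage_seed(gseed, "genome")))),
    reads = build(read_sim_config,
                  c(y$reads, list(seed = stage_seed(gseed, "reads")))),
    trim = build(trim_params, y$trim),
    screen = build(kmer_screen_params, y$screen),
    assembly = build(assembly_params, y$assembly),
    rescue_ratio = y$rescue_ratio %||% 2,
    min_candidate_length = y$min_candidate_length %||% 100,
    pcr = build(pcr_params, y$pcr),
    y_dosage = y$y_dosage %||% 0.5,
    seed = gseed
  )
}

#' Run the full marker-discovery pipeline on a simulated dataset
#'
#' Executes, in order: genome simulation, pooled read simulation (male pool
#' with the hemizygous Y-MSR at `y_dosage`), quality trimming, pooled
#' k-mer screening and MSK selection, candidate-pair extraction, unitig
#' assembly, zero-mismatch map-back with depth classification, and
#' candidate selection. When `out_dir` is given, every stage's outputs are
#' written (FASTA/FASTQ/TSV) together with a JSON run manifest of file
#' checksums, record counts and the full parameter set; reruns with the
#' same config are byte-identical.
#'
#' @param config A [run_config].
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return A list with the per-stage objects: `genomes`, `male_reads`,
#'   `female_reads` (trimmed), `kmer_table` (filtered), `msks`,
#'   `candidate_pairs`, `scaffolds`, `report`, `candidates`, and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] genomes: autosome %d bp, X %d bp, Y-MSR %d bp",
      config$genome$autosome_length, config$genome$x_region_length,
      config$genome$y_msr_length)
  genomes <- simulate_genomes(config$genome)

  rcfg <- config$reads
  mcfg <- rcfg; mcfg$seed <- stage_seed(config$seed, "male_pool")
  fcfg <- rcfg; fcfg$seed <- stage_seed(config$seed, "female_pool")
  male_raw <- simulate_pool_reads(genomes$male, mcfg,
                                  dosage = c(y_msr = config$y_dosage),
                                  id_prefix = "m")
  female_raw <- simulate_pool_reads(genomes$female, fcfg, id_prefix = "f")
  say("[simulate] reads: %d male pairs, %d female pairs",
      length(male_raw), length(female_raw))

  male_reads <- quality_trim(male_raw, config$trim)
  female_reads <- quality_trim(female_raw, config$trim)
  say("[trim] kept %d/%d male, %d/%d female pairs",
      length(male_reads), length(male_raw),
      length(female_reads), length(female_raw))

  table_raw <- count_pool_kmers(male_reads, female_reads, config$screen)
  screened <- filter_and_select_msks(table_raw, config$screen)
  say("[screen] %d prefixed k-mers, %d retained, %d MSKs",
      nrow(table_raw), nrow(screened$table), length(screened$msks))

  candidate_pairs <- extract_candidate_read_pairs(male_reads, screened$msks,
                                                  config$screen)
  say("[screen] %d candidate read pairs", length(candidate_pairs))

  scaffolds <- if (length(candidate_pairs)) {
    assemble_reads(candidate_pairs, config$assembly)
  } else Biostrings::DNAStringSet()
  say("[assemble] %d scaffolds, %d bp", length(scaffolds),
      sum(Biostrings::width(scaffolds)))

  if (length(scaffolds)) {
    profiles <- profile_coverage(male_reads, female_reads, scaffolds)
    report <- classify_scaffolds(profiles, config$rescue_ratio)
    candidates <- filter_candidates(report, scaffolds,
                                    config$min_candidate_length)
  } else {
    report <- classify_scaffolds(profile_coverage_empty())
    candidates <- Biostrings::DNAStringSet()
  }
  say("[classify] %d MALE_SPECIFIC, %d RESCUED, %d PENDING; %d candidates",
      sum(report$label == "MALE_SPECIFIC"),
      sum(report$label == "RESCUED_MALE_SPECIFIC"),
      sum(report$label == "PENDING"), length(candidates))

  res <- list(genomes = genomes, male_reads = male_reads,
              female_reads = female_reads, kmer_table = screened$table,
              msks = screened$msks, candidate_pairs = candidate_pairs,
              scaffolds = scaffolds, report = report,
              candidates = candidates)

  if (!is.null(out_dir)) {
    res$manifest <- write_run_outputs(res, config, out_dir, t0)
  } else {
    res$manifest <- build_manifest(res, config, files = list(), t0)
  }
  res
}

profile_coverage_empty <- function() {
  data.frame(scaffold_id = character(0), length = integer(0),
             male_mapped_reads = integer(0), female_mapped_reads = integer(0),
             male_mean_depth = numeric(0), female_mean_depth = numeric(0))
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

build_manifest <- function(res, config, files, t0) {
  list(
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = strip_classes(config),
    counts = list(
      male_pairs_trimmed = length(res$male_reads),
      female_pairs_trimmed = length(res$female_reads),
      kmers_retained = nrow(res$kmer_table),
      msks = length(res$msks),
      candidate_pairs = length(res$candidate_pairs),
      scaffolds = length(res$scaffolds),
      male_specific = sum(res$report$label == "MALE_SPECIFIC"),
      rescued_male_specific = sum(res$report$label ==
                                    "RESCUED_MALE_SPECIFIC"),
      pending = sum(res$report$label == "PENDING"),
      candidates = length(res$candidates)
    ),
    files = files
  )
}

write_run_outputs <- function(res, config, out_dir, t0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(res$genomes$female, p("genome_female.fasta"))
  write_fasta(res$genomes$male, p("genome_male.fasta"))
  write_read_pairs(res$male_reads, p("male_R1.fastq"), p("male_R2.fastq"))
  write_read_pairs(res$female_reads, p("female_R1.fastq"),
                   p("female_R2.fastq"))
  write_tsv(res$kmer_table, p("kmer_table.tsv"))
  writeLines(res$msks, p("msks.txt"))
  write_read_pairs(res$candidate_pairs, p("candidates_R1.fastq"),
                   p("candidates_R2.fastq"))
  if (length(res$scaffolds)) {
    write_fasta(res$scaffolds, p("scaffolds.fasta"))
    write_tsv(assembly_stats(res$scaffolds), p("assembly_stats.tsv"))
  }
  write_tsv(res$report, p("scaffold_report.tsv"))
  if (length(res$candidates))
    write_fasta(res$candidates, p("candidates.fasta"))

  rel <- list.files(out_dir, recursive = TRUE)
  rel <- setdiff(rel, "manifest.json")
  files <- lapply(rel, function(f) {
    list(path = f, md5 = unname(tools::md5sum(p(f))),
         bytes = file.size(p(f)))
  })
  names(files) <- rel
  manifest <- build_manifest(res, config, files, t0)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest
}

#' Published kiwiberry sex-marker primer pairs
#'
#' The two validated dominant male markers for *Actinidia arguta*
#' (kiwiberry): P51 (609 bp product, annealing 60 degC) and P11 (304 bp
#' product, annealing 65 degC). Sequences are bundled at
#' `inst/extdata/primers_arguta.tsv`.
#'
#' @return Named list of [primer_pair] objects (`P51`, `P11`).
#' @export
arguta_sex_primers <- function() {
  read_primers_tsv(system.file("extdata", "primers_arguta.tsv",
                               package = "sexmark", mustWork = TRUE))
}

#' Published validation-panel contingency counts
#'
#' Presence/absence counts of the P51 and P11 markers across the published
#' *A. arguta* validation panel: 97 F1 hybrids (45 males, 52 females) and
#' 31 wild accessions (18 males, 13 females), 128 individuals per marker.
#'
#' @return A data.frame: `marker`, `sex`, `subpopulation`, `presence`,
#'   `absence`.
#' @export
arguta_panel_counts <- function() {
  read_tsv(system.file("extdata", "arguta_panel_counts.tsv",
                       package = "sexmark", mustWork = TRUE),
           required = c("marker", "sex", "subpopulation", "presence",
                        "absence"))
}

#' Synthetic marker template for a primer pair
#'
#' Builds a synthetic template whose single predicted product for `pair`
#' has exactly `product_size` bases: forward primer + seeded random filler
#' + reverse complement of the reverse primer, embedded in random flanks.
#' Used where the real marker locus sequence is not distributed with the
#' package.
#'
#' @param pair A [primer_pair].
#' @param product_size Total product length in bases (defaults to the
#'   pair's `expected_size`).
#' @param flank Random flanking bases on each side (default 200).
#' @param seed Integer seed.
#' @return A single character string.
#' @export
synthetic_marker_template <- function(pair, product_size = NULL,
                                      flank = 200, seed = 1) {
  product_size <- product_size %||% pair$expected_size
  stopifnot(is.numeric(product_size), !is.na(product_size))
  inner <- product_size - nchar(pair$forward) - nchar(pair$reverse)
  if (inner < 0) stop_sexmark("product_size smaller than the two primers")
  withr::with_seed(seed, {
    paste0(random_dna(flank), pair$forward, random_dna(inner),
           revcomp(pair$reverse), random_dna(flank))
  })
}
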