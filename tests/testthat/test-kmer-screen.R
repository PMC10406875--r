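test_that("sliding-window quality trimming matches a hand oracle", {
  p <- trim_params(window = 4, min_mean_quality = 20, min_length = 50)

  # all-Q37 input is untouched
  rp <- make_rp(rand_seq(150), rand_seq(150))
  out <- quality_trim(rp, p)
  expect_identical(out$seq1, rp$seq1)
  expect_identical(out$seq2, rp$seq2)

  # 150 bp read whose 3' 60 bases are Q2: the first window whose mean
  # drops below Q20 starts at base 89 (37,37,2,2 -> 19.5); trimming cuts
  # there and extends through the remaining Q37 bases 89 and 90.
  seq150 <- rand_seq(150)
  qual <- paste0(strrep("F", 90), strrep("#", 60))
  rp2 <- make_rp(seq150, seq150, qual1 = qual)
  out2 <- quality_trim(rp2, p)
  expect_equal(length(out2), 1)
  expect_identical(out2$seq1, substr(seq150, 1, 90))
  expect_identical(out2$qual1, strrep("F", 90))
  expect_identical(nchar(out2$seq2), 150L)  # clean mate untouched

  # entirely Q2: whole pair dropped
  rp3 <- make_rp(seq150, seq150, qual1 = strrep("#", 150))
  expect_equal(length(quality_trim(rp3, p)), 0)

  # pair-level drop: mate 2 failing removes the pair even if mate 1 passes
  rp4 <- make_rp(seq150, seq150, qual2 = strrep("#", 150))
  expect_equal(length(quality_trim(rp4, p)), 0)

  # sequence/quality length mismatch is rejected at construction
  expect_error(read_pairs("a", "ACGT", "FFF", "ACGT", "FFFF"))
})

test_that("trimming agrees with an independent per-base oracle", {
  # oracle: recompute every window mean directly, then replicate the
  # cut-and-extend rule
  oracle_len <- function(q, w, minq) {
    n <- length(q)
    if (n < w) return(if (mean(q) >= minq) n else 0)
    means <- vapply(1:(n - w + 1), function(i) mean(q[i:(i + w - 1)]),
                    numeric(1))
    bad <- which(means < minq)
    if (!length(bad)) return(n)
    end <- bad[1] - 1
    while (end < n && q[end + 1] >= minq) end <- end + 1
    end
  }
  set.seed(20)
  p <- suppressWarnings(trim_params(window = 4, min_mean_quality = 20,
                                    min_length = 1))
  for (i in 1:25) {
    n <- sample(40:120, 1)
    q <- sample(c(2L, 15L, 25L, 37L), n, replace = TRUE,
                prob = c(0.2, 0.1, 0.2, 0.5))
    qs <- intToUtf8(q + 33L)
    s <- rand_seq(n)
    rp <- make_rp(s, s, qual1 = qs, qual2 = strrep("F", n))
    exp_len <- oracle_len(q, 4, 20)
    out <- suppressWarnings(quality_trim(rp, p))
    if (exp_len >= 1) {
      expect_identical(out$seq1, substr(s, 1, exp_len))
    } else {
      expect_equal(length(out), 0)
    }
  }
})

test_that("prefixed k-mer extraction returns ordered, N-free windows", {
  p3 <- kmer_screen_params(k = 3, prefix = "AG", min_total = 1)
  expect_identical(extract_prefixed_kmers("AGAAGT", p3), c("AGA", "AGT"))

  p35 <- kmer_screen_params()
  expect_identical(extract_prefixed_kmers(rand_seq(34), p35), character(0))
  s35 <- paste0("AG", rand_seq(33))
  expect_identical(extract_prefixed_kmers(s35, p35), s35)

  # N windows are skipped
  expect_identical(extract_prefixed_kmers("AGNAGA", p3), "AGA")

  # brute-force equivalence on random sequences with occasional Ns
  set.seed(30)
  for (i in 1:10) {
    s <- rand_seq(300, alphabet = c("A", "C", "G", "T", "N"))
    expect_identical(extract_prefixed_kmers(s, p3),
                     naive_prefixed_kmers(s, 3, "AG"))
  }
})

test_that("pool counting is multiplicity-aware, symmetric, and oracle-exact", {
  p3 <- kmer_screen_params(k = 3, prefix = "AG", min_total = 1)

  tab <- count_pool_kmers(make_rp("AGAAGA", "TTTTTT"),
                          make_rp(character(0), character(0)), p3)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$kmer, "AGA")
  expect_equal(tab$male_count, 2L)
  expect_equal(tab$female_count, 0L)

  rp <- make_rp(replicate(5, rand_seq(80)), replicate(5, rand_seq(80)))
  sym <- count_pool_kmers(rp, rp, p3)
  expect_identical(sym$male_count, sym$female_count)

  empty <- make_rp(character(0), character(0))
  expect_equal(nrow(count_pool_kmers(empty, empty, p3)), 0)

  # oracle equivalence, including both mates of each pair
  set.seed(31)
  m <- make_rp(replicate(4, rand_seq(60)), replicate(4, rand_seq(60)))
  f <- make_rp(replicate(3, rand_seq(60)), replicate(3, rand_seq(60)))
  got <- as.data.frame(count_pool_kmers(m, f, p3))
  want <- naive_pool_counts(c(m$seq1, m$seq2), c(f$seq1, f$seq2), 3, "AG")
  expect_equal(got, want)
})

test_that("count thresholds and the female-zero rule define the MSK set", {
  p <- kmer_screen_params()  # min 2, max 200
  tab <- data.table::data.table(
    kmer = c("k1", "k2", "k3", "k4"),
    male_count = c(1L, 2L, 201L, 150L),
    female_count = c(0L, 0L, 0L, 1L))
  res <- filter_and_select_msks(tab, p)
  expect_setequal(res$table$kmer, c("k2", "k4"))  # totals 2 and 151
  expect_identical(res$msks, "k2")                # the only female-zero key

  # every MSK satisfies the definitional invariants
  expect_true(all(res$table[res$table$kmer %in% res$msks]$female_count == 0))
  expect_true(all(res$table[res$table$kmer %in% res$msks]$male_count >= 2))
})

test_that("widening the count window never shrinks table or MSK set", {
  set.seed(32)
  tab <- data.table::data.table(
    kmer = sprintf("k%03d", 1:200),
    male_count = as.integer(rpois(200, 30)),
    female_count = as.integer(rpois(200, 30) *
                                rbinom(200, 1, 0.8)))
  narrow <- filter_and_select_msks(tab, kmer_screen_params(min_total = 10,
                                                           max_total = 60))
  wide <- filter_and_select_msks(tab, kmer_screen_params(min_total = 2,
                                                         max_total = 200))
  expect_true(all(narrow$table$kmer %in% wide$table$kmer))
  expect_true(all(narrow$msks %in% wide$msks))
})

test_that("candidate pairs are exactly those carrying an MSK in either mate", {
  p3 <- kmer_screen_params(k = 3, prefix = "AG", min_total = 1)
  rp <- make_rp(c("AGATTT", "TTTTTT", "CCCCCC"),
                c("GGGGGG", "GGGGGG", "CAGACC"))
  kept <- extract_candidate_read_pairs(rp, "AGA", p3)
  expect_identical(kept$id, rp$id[c(1, 3)])  # mate-1 hit and mate-2 hit

  expect_equal(length(extract_candidate_read_pairs(rp, character(0), p3)), 0)
})

test_that("on error-free simulation every MSK is Y-derived and every
           candidate pair overlaps the planted MSR", {
  cfg <- small_run_config(seed = 21, autosome = 12000, x = 3000, y = 2000,
                          coverage = 25)
  genomes <- simulate_genomes(cfg$genome)
  male <- simulate_pool_reads(genomes$male, cfg$reads,
                              dosage = c(y_msr = 0.5), id_prefix = "m")
  female <- simulate_pool_reads(genomes$female, cfg$reads, id_prefix = "f")
  params <- kmer_screen_params()
  screened <- filter_and_select_msks(
    count_pool_kmers(male, female, params), params)
  expect_gt(length(screened$msks), 0)

  y <- as.character(genomes$male[["y_msr"]])
  fem <- paste(as.character(genomes$female), collapse = "N")
  in_y <- vapply(screened$msks, function(k) {
    grepl(k, y, fixed = TRUE) || grepl(rc_chr(k), y, fixed = TRUE)
  }, logical(1))
  in_female <- vapply(screened$msks, function(k) {
    grepl(k, fem, fixed = TRUE) || grepl(rc_chr(k), fem, fixed = TRUE)
  }, logical(1))
  expect_true(all(in_y))
  expect_false(any(in_female))

  cand <- extract_candidate_read_pairs(male, screened$msks, params)
  expect_gt(length(cand), 0)
  expect_true(all(cand$info$source == "y_msr"))
})
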