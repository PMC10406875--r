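p51 <- function() primer_pair("P51", "TCTTCCTCTTGGTGCCCG",
                              "TCAAAGAACCGCTAATCCCAT",
                              annealing_temp = 60, expected_size = 609)
p11 <- function() primer_pair("P11", "TCTCGCCATCTTCAACCATTT",
                              "ATCTTGGCGTATCTCGGCTTT",
                              annealing_temp = 65, expected_size = 304)

test_that("primer sites are found on both strands with the 3' anchor rule", {
  set.seed(70)
  primer <- "ACGGATTACCGTAGGCT"  # 17-mer

  tpl <- paste0(rand_seq(50), primer, rand_seq(50))
  h <- find_primer_sites(tpl, primer)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 51)
  expect_equal(h$strand, "+")

  tpl2 <- paste0(rand_seq(40), rc_chr(primer), rand_seq(40))
  h2 <- find_primer_sites(tpl2, primer)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 41)

  # zero-mismatch mode rejects a single-substitution copy
  mut <- primer
  substr(mut, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                               substr(primer, 8, 8))[1]
  tpl3 <- paste0(rand_seq(30), mut, rand_seq(30))
  expect_equal(nrow(find_primer_sites(tpl3, primer)), 0)
  # ... but a 1-mismatch budget accepts it
  expect_equal(nrow(find_primer_sites(tpl3, primer,
                                      pcr_params(max_mismatches = 1))), 1)

  # a 3'-terminal mismatch is rejected even within the budget
  mut3 <- primer
  substr(mut3, 17, 17) <- setdiff(c("A", "C", "G", "T"),
                                  substr(primer, 17, 17))[1]
  tpl4 <- paste0(rand_seq(30), mut3, rand_seq(30))
  expect_equal(nrow(find_primer_sites(tpl4, primer,
                                      pcr_params(max_mismatches = 1))), 0)
})

test_that("primer-site finding matches the naive window oracle", {
  set.seed(71)
  for (i in 1:10) {
    primer <- rand_seq(16)
    tpl <- paste0(rand_seq(120),
                  if (i %% 2) primer else rc_chr(primer),
                  rand_seq(120))
    for (mm in 0:1) {
      got <- find_primer_sites(tpl, primer, pcr_params(max_mismatches = mm))
      want <- naive_primer_sites(tpl, primer, mm)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) expect_equal(got$start, sort(want$start))
    }
  }
})

test_that("amplicons are predicted exactly between facing primer sites", {
  set.seed(72)
  fwd <- rand_seq(18); rev <- rand_seq(21)
  pair <- primer_pair("T1", fwd, rev)
  params <- pcr_params(min_product_size = 30)

  tpl <- paste0(rand_seq(40), fwd, rand_seq(10), rc_chr(rev), rand_seq(40))
  amp <- predict_amplicons(tpl, pair, params)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 18 + 10 + 21)
  expect_equal(amp$start, 41)
  expect_true(startsWith(amp$sequence, fwd))
  expect_true(endsWith(amp$sequence, rc_chr(rev)))

  # no reverse site -> no product
  expect_equal(nrow(predict_amplicons(paste0(rand_seq(30), fwd,
                                             rand_seq(60)),
                                      pair, params)), 0)
  # product outside the size window is dropped
  expect_equal(nrow(predict_amplicons(tpl, pair,
                                      pcr_params(min_product_size = 100))),
               0)
})

test_that("amplicon prediction is strand-symmetric and mismatch-monotone", {
  set.seed(73)
  fwd <- rand_seq(18); rev <- rand_seq(20)
  pair <- primer_pair("T2", fwd, rev)
  params <- pcr_params(min_product_size = 30)
  tpl <- paste0(rand_seq(35), fwd, rand_seq(25), rc_chr(rev), rand_seq(55))

  a <- predict_amplicons(tpl, pair, params)
  b <- predict_amplicons(rc_chr(tpl), pair, params)
  expect_equal(a$length, b$length)
  # products are reported forward-primer-first, so the same molecule is
  # returned from either template orientation (i.e. the mirrored genomic
  # segment, reverse-complemented), at mirrored coordinates
  expect_equal(sort(a$sequence), sort(b$sequence))
  expect_equal(b$start, nchar(tpl) - a$end + 1)
  expect_equal(b$end, nchar(tpl) - a$start + 1)
  expect_true(all(b$strand != a$strand))

  # allowing mismatches can only add predictions
  mut <- tpl
  substr(mut, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(tpl, 40, 40))[1]
  n0 <- nrow(predict_amplicons(mut, pair, params))
  n1 <- nrow(predict_amplicons(mut, pair,
                               pcr_params(max_mismatches = 1,
                                          min_product_size = 30)))
  expect_gte(n1, n0)
})

test_that("published primer pairs produce their printed product sizes on
           synthetic marker templates", {
  t51 <- synthetic_marker_template(p51(), seed = 101)
  a51 <- predict_amplicons(t51, p51())
  expect_equal(nrow(a51), 1)
  expect_equal(a51$length, 609)

  t11 <- synthetic_marker_template(p11(), seed = 102)
  a11 <- predict_amplicons(t11, p11())
  expect_equal(nrow(a11), 1)
  expect_equal(a11$length, 304)

  # the packaged primer table carries the same sequences and metadata
  pairs <- arguta_sex_primers()
  expect_identical(pairs$P51$forward, p51()$forward)
  expect_identical(pairs$P11$reverse, p11()$reverse)
  expect_equal(pairs$P51$expected_size, 609L)
  expect_equal(pairs$P11$expected_size, 304L)
})

test_that("dominant sex calls follow amplicon presence", {
  set.seed(74)
  pair <- p51()
  marker <- synthetic_marker_template(pair, seed = 103)
  bg <- rand_seq(600)

  carrier <- Biostrings::DNAStringSet(c(bg = bg, marker = marker))
  expect_equal(call_sex(carrier, pair)$predicted_sex, "male")

  noncarrier <- Biostrings::DNAStringSet(c(bg = bg))
  expect_equal(call_sex(noncarrier, pair)$predicted_sex, "female")

  # deleting the reverse-primer site models marker dropout -> female call
  dropped <- sub(rc_chr(pair$reverse), "", marker, fixed = TRUE)
  expect_equal(call_sex(Biostrings::DNAStringSet(c(m = dropped)),
                        pair)$predicted_sex, "female")

  expect_error(call_sex(Biostrings::DNAStringSet(), pair), "empty")
})

test_that("panel scoring reproduces published accuracy rates from counts", {
  counts <- arguta_panel_counts()
  r51 <- score_contingency_counts(counts[counts$marker == "P51", ])
  expect_equal(r51$accuracy_rate, 96.88)
  expect_equal(r51$n, 128)

  r11 <- score_contingency_counts(counts[counts$marker == "P11", ])
  expect_equal(r11$accuracy_rate, 96.09)
  expect_equal(r11$n, 128)

  # contingency output mirrors the input counts
  c51 <- r51$contingency
  expect_equal(c51$presence[c51$sex == "male" & c51$subpopulation == "F1"],
               45L)
  expect_equal(c51$absence[c51$sex == "female" & c51$subpopulation == "wild"],
               12L)
})

test_that("accuracy equals a brute-force recount and rounds half-up", {
  set.seed(75)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    truth <- data.frame(
      individual_id = sprintf("i%03d", 1:n),
      sex = sample(c("male", "female"), n, replace = TRUE),
      subpopulation = sample(c("F1", "wild"), n, replace = TRUE))
    calls <- data.frame(
      individual_id = truth$individual_id,
      call = sample(c("presence", "absence"), n, replace = TRUE))
    res <- score_panel(calls, truth)
    correct <- sum((truth$sex == "male" & calls$call == "presence") |
                     (truth$sex == "female" & calls$call == "absence"))
    expect_equal(res$accuracy_rate, floor(10000 * correct / n + 0.5) / 100)
    expect_equal(sum(res$contingency$presence) +
                   sum(res$contingency$absence), n)
  }

  # all-correct panel prints 100.00
  truth <- data.frame(individual_id = c("a", "b"),
                      sex = c("male", "female"))
  calls <- data.frame(individual_id = c("a", "b"),
                      call = c("presence", "absence"))
  expect_equal(score_panel(calls, truth)$accuracy_rate, 100)

  # orphan ids are reported
  expect_error(score_panel(data.frame(individual_id = "x",
                                      call = "presence"), truth),
               "orphans.*x")
})

test_that("a simulated noisy panel is scored consistently with its truth", {
  pair <- p11()
  marker <- synthetic_marker_template(pair, seed = 104)
  set.seed(76)
  bg <- rand_seq(500)
  panel <- simulate_panel(marker, bg,
                          panel_spec(30, 30, male_dropout = 0.1,
                                     female_leakage = 0.05, seed = 77))
  calls <- genotype_panel(panel$templates, pair)
  res <- score_panel(calls, panel$truth)
  # the in-silico call must equal the planted carrier status exactly
  expect_identical(calls$call == "presence",
                   panel$truth$carries_marker[
                     match(calls$individual_id, panel$truth$individual_id)])
  # hence accuracy = fraction of individuals whose carrier status matches sex
  agree <- with(panel$truth, (sex == "male") == carries_marker)
  expect_equal(res$accuracy_rate, floor(10000 * mean(agree) + 0.5) / 100)
})
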