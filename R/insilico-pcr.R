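#' PCR primer pair for a dominant sex marker
#'
#' Holds the primer sequences (both written 5'→3') plus metadata. The
#' annealing temperature is carried as metadata only and never enters the
#' matching — in-silico specificity is governed by [pcr_params].
#'
#' @param name Marker name, e.g. `"P51"`.
#' @param forward,reverse Primer sequences 5'→3', A/C/G/T, length >= 15.
#' @param annealing_temp Annealing temperature in degrees C (metadata).
#' @param expected_size Expected product size in bases (metadata).
#' @param marker_type Marker scoring model; only `"dominant"`
#'   (presence/absence) is implemented.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, annealing_temp = NA_real_,
                        expected_size = NA_integer_,
                        marker_type = "dominant") {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15) stop_sexmark("primers must be at least 15 bases")
    if (grepl("[^ACGT]", p)) stop_sexmark("primers must be over A/C/G/T")
  }
  marker_type <- match.arg(marker_type, "dominant")
  structure(list(name = name, forward = forward, reverse = reverse,
                 annealing_temp = annealing_temp,
                 expected_size = expected_size, marker_type = marker_type),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair %s: F 5'-%s-3', R 5'-%s-3' (%s)\n",
              x$name, x$forward, x$reverse, x$marker_type))
  invisible(x)
}

#' In-silico PCR stringency parameters
#'
#' @param max_mismatches Substitutions tolerated per primer site
#'   (default 0); the primer's 3'-terminal base must always match exactly,
#'   since a 3' mismatch abolishes polymerase extension.
#' @param min_product_size,max_product_size Product length window in bases
#'   (defaults 50 and 5000).
#' @return An object of class `pcr_params`.
#' @export
pcr_params <- function(max_mismatches = 0, min_product_size = 50,
                       max_product_size = 5000) {
  max_mismatches <- check_count(max_mismatches, "max_mismatches")
  if (min_product_size >= max_product_size)
    stop_sexmark("min_product_size must be below max_product_size")
  structure(list(max_mismatches = max_mismatches,
                 min_product_size = min_product_size,
                 max_product_size = max_product_size),
            class = "pcr_params")
}

#' Find primer binding sites on a template
#'
#' Reports every position where the primer binds the plus strand (the
#' primer itself matches the template) or the minus strand (the reverse
#' complement of the primer matches), with at most `max_mismatches`
#' substitutions. The 3'-terminal base of the primer must match exactly
#' regardless of the mismatch budget.
#'
#' @param template A character string or [Biostrings::DNAString].
#' @param primer Primer sequence 5'→3'.
#' @param params A [pcr_params].
#' @return A data.frame with one row per site: `start`, `end` (1-based,
#'   inclusive, on the template's plus strand), `strand`, `mismatches`.
#' @export
find_primer_sites <- function(template, primer, params = pcr_params()) {
  if (is.character(template)) template <- Biostrings::DNAString(toupper(template))
  primer <- toupper(primer)
  plen <- nchar(primer)
  site_scan <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, template,
                                  max.mismatch = params$max_mismatches)
    if (length(m) == 0L)
      return(data.frame(start = integer(0), end = integer(0),
                        strand = character(0), mismatches = integer(0)))
    starts <- IRanges::start(m)
    hits <- as.character(m)
    # 3' anchor: primer's last base is the window's last base on the plus
    # strand, but the window's first base when bound on the minus strand.
    anchor_pos <- if (strand == "+") plen else 1L
    anchor_base <- substr(pattern, anchor_pos, anchor_pos)
    ok <- substr(hits, anchor_pos, anchor_pos) == anchor_base
    mm <- mapply(function(h, p) sum(utf8ToInt(h) != utf8ToInt(p)),
                 hits, MoreArgs = list(p = pattern), USE.NAMES = FALSE)
    data.frame(start = starts[ok], end = starts[ok] + plen - 1L,
               strand = rep(strand, sum(ok)),
               mismatches = as.integer(mm[ok]))
  }
  out <- rbind(site_scan(primer, "+"), site_scan(revcomp(primer), "-"))
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' An amplicon is produced by a forward-primer site and a reverse-primer
#' site binding opposite strands and facing each other, with a product
#' length inside the [pcr_params] window. Both layouts are searched: the
#' forward primer on the plus strand with the reverse primer downstream on
#' the minus strand, and the mirror layout (in which case the product
#' sequence is reported reverse-complemented, so it always begins with the
#' forward primer and ends with the reverse complement of the reverse
#' primer).
#'
#' @param template A character string or [Biostrings::DNAString]; a name
#'   for reporting can be given via `template_id`.
#' @param pair A [primer_pair].
#' @param params A [pcr_params].
#' @param template_id Template name used in the report.
#' @return A data.frame sorted by `start`: `template_id`, `primer_name`,
#'   `start`, `end` (1-based inclusive template coordinates), `length`,
#'   `strand` (`"+"` if the forward primer sits on the plus strand),
#'   `sequence`.
#' @export
predict_amplicons <- function(template, pair, params = pcr_params(),
                              template_id = "template") {
  stopifnot(inherits(pair, "primer_pair"))
  if (is.character(template)) template <- Biostrings::DNAString(toupper(template))
  fwd <- find_primer_sites(template, pair$forward, params)
  rev <- find_primer_sites(template, pair$reverse, params)

  products <- function(left, right, strand) {
    # left: sites whose 5' end opens the product (plus-strand binding);
    # right: sites on the minus strand closing it.
    if (nrow(left) == 0L || nrow(right) == 0L) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
    start <- left$start[grid$i]
    end <- right$end[grid$j]
    len <- end - start + 1L
    ok <- left$start[grid$i] <= right$start[grid$j] &
      len >= params$min_product_size & len <= params$max_product_size
    if (!any(ok)) return(NULL)
    data.frame(start = start[ok], end = end[ok], length = len[ok],
               strand = strand)
  }
  out <- rbind(
    products(fwd[fwd$strand == "+", ], rev[rev$strand == "-", ], "+"),
    products(rev[rev$strand == "+", ], fwd[fwd$strand == "-", ], "-")
  )
  if (is.null(out))
    return(data.frame(template_id = character(0), primer_name = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), strand = character(0),
                      sequence = character(0)))
  seqs <- as.character(Biostrings::extractAt(
    template, IRanges::IRanges(out$start, out$end)))
  seqs[out$strand == "-"] <- revcomp(seqs[out$strand == "-"])
  out <- data.frame(template_id = template_id, primer_name = pair$name,
                    start = out$start, end = out$end, length = out$length,
                    strand = out$strand, sequence = seqs)
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Dominant-marker sex call for one individual
#'
#' Runs [predict_amplicons()] over every template of the individual;
#' presence of at least one product anywhere is called `male`, absence
#' `female` — dominant-marker semantics, in which amplification failure and
#' true absence are indistinguishable.
#'
#' @param templates A [Biostrings::DNAStringSet] (or character vector) of
#'   the individual's template sequences.
#' @param pair A [primer_pair].
#' @param params A [pcr_params].
#' @return A list: `call` (`"presence"` / `"absence"`), `predicted_sex`
#'   (`"male"` / `"female"`), `n_amplicons`.
#' @export
call_sex <- function(templates, pair, params = pcr_params()) {
  if (length(templates) == 0L) stop_sexmark("template set is empty")
  seqs <- as.character(templates)
  n_amp <- 0L
  for (s in seqs) {
    n_amp <- n_amp + nrow(predict_amplicons(s, pair, params))
    if (n_amp > 0L) break
  }
  list(call = if (n_amp > 0L) "presence" else "absence",
       predicted_sex = if (n_amp > 0L) "male" else "female",
       n_amplicons = n_amp)
}

#' Genotype a whole validation panel
#'
#' Applies [call_sex()] to every individual of a simulated or loaded
#' panel.
#'
#' @param templates Named list of per-individual template
#'   [Biostrings::DNAStringSet]s (e.g. `simulate_panel()$templates`).
#' @param pair A [primer_pair].
#' @param params A [pcr_params].
#' @return A data.frame: `individual_id`, `call`, `predicted_sex`.
#' @export
genotype_panel <- function(templates, pair, params = pcr_params()) {
  calls <- lapply(templates, call_sex, pair = pair, params = params)
  data.frame(individual_id = names(templates),
             call = vapply(calls, `[[`, character(1), "call"),
             predicted_sex = vapply(calls, `[[`, character(1),
                                    "predicted_sex"),
             row.names = NULL)
}

#' Score a genotyped panel against known sexes
#'
#' Builds the presence/absence-by-sex contingency table (per subpopulation
#' and overall) and the accuracy rate of the dominant marker: the percent
#' of individuals where a male shows presence or a female shows absence,
#' rounded half-up to two decimals.
#'
#' @param calls Data.frame with `individual_id` and `call`
#'   (`"presence"`/`"absence"`), as from [genotype_panel()].
#' @param truth Data.frame with `individual_id`, `sex` (`"male"`/
#'   `"female"`) and optionally `subpopulation`.
#' @return An object of class `panel_result`: list with `rows` (per
#'   individual), `contingency` (counts per sex x subpopulation), and
#'   `accuracy_rate` (percent, 2 decimals).
#' @export
score_panel <- function(calls, truth) {
  for (col in c("individual_id", "call")) if (!col %in% names(calls))
    stop_sexmark(sprintf("calls lacks column '%s'", col))
  for (col in c("individual_id", "sex")) if (!col %in% names(truth))
    stop_sexmark(sprintf("truth lacks column '%s'", col))
  orphans_c <- setdiff(calls$individual_id, truth$individual_id)
  orphans_t <- setdiff(truth$individual_id, calls$individual_id)
  if (length(orphans_c) || length(orphans_t))
    stop_sexmark("calls/truth id mismatch; orphans: ",
                 paste(c(orphans_c, orphans_t), collapse = ", "))
  if (!"subpopulation" %in% names(truth)) truth$subpopulation <- "all"

  rows <- merge(truth[, c("individual_id", "sex", "subpopulation")],
                calls[, c("individual_id", "call")], by = "individual_id")
  rows$predicted_sex <- ifelse(rows$call == "presence", "male", "female")
  correct <- (rows$sex == "male" & rows$call == "presence") |
    (rows$sex == "female" & rows$call == "absence")
  acc <- round_half_up(100 * sum(correct) / nrow(rows), 2)

  cont <- as.data.frame(
    data.table(sex = rows$sex, subpopulation = rows$subpopulation,
               call = rows$call)[, .N, by = .(sex, subpopulation, call)])
  cont <- as.data.frame(dcast(as.data.table(cont),
                              sex + subpopulation ~ call,
                              value.var = "N", fill = 0L))
  for (col in c("presence", "absence"))
    if (!col %in% names(cont)) cont[[col]] <- 0L
  cont <- cont[order(cont$sex, cont$subpopulation),
               c("sex", "subpopulation", "presence", "absence")]
  rownames(cont) <- NULL

  structure(list(rows = rows, contingency = cont,
                 accuracy_rate = acc, n = nrow(rows)),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("panel_result: %d individuals, accuracy rate %.2f%%\n",
              x$n, x$accuracy_rate))
  print(x$contingency)
  invisible(x)
}

#' Build a panel scoring from published-style contingency counts
#'
#' Expands per-group presence/absence counts into per-individual rows and
#' scores them with [score_panel()] — the route by which a printed
#' contingency table is re-scored by the same code path as a simulated
#' panel.
#'
#' @param counts Data.frame with columns `sex`, `subpopulation`,
#'   `presence`, `absence` (counts of individuals).
#' @return A `panel_result`.
#' @export
score_contingency_counts <- function(counts) {
  need <- c("sex", "subpopulation", "presence", "absence")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop_sexmark("counts lacks column(s): ", paste(missing, collapse = ", "))
  rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$presence + r$absence
    if (n == 0) return(NULL)
    data.frame(sex = r$sex, subpopulation = r$subpopulation,
               call = rep(c("presence", "absence"), c(r$presence, r$absence)))
  }))
  rows$individual_id <- sprintf("ind_%04d", seq_len(nrow(rows)))
  score_panel(rows[, c("individual_id", "call")],
              rows[, c("individual_id", "sex", "subpopulation")])
}

#' Read a primer table
#'
#' Tab-separated with header columns `name`, `forward`, `reverse` and
#' optionally `annealing_temp`, `expected_size`.
#'
#' @param path TSV path.
#' @return A list of [primer_pair] objects, named by marker.
#' @export
read_primers_tsv <- function(path) {
  df <- read_tsv(path, required = c("name", "forward", "reverse"))
  pairs <- lapply(seq_len(nrow(df)), function(i) {
    primer_pair(df$name[i], df$forward[i], df$reverse[i],
                annealing_temp = if ("annealing_temp" %in% names(df))
                  df$annealing_temp[i] else NA_real_,
                expected_size = if ("expected_size" %in% names(df))
                  as.integer(df$expected_size[i]) else NA_integer_)
  })
  setNames(pairs, df$name)
}
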