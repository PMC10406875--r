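---
title: "Pooled k-mer discovery of male-specific sequences and dominant sex markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled k-mer discovery of male-specific sequences and dominant sex markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexmark)
```

## The problem

In dioecious plants with an XX/XY sex-determination system, males carry a
hemizygous Y-restricted segment — a male-specific region (MSR) — absent
from every female genome. Because sex often cannot be scored until
flowering, which can take years in woody perennials such as kiwiberry
(*Actinidia arguta*), a PCR marker anchored in the MSR lets breeders sex
seedlings at the cotyledon stage. `sexmark` implements the computational
side of a bulked-segregant strategy for finding such markers: sequence one
pooled male library and one pooled female library, find sequence present
only in the male pool, assemble it, confirm it by mapping both pools back,
and validate candidate PCR markers on sexed panels. A seeded simulator
generates genomes, pools and panels with the statistical structure the
method assumes, so the whole pipeline is testable with no external data.

## The screen

Let $c_m(w)$ and $c_f(w)$ be the occurrence counts of a k-mer $w$ across
all mates of the male and female pools, counted *as sequenced* (no
reverse-complement collapsing). The screen retains

$$ \mathcal{K} = \{\, w : w_{1..2} = \mathrm{AG},\;
   2 \le c_m(w) + c_f(w) \le 200 \,\} $$

and defines the pure male-specific k-mers (MSKs) as

$$ \mathrm{MSK} = \{\, w \in \mathcal{K} : c_f(w) = 0 \,\}. $$

The defaults are $k = 35$ and the `AG` prefix; the prefix restriction
keeps an expected 1/16 of all k-mers, which cuts memory and time without
biasing *which loci* are detectable, because every ~16 bp of a Y-specific
locus contributes some AG-prefixed window on one strand or the other. The
lower total-count bound removes singleton k-mers (almost always sequencing
errors at realistic depths); the upper bound removes high-copy repeats,
which cannot yield locus-specific markers. Counting is deliberately
stranded: the prefix trick is orientation-specific, and canonicalising
would collapse `AG`-prefixed keys onto non-`AG` partners.

Read pairs in which at least one mate contains at least one MSK are
extracted as candidates. Upstream of the screen, reads are quality-trimmed
with a 3' sliding window (width 4, mean Phred >= 20, minimum surviving
length 50, pair-level drop). The trimmer scans 5'→3', cuts at the first
failing window, then extends base-by-base while individual base qualities
still pass — so a single low-quality base inside an otherwise good window
does not truncate the read. These trimming parameters are conventional
defaults; they are fully parameterised because the upstream protocol they
stand in for is not standardised.

## Assembly

Candidate pairs are assembled by a minimal de Bruijn unitig assembler:
nodes are canonical 31-mers (lexicographic minimum of a k-mer and its
reverse complement — assembly *must* merge strands, unlike the screen)
with multiplicities; nodes below `min_kmer_count = 2` are dropped; unitigs
are maximal non-branching paths in the bidirected graph. An edge is
absorbed into a unitig only when it is the unique extension of its source
side *and* the unique entry of its target side. Determinism is part of the
contract: each unitig is reported in its lexicographically smaller
orientation, output is sorted by decreasing length then sequence, and
isolated cycles are broken at their smallest node. Optional tip clipping
removes dead-end unitigs shorter than `2 * graph_k` whose every node was
seen once; with the default count floor of 2 it is a no-op. There is no
bubble popping, no scaffolding over mate gaps and no repeat resolution —
candidate regions are small and simplicity plus determinism are worth more
here than contiguity. Externally assembled FASTA can be substituted for
this stage.

## Classification by pooled map-back

Both original pools are mapped back to the scaffolds with **zero
mismatches** (a read hits wherever it, or its reverse complement, is an
exact substring of a scaffold; multi-mapping reads count toward every
scaffold they hit, which is conservative for the female-zero rule). Per
scaffold and pool the package reports the mapped-read count and the mean
per-base depth (sum of mapped read lengths / scaffold length). Labels:

* `MALE_SPECIFIC` — male reads map, zero female reads map;
* `RESCUED_MALE_SPECIFIC` — some female depth, but male mean depth is at
  least twice the female mean depth (`rescue_ratio = 2`, inclusive `>=`);
* `PENDING` — everything else.

The inclusive boundary reads the 2× rescue as a threshold; it is
configurable, as is the choice of mean depth (rather than read count) as
the rescue metric — both counts and depths are always reported so the
decision is auditable. Candidates are the male-linked scaffolds at least
`min_candidate_length = 100` bases long, a simple length filter standing
in for gene-level screening of candidates.

## In-silico PCR and panel scoring

A primer site is a window matching the primer (or its reverse complement,
for minus-strand binding) with at most `max_mismatches` substitutions
(default 0) — except the primer's 3'-terminal base, which must always
match, since a 3' mismatch abolishes extension. An amplicon joins a
plus-strand forward site to a downstream minus-strand reverse site (and
the mirror layout, reported reverse-complemented so products always read
forward-primer-first), with product length in `[50, 5000]` by default.
Coordinates are 1-based inclusive throughout the R interface. Annealing
temperature is carried as marker metadata only; empirical
temperature-dependent specificity is not modelled, and the simulator's
`female_leakage` parameter stands in for imperfect female paralogs without
claiming a mechanism.

Markers are dominant: for an individual, presence of any product calls
male, absence calls female — amplification failure and true absence are
indistinguishable, which is exactly the marker's real failure mode and the
reason validation panels matter. Panel accuracy is
$100 \times (\text{males with presence} + \text{females with absence}) /
\text{total}$, rounded half-up to two decimals (so 124/128 prints 96.88
and 123/128 prints 96.09). `score_contingency_counts()` routes published
per-group counts through the same per-individual scorer used for
simulated panels.

## What the simulator emulates — and what it does not

`simulate_genomes()` builds a female genome {autosome, X region} and a
male genome that adds an independent random Y-MSR (uniform i.i.d. A/C/G/T,
no Ns by default). Independence makes the screen's core property provable:
for regions of kilobase scale, no 35-mer of the Y-MSR occurs in the female
genome. Setting `divergence_xy < 1` instead derives the Y-MSR from the X
as a gametolog with that fraction of substituted sites.
`simulate_pool_reads()` draws fragments of Normal(400, 40) length
(truncated below at the read length — a standard Illumina insert model,
chosen once), uniform positions, both strands equally, 150 bp paired ends,
i.i.d. substitution errors, constant Q37 qualities (optionally degraded at
the 3' end to exercise trimming). The hemizygous Y-MSR is sampled at
dosage 0.5 in the male pool — half the autosomal copy number — which is
what makes depth-based classification meaningful. Default pool coverage is
30×, a typical resequencing depth for this design; the real study's
per-pool depth is not fixed by the protocol. Panels
(`simulate_panel()`) give every individual a background template and give
the marker template to males with probability `1 - male_dropout` and
females with probability `female_leakage`.

Not modelled: indels and structural variants, diploid heterozygosity
within pools, repeats and low-complexity sequence, instrument-calibrated
error/quality profiles, polyploidy. Passing tests on this simulator
therefore demonstrate the pipeline's logic and its behaviour under
idealised sampling noise — not robustness to repeat-rich genomes or real
error profiles.

## Numerical and design choices

* Seeds: every stochastic stage takes an explicit seed; the pipeline fans
  one global seed out to stages via a fixed string-hash derivation, so any
  stage can be rerun alone and reproduce its slice of a full run.
  Identical configurations give byte-identical outputs.
* K-mers containing `N` are skipped everywhere (not genomic sequence).
* Counting is occurrence-level, not per-read presence: a k-mer occurring
  twice in one read counts twice.
* `graph_k` must be odd, which excludes reverse-complement-palindromic
  nodes and keeps the bidirected graph well-defined.
* Unitig tie-breaks (orientation, ordering, cycle entry) are all
  lexicographic, making assembly output a pure function of the read
  multiset.
* Accuracy rounding is half *up*, not banker's rounding.
* Degenerate inputs: empty pools give empty tables; an empty MSK set gives
  zero candidates; scaffold sets classify to an empty report rather than
  erroring mid-pipeline.

## Known limitations

Two limitations follow from the method's own definitions and surface in
the package's 20-seed property checks at 30× coverage:

1. **Stranded counting admits rare false MSKs.** Because counting is
   orientation-specific, a given k-mer key sees only the mates sequenced
   in its orientation — about half the pool depth. A female-genome
   AG-window therefore has a small but non-negligible probability
   (~1e-5 at 30×, amplified by local coverage dips that affect several
   overlapping windows at once) of a zero female count, becoming an MSK
   despite being autosomal. Roughly half of simulated runs at these
   conditions contain at least one such k-mer.
2. **Read-length scaffolds can evade the female-zero check.** A read maps
   only where it is *fully contained*, so a false scaffold about one read
   length long (assembled from the reads carrying a false MSK) can show
   male hits — the very reads that built it — and no female hits, and be
   labelled `MALE_SPECIFIC`. The map-back rescue logic assumes scaffolds
   much longer than a read.

Both effects shrink with depth and with a higher candidate length floor,
and both are exactly why this marker-discovery design validates candidates
by PCR on sexed panels rather than trusting the sequence screen alone: in
the original application, only two of nine primer pairs designed from
male-specific scaffolds proved sex-linked.

## Problem sizes used by the test suite

The packaged checks run the full pipeline on simulated genomes of 100 kb
autosome + 20 kb X + 10 kb Y-MSR at 30× per pool (20 seeds for the
recovery properties), with smaller 8–25 kb genomes for stage-level tests;
oracle-equivalence checks compare the indexed k-mer counter, exact mapper
and primer-site finder against naive full scans on dozens of randomized
instances. These sizes were chosen so every property that matters —
seeded determinism, screen soundness, MSR recovery, classification rules,
panel scoring — is exercised end to end in minutes on a laptop.
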