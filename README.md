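# sexmark

Discovery and validation of male-specific PCR markers for dioecious
(XX/XY) plants from pooled whole-genome resequencing — the bulked
segregant design used to develop the P51/P11 sex markers in kiwiberry
(*Actinidia arguta*), implemented as a tested, reusable R pipeline with a
built-in simulator so every stage runs without external data.

In an XX/XY species, males carry a hemizygous Y male-specific region (MSR)
absent from all female genomes. Sequencing one male pool and one female
pool, `sexmark`:

1. **screens k-mers** — counts 35-mers starting with `AG` per pool, as
   sequenced (the prefix keeps ~1/16 of k-mers with no loss of detectable
   loci), retains those with total count `2 ≤ c_m + c_f ≤ 200`, and calls
   *pure male-specific k-mers* (MSKs) those with `c_f = 0`;
2. **extracts and assembles** read pairs carrying an MSK into unitigs with
   a minimal deterministic de Bruijn assembler (canonical 31-mers,
   maximal non-branching paths);
3. **classifies scaffolds** by zero-mismatch map-back of both pools:
   `MALE_SPECIFIC` (female depth exactly zero), `RESCUED_MALE_SPECIFIC`
   (male mean depth ≥ 2× female), `PENDING` otherwise;
4. **validates markers in silico** — predicts PCR amplicons (exact primer
   sites, mandatory 3'-terminal match), makes dominant presence/absence
   sex calls on validation panels, and scores Table-style contingency
   counts into an accuracy rate,
   `100 × (males presence + females absence) / n`.

The simulator generates seeded dioecious genome pairs, pooled 150 bp
paired-end reads at configurable coverage/error with the Y-MSR at half
autosomal dosage, and sexed validation panels with configurable marker
dropout and leakage.

## Worked example

```r
library(sexmark)

cfg <- run_config(
  genome = genome_model(autosome_length = 50000, x_region_length = 10000,
                        y_msr_length = 5000, seed = 7),
  reads  = read_sim_config(coverage = 30, error_rate = 0, seed = 7),
  seed   = 7)
res <- run_pipeline(cfg)
#> [simulate] genomes: autosome 50000 bp, X 10000 bp, Y-MSR 5000 bp
#> [simulate] reads: 6250 male pairs, 6000 female pairs
#> [trim] kept 6250/6250 male, 6000/6000 female pairs
#> [screen] 7963 prefixed k-mers, 7934 retained, 603 MSKs
#> [screen] 249 candidate read pairs
#> [assemble] 3 scaffolds, 5265 bp
#> [classify] 3 MALE_SPECIFIC, 0 RESCUED, 0 PENDING; 3 candidates
res$report
#>   scaffold_id length male_mapped_reads female_mapped_reads male_mean_depth
#> 1  scaffold_1   4965               490                   0        14.80363
#> 2  scaffold_2    150                 1                   0         1.00000
#> 3  scaffold_3    150                 1                   0         1.00000
#>   female_mean_depth         label
#> 1                 0 MALE_SPECIFIC
#> 2                 0 MALE_SPECIFIC
#> 3                 0 MALE_SPECIFIC
```

`scaffold_1` recovers the planted 5 kb Y-MSR at ~15× male depth (half of
30×: the Y is hemizygous) and zero female depth. The two 150 bp scaffolds
illustrate a real limitation of the design — a scaffold about one read
length long can show zero female hits simply because no 150 bp female
read fits inside it; see the vignette's *Known limitations*.

Scoring the published P51 validation panel (97 F1 hybrids + 31 wild
accessions) from its per-group presence/absence counts:

```r
counts <- arguta_panel_counts()
score_contingency_counts(counts[counts$marker == "P51", ])
#> panel_result: 128 individuals, accuracy rate 96.88%
#>      sex subpopulation presence absence
#> 1 female            F1        2      50
#> 2 female          wild        1      12
#> 3   male            F1       45       0
#> 4   male          wild       17       1
```

In-silico PCR of the published P51 primer pair on a synthetic template
built to the marker's product size:

```r
pairs <- arguta_sex_primers()
predict_amplicons(synthetic_marker_template(pairs$P51, seed = 1), pairs$P51)
#>   primer_name start end length strand
#> 1         P51   201 809    609      +
```

The P11 pair analogously yields its 304 bp product.

## Command line

A thin CLI over the same functions ships at `inst/cli/sexmark.R`:

```sh
Rscript inst/cli/sexmark.R run --config run.yaml --seed 1 --out outdir
Rscript inst/cli/sexmark.R pcr --primers primers.tsv --templates panel_dir \
    --truth truth.tsv --out outdir
```

Subcommands `simulate`, `screen`, `assemble`, `classify` and `pcr` run the
stages standalone; `--external-assembly` substitutes an external FASTA for
the built-in assembler.

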