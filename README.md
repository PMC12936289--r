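# mspkit

Mutation-guided selection of mutated surface proteins (MSPs) as antibody
targets.

Tumors carry somatic missense mutations that are overwhelmingly private to
each patient. When the mutated residue sits in an extracellular domain of a
membrane protein, or anywhere on the mature chain of a secreted protein, it
is accessible to antibodies — a *mutated surface protein*. Personalized
oligoclonal antibody cocktails are built by selecting ~10 such MSPs per
tumor, synthesizing a short mutant peptide for each (with a C-terminal
cysteine for carrier conjugation), and raising one antibody per peptide.

`mspkit` implements the computational pipeline for this workflow, aimed at
bioinformaticians working with TCGA-style somatic variant tables:

* **variant IO** — read MAF-dialect TSVs, normalize variant classifications,
  parse HGVS `p.` protein changes (1- or 3-letter), log every rejection
  with a machine-readable reason;
* **annotation store** — a deterministic, validated JSON store of per-gene
  protein records (sequence, topology intervals, location labels),
  emulating curated UniProt annotation;
* **MSP classifier** — residue-level localization by interval lookup with
  a documented overlap precedence, and the MSP call

  `is_msp = (L(p) == extracellular) OR (secreted AND L(p) not in {signal_peptide, out_of_bounds})`

  plus protein-level compartment tallies;
* **peptide design** — mutant/wild-type 14-mer windows (length and
  placement are parameters), single-substitution validation (Hamming
  distance exactly 1), deterministic n-gene panel selection, FASTA export;
* **cohort statistics** — per-patient burden five-number summaries
  (type-7 quartiles), threshold prevalence (fraction of patients with
  ≥ n MSPs), the inter-patient sharing spectrum with its conservation
  identities, and the caliper tumor-volume formula `V = w²·l/2`;
* **synthetic data** — a proteome + cohort generator with recorded ground
  truth (heavy-tailed burdens, constructed sharing plans) so every stage
  is testable offline.

## Worked example

```r
library(mspkit)

prot   <- make_proteome(proteome_spec(seed = 42))          # 60 annotated proteins
cohort <- make_cohort(cohort_spec(n_patients = 100, seed = 42), prot)

maf_path <- tempfile(fileext = ".maf.tsv")
write.table(cohort$maf, maf_path, sep = "\t", quote = FALSE, row.names = FALSE)

res  <- read_maf(maf_path)                 # 34,745 accepted, 0 rejected
cls  <- classify_cohort(res$variants, prot$store)
summ <- patient_summaries(cls$calls)
summarize_cohort(summ)
#> cohort of 100 patient(s)
#>   missense  median 81.5 (Q1 51.75, Q3 118.25, IQR 66.5; min 12, max 8550)
#>   msp       median 25.5 (Q1 15, Q3 37, IQR 22; min 2, max 2705)
fraction_at_least(summ, 10, "msp")
#> [1] 0.92
```

The burden summary is read like any cohort report: the median patient in
this synthetic cohort carries 81.5 missense mutations, of which a median
25.5 are MSPs, and 92% of patients carry at least 10 MSPs — enough to
design a 10-target panel for nearly everyone. The long right tail (max
8,550) comes from the generator's deterministic hypermutator subset.

```r
panel <- select_panel(cls$calls[cls$calls$is_msp, ], prot$store, n = 10)
head(panel$targets[, c("gene_symbol", "protein_change", "mutant_seq", "synthesis_seq")], 3)
#>   gene_symbol protein_change     mutant_seq   synthesis_seq
#> 1     SYNG003          p.M2R RRWLCFWMVYMLFP RRWLCFWMVYMLFPC
#> 2     SYNG005          p.N1H HQRNNKCITARGFF HQRNNKCITARGFFC
#> 3     SYNG007          p.G1H HQWQHEYFVFDLTY HQWQHEYFVFDLTYC

sharing_spectrum(cls$calls[cls$calls$is_msp, ])
#> sharing spectrum: 10740 unique key(s), 10740 patient-key occurrence(s)
#>   shared by exactly 1 patient(s): 10740 key(s)
```

Each panel row is one target: the mutant 14-mer and its synthesis sequence
(mutant + C-terminal cysteine conjugation tag). With no sharing plan
injected, every one of the 10,740 unique MSP keys is private to a single
patient — the situation that motivates per-patient panels in the first
place. `export_panel_fasta(panel, "panel.fasta")` writes mutant/wild-type
FASTA pairs for synthesis ordering.

The ten published immunogen pairs ship as a golden fixture:

```r
pairs <- read_pair_table(system.file("extdata", "immunogen_pairs.tsv", package = "mspkit"))
validate_pair(pairs$wildtype[2], pairs$mutant[2])  # Cntnap4: pass, H -> L at offset 11
```

## Command line

```sh
Rscript -e 'quit(status = mspkit::pipeline_cli())' \
  run --maf cohort.maf.tsv --store proteome.json --outdir out --n 10
```

Subcommands: `simulate-proteome`, `simulate-cohort`, `run`,
`validate-pairs`. Exit codes: 0 success, 2 panel shortfall, 1 error. The
`run` output directory contains every stage artifact (normalized variants,
rejection/exclusion logs, MSP calls, compartment tally, panel TSV + FASTA,
per-patient counts, cohort summary, sharing histogram) plus
`manifest.json`, whose config echo and seed are sufficient to re-run
identically.

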