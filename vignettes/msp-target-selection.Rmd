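---
title: "Selecting mutated surface proteins as antibody targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting mutated surface proteins as antibody targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspkit)
```

## The problem

Tumors accumulate somatic missense mutations that are almost entirely private
to each patient. A mutation whose altered residue is displayed on the cell
surface — in an extracellular domain of a membrane protein, or anywhere on
the mature chain of a secreted protein — creates a tumor-specific epitope
that an antibody can reach. A *mutated surface protein* (MSP) is exactly
that: a protein carrying a somatic missense change whose mutated residue is
antibody-accessible. Given enough MSPs per tumor, one can raise a small
panel of polyclonal antibodies, each against a short synthetic peptide
containing one mutated residue, and pool them into an oligoclonal cocktail.

`mspkit` implements the computational side of that workflow: from a somatic
variant table to residue-level localization, MSP calls, immunogen peptide
pairs, a deterministic target panel, and cohort-level prevalence and sharing
statistics.

## The MSP rule

For a variant at protein position $p$ with reference residue $r$ and
alternate residue $a$, let $L(p)$ be the residue's topological location and
$S$ the indicator that the protein is secreted. The call is

$$\text{MSP} \iff L(p) = \text{extracellular} \;\lor\;
\bigl(S \wedge L(p) \notin \{\text{signal peptide}, \text{out of bounds}\}\bigr).$$

Three deliberate choices sit inside this rule:

* **Signal peptides are excluded.** The signal peptide is cleaved during
  secretion and absent from the mature protein, so a mutation there can
  never be bound by an antibody on the product. The same applies to
  propeptides; residues covered only by a propeptide feature are reported
  under the `signal_peptide` location because the two cases are
  indistinguishable in consequence (this also resolves the fact that the
  feature vocabulary admits propeptides while the residue-location
  vocabulary does not).
* **Overlapping features resolve by precedence** transmembrane >
  extracellular > intracellular > lumenal > signal peptide, with a warning.
  Transmembrane spans are the most structurally constrained annotation, so
  when annotations disagree the membrane-embedded interpretation is the
  conservative one for antibody accessibility.
* **Reference mismatches are never MSPs.** If the annotated sequence does
  not carry the expected reference residue at $p$, the isoform or sequence
  version disagrees with the variant caller's transcript, and the
  localization cannot be trusted. Such calls keep their row (they count in
  totals) but are flagged `reference_mismatch` and forced negative.

## Annotation model

Residue-level localization needs, per gene, one canonical protein record:
the sequence, topology features as 1-based inclusive intervals, and a small
controlled vocabulary of protein-level location labels (`plasma_membrane`,
`cell_junction`, `extracellular_matrix`, `secreted`,
`intracellular_other`). Real annotation sources mix feature-level topology
and free-text location keywords and leave isoform choice to the analyst;
this package pushes both decisions into store construction so that the
pipeline itself is deterministic: a store admits at most one record per
gene, secreted status is a protein-level label (matching the way secreted
proteins are usually tallied), and unknown feature kinds or labels are load
errors rather than silently drifting categories. Genes absent from the
store are not errors — `resolve()` returns `NULL`, and `classify_cohort()`
drops and logs such variants, mirroring the practice of eliminating
entries for which no localization data can be obtained.

## Peptide windows

`design_window()` cuts a window of `length` residues (default **14**)
containing the mutated position and substitutes the alternate residue to
form the mutant/wild-type pair. The default length follows the published
immunogen pairs, which are all 14-mers even though the accompanying prose
calls them 11-mers; printed sequences were taken as authoritative and the
length left as a parameter. The default `"centered"` policy puts the
mutation at offset $\lceil \text{length}/2 \rceil$ and clamps at the
termini; published pairs show offsets 4–11 with no fixed rule, so an
explicit `window_start` override reproduces any given placement. The
synthesis sequence appends a C-terminal cysteine for carrier-protein (KLH)
conjugation. A cysteine already inside the window is a chemistry risk
(competing conjugation sites), reported as a warning and a flag, never a
failure — random sequence makes this common and a hard error would be
wrong for real proteins too. Windows may cross feature boundaries; a flag
records when they do.

`validate_pair()` is the independent check used for golden pairs: equal
length, canonical alphabet, Hamming distance exactly one, and the
substitution triple recovered by character comparison.

## Panel selection

The published procedure selected "10 distinct surface-associated mutated
proteins" without stating a ranking rule. `select_panel()` therefore uses
an explicitly artifact-level, fully deterministic rule: drop excluded
genes (e.g. known oncogenes), keep one call per gene (lowest position,
then lexicographic tie-breaks), rank extracellular-domain calls ahead of
secreted-protein calls, order by gene symbol, take the first `n`
(default 10). Identical inputs give byte-identical panels; a shortfall
returns everything eligible with a warning and a distinct exit status in
the CLI.

## Cohort statistics

* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile` type 7), the method consistent with fractional
  published medians such as 76.5 and 24.75 on even-sized cohorts; the
  method name is recorded in the output. Published "IQR" values that
  nearly equal the full range are numerically implausible as standard
  interquartile ranges and are *not* reproduced; the standard IQR and all
  quartiles are reported instead.
* **Compartment tallies** count a variant toward a category iff its
  protein carries that label, in either `overlapping` mode (a variant may
  count in several categories) or `exclusive` mode (precedence
  plasma_membrane > cell_junction > extracellular_matrix). Both are
  offered because published category percentages summing to far below
  100% are consistent with either convention. Percentages round half-up
  to one decimal; note that 153/1,354 computes to 11.3% even where 11.2%
  has been printed elsewhere — the computation is not bent to match.
* **The sharing spectrum** keys variants at the protein level
  (gene + substitution), the information the pipeline actually retains
  from MAF input; a patient contributes at most once per key. Conservation
  identities ($\sum_k h_k = $ unique keys, $\sum_k k\,h_k = $ occurrences)
  are asserted on every call. Shared-by-at-least percentages are reported
  to three decimals. Note that 12/13,488 rounds to 0.089% at three
  decimals even where 0.088% has been printed.
* **Tumor volume** is the caliper formula $V = w^2 l / 2$ (mm³), with the
  convention that width is the smaller dimension (inputs swapped with a
  warning).

## The synthetic world

`make_proteome()` / `make_cohort()` generate the fixtures every stage is
tested against, with ground truth recorded at creation:

* Proteome: 35% membrane / 15% secreted / 50% intracellular by exact
  apportionment. Membrane proteins are tiled completely and without
  overlap by alternating extracellular (25–90 aa), transmembrane
  (18–25 aa) and intracellular (10–60 aa) segments, N-terminus out;
  15% also carry the cell-junction label and 10% the extracellular-matrix
  label (20% of secreted proteins are ECM-labeled), giving the compartment
  tally something to count. Secreted proteins get a 16–30 residue signal
  peptide and an unannotated mature chain. Sequences are uniform over the
  canonical alphabet.
* Cohort: per-patient burdens are log-normal with median 75 and
  `sdlog = 0.6`, with the first 5% of patients deterministically marked
  hypermutators and multiplied by 50 — echoing cohorts whose per-patient
  missense counts span roughly 12 to several thousand. Substitutions are
  uniform over proteins, positions and the 19 non-reference residues, and
  globally unique before sharing is injected.
* Sharing is **constructed, not sampled**: a plan `{k: m}` copies exactly
  `m` chosen variants into exactly `k` patients (round-robin), so the
  measured spectrum recovers the plan with equality, not within tolerance.
  A plan that includes `k = 1` fixes the total number of unique variants
  and base variants are apportioned to patients proportionally to the
  drawn burden model.
* Ground truth (residue location, MSP flag) is computed inside the
  generator from its own construction segments — a second, independent
  implementation of the lookup — so the classifier-vs-truth agreement
  test is a real cross-check, not a tautology.

What a green suite does establish: the interval lookup, the MSP rule, the
window algebra, panel determinism and the spectrum bookkeeping are exact on
a world whose truth is known. What it does not establish: performance on
real annotation (isoform mismatches, incomplete or conflicting topology,
non-uniform mutation processes, gene-length biases) — the generator
deliberately simulates none of these, and cohort medians produced from it
are properties of the stated world, not reproductions of any published
cohort.

## Numerical and degenerate-input choices

Percentage rounding is half-up (not banker's) to match reporting style.
Empty variant sets tally to zeros with an `empty_input` flag rather than
NaN percentages. An empty cohort summary is a hard error (no patients is
unanswerable, unlike a patient with zero variants, who counts). HGVS
parsing rejects — with machine-readable reasons — stop-gains, frameshifts,
indels, synonymous changes and the ambiguous residues B/Z/X/U/O/J, since
downstream peptide synthesis requires canonical residues. Duplicate MAF
rows (same sample, gene, change — typically multi-transcript annotation)
are deduplicated and logged.

## Known limitations

No epitope accessibility, glycosylation or structural modeling; no MHC or
immunogenicity prediction; no transcript-level consequence calling (input
is already protein-annotated); no live annotation-service queries. The
sharing key is protein-level, so two genomically distinct events producing
the same protein change collapse into one key.
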