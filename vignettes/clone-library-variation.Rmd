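---
title: "Quantifying intragenomic variation in cloned amplicon libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intragenomic variation in cloned amplicon libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevar)
library(dplyr)
```

## The problem

Single-pass Sanger sequencing of a PCR product assumes the amplicon behaves
like a single-copy locus. For two of the most widely used insect marker
regions that assumption can fail in different ways: the ribosomal internal
transcribed spacer 2 (ITS2) is a multicopy region whose copies are kept
similar only as fast as concerted evolution homogenises them, and the
mitochondrial cytochrome oxidase 1 fragment (mtCO1) can be co-amplified with
nuclear pseudogene copies (numts) or, rarely, heteroplasmic variants. Cloning
the PCR product and sequencing many clones per individual exposes the hidden
variation: each clone is one molecule from the amplified pool.

`clonevar` implements the analysis of such clone libraries end to end:

1. **Haplotype collapsing** with a guard against Taq polymerase error
   (the *singleton-mutation filter*).
2. **Gap-aware p-distances** partitioned into *intragenomic* variation
   (among unique haplotypes within one individual) and *intergenomic*
   variation (among individuals of the same species).
3. **Permutation tests** for the three contrasts of interest: gene
   differences, intra- vs intergenomic variation, and sex differences.
4. **Artifact screening** of mtCO1 haplotypes for numts and heteroplasmy and
   of ITS2 haplotypes for pseudogene signals.
5. A **ground-truthed simulator** of cloned amplicon libraries, so every
   stage can be validated against known truth without any external data.

A clone set is an ordinary tibble (one row per clone: `clone_id`,
`individual_id`, `sex`, `species`, `gene`, `aligned_seq`), so the whole
pipeline composes with dplyr verbs and the pipe.

## The singleton-mutation filter

A Taq error arising in an early PCR cycle is inherited by a single cloned
molecule, so a character state seen at a site in only one clone of the pool
is the signature of polymerase error. The filter is applied at the scope of
the whole species-by-gene pool (all individuals jointly), and two readings
of "disregard single unique mutations" are supported:

* `column_mask` (default): at each alignment column, a state carried by
  exactly one clone is replaced by that column's consensus state. After
  masking, every remaining state at every column occurs zero or at least two
  times. This is the site-wise reading.
* `clone_merge`: a clone that differs from some other clone at exactly one
  column, with a pool-unique state there, is rewritten to match that clone.
  This is the clone-wise reading; it leaves multi-mutation singleton clones
  untouched, consistent with published libraries in which most single-clone
  haplotypes differ by more than one mutation.

Both are exposed because summary tables in the literature retain many
single-clone haplotypes, which a strict site-wise mask would largely
collapse; `summarize_clone_library()` therefore reports raw haplotype counts
alongside filtered ones whenever filtering is on.

## Distances: gaps as a fifth state

`p_distance()` is the uncorrected proportion of differing aligned columns,
with `-` treated as an ordinary fifth character state: a k-column indel
counts as k differences ("regardless of size"), a gap aligned to a gap is a
match and stays in the denominator, and columns containing `N` are excluded
from numerator and denominator. A `pairwise_delete` mode is provided for
comparison with tools that drop gapped columns. Distances are computed on
the distinct haplotypes by default (`unit = "unique_haplotypes"`); the
`all_clones` unit is a sensitivity analysis that re-weights by haplotype
frequency.

`partition_divergence()` reports, per individual, the mean p-distance over
all unordered pairs of units within that individual (intragenomic), and per
individual pair the mean over all cross pairs (intergenomic). Grand means
and standard errors are computed over the pooled per-pair value lists
(`SE = sd/sqrt(n)`); because pairs share sequences these SEs understate
sampling error, so pair counts are recorded for auditing. The *exceedance*
statistic is the fraction of ordered (individual, pair) comparisons —
`n(n-1)` of them, 12 in the standard four-individual design — where an
individual's intragenomic mean strictly exceeds the corresponding
intergenomic mean. All reported percentages are *truncated* (not rounded) to
one decimal, which is the convention the reference summary tables follow
(e.g. 34/44 = 77.27 prints as 77.2).

## Permutation inference

All three tests are permutation-based, assumption-free, and seed-stable:

* `perm_test_two_groups()`: difference of group means, two-sided. With
  `choose(na + nb, na)` relabellings below `exact_threshold` (default 1e5)
  the null is enumerated exactly; otherwise Monte-Carlo with the add-one
  rule `(b + 1)/(n_perm + 1)`, which cannot return 0. In the standard
  4 + 4 design the exact test has 70 relabellings, so the smallest
  attainable two-sided p is 2/70 ≈ 0.029.
* `perm_test_intra_vs_inter()`: statistic `inter_mean - intra_mean`; the
  null permutes the clone-to-individual assignment preserving per-individual
  clone counts — the natural exchangeability null for whether individual
  identity structures the clones. Monte-Carlo only.
* `perm_test_sex()`: difference of mean female and male per-individual
  intragenomic divergences, enumerated exactly over sex-label assignments.
  With 2 + 2 individuals there are only 6 assignments, so the minimum
  attainable p (2/6) is reported alongside as a design caveat. This is a
  deliberate substitute for mixed-model inference: with four individuals a
  mixed model's p-values depend entirely on parametric assumptions, and the
  exact test makes the design's resolution explicit instead.

## Artifact screening

For mtCO1 the reading frame is chosen as the frame of the degapped dominant
haplotype minimising stop codons (ties to the lowest frame), and translation
uses the invertebrate mitochondrial code (AGA/AGG = Ser, ATA = Met,
TGA = Trp; stops TAA/TAG). A haplotype is a `numt_suspect` when it carries
an in-frame stop or a frameshift (a gap run relative to the dominant whose
length is not a multiple of 3). A non-dominant haplotype that is stop- and
frameshift-free with at least `min_support` clones (default 5, anchored by a
published 38-clone heteroplasmy example) is a `heteroplasmy_candidate`.
Point mutations alone never trigger a numt call — every variant has them,
and they cannot separate numts from heteroplasmy — but their counts are
reported. For ITS2, haplotypes with at least 3 indel columns relative to the
dominant are `pseudogene_suspect`: indels in this normally length-conserved
spacer disrupt its secondary structure. The call is deliberately labelled
"suspect"; no secondary-structure analysis is attempted.

## The simulator

`simulate_clone_library()` draws a species master sequence (`make_master()`;
codon-wise and stop-free in frame 0 for mtCO1), builds each individual's
weighted template pool, and samples clones with PCR error.

* **ITS2 branch.** Each individual carries one rDNA array if male, two if
  female (haplodiploidy). Each array holds `C` copies (default 50; the true
  copy number in thrips is unknown, so this is a free parameter); a fraction
  `h` (`homogenization`) is forced identical to the array master —
  the strength of concerted evolution — and the rest mutate at the copy SNP
  and indel rates. A female's two array masters are separated by
  `between_array_divergence` expected substitutions, which is what makes the
  female-versus-male contrast non-trivial: with divergent arrays a female's
  pool mixes two lineages and her intragenomic divergence exceeds a male's.
* **mtCO1 branch.** A functional stop-free template per individual,
  an optional heteroplasmic variant (stop-free by construction, weight
  `f`), and `n_numts` numt templates. Numts are germline insertions carried
  by the population, so they are drawn once per species and shared across
  individuals; each carries a guaranteed in-frame stop (or, if
  `numt_has_stop = FALSE`, a 1-2 column frameshift deletion), so injected
  numts are detectable by construction.
* **PCR error.** Rather than simulating the branching amplification tree,
  each site of each clone mutates independently with the endpoint
  probability `q = 1 - (1 - eps)^cycles`, which matches the expected
  per-site error load of `cycles` rounds at per-cycle rate `eps`
  (the empirical Taq range is 1e-5 to 1e-4 per base per cycle; at
  `eps = 1e-4`, 35 cycles and a 655 bp amplicon this is about 2.29 errors
  per clone). Setting `eps = 0` gives exact template recovery and is used
  for calibration runs.
* **Indels are deletions only**, arising in template construction and never
  from PCR (polymerase slippage is negligible for these markers). Because an
  insertion in one copy is equivalent, up to relabeling, to deletions in all
  others, this loses no generality for the gap-as-fifth-state statistics,
  and it lets the simulator emit the *true* alignment of fixed length `L` —
  multiple sequence alignment is outside the package's scope.
* `individual_divergence` separates each individual's template lineage from
  the species master. It is the knob that controls intergenomic structure:
  0 gives a single common template pool (the exchangeable null used to
  calibrate the intra-vs-inter permutation test), larger values give
  individual-specific clusters.

Every clone gets a truth row (template of origin, template class, injected
error positions), and `write_clone_sim()` emits FASTA + metadata + truth +
the flat config, all of which re-ingest through `read_clone_set()`.

### Presets

`preset_paperlike(species, gene)` returns configurations whose *emergent*
summaries bracket the published ranges for the three thrips species: the
`FO` preset (strong homogenisation, `h = 0.97`) yields pooled ITS2 dominant
frequencies above 60%, the `SD`/`TP` presets (`h = 0.35`) yield ITS2
dominant frequencies below 35% and roughly 2-3 times more ITS2 than mtCO1
intragenomic divergence. All presets use the published design (2 females +
2 males, per-individual clone counts in the published ranges) and set the
polymerase error to 1e-5, the low end of the empirical range, so that
dominant-haplotype frequencies reflect template structure rather than PCR
noise. These parameters were calibrated once against the published summary
ranges and are not meant to be re-tuned per run.

## What passing tests do and do not show

The simulator emulates the *mechanisms* the clone-library design can probe:
multicopy variation under concerted evolution, shared numts, heteroplasmy,
haplodiploid array dosage, and polymerase error. It does not emulate
chimeric PCR recombination, alignment uncertainty (it emits the true
alignment), coalescent genealogies within populations, or insertion
polymorphism as such. Tests passing on simulated libraries therefore
validate the statistical machinery and the screening logic under known
truth; they do not certify that any real library's variation is free of
those unmodelled processes.

Two numerical caveats worth knowing:

* With a per-clone error load around 0.2, occasional clones carry two or
  more Taq errors, and independently erroneous clones can collide on the
  same column and base. Such states survive the singleton mask, and if one
  of them creates a stop codon the haplotype is (honestly) flagged
  `numt_suspect` although its template was functional — the same ambiguity
  the original cloning studies report being unable to resolve. Screening
  performance against simulator truth is therefore high but not identically
  1 across seeds.
* The `clone_merge` filter resolves merge targets deterministically
  (highest-frequency neighbour, then lexicographic), so results are
  order-invariant, as are haplotype identifiers (`H1..Hk` by descending
  count, ties by sequence).

## Worked example

```{r example, eval = FALSE}
# simulate a weakly homogenised ITS2 library and analyse it
sim <- simulate_clone_library(preset_paperlike("SD", "ITS2", seed = 1))
summarize_clone_library(sim$clones, mode = "column_mask")

ds <- partition_divergence(filter_singletons(sim$clones))
glance(ds)
perm_test_intra_vs_inter(filter_singletons(sim$clones), seed = 2)

# the same analysis, orchestrated:
bundle <- run_pipeline(list(preset_species = "SD", preset_gene = "ITS2",
                            seed = 1, out_dir = "sd_its2_report"))
bundle$table1
```

Problem sizes throughout the test-suite and the acceptance script are kept
at desk scale — libraries of 60-180 clones, permutation nulls of 199-999
replicates, 1000-replicate type-I calibrations, 2000-clone error-load
checks — chosen so that every property is measurable with comfortable
Monte-Carlo margins while the whole suite runs in well under a minute of
compute per module.

## Degenerate inputs and numerical conventions

* An individual with one unique haplotype has intragenomic divergence 0 and
  is flagged `degenerate`; it contributes no pairs to the pooled SE lists.
* A fully monomorphic clone set gives `p = 1` with a `degenerate` flag from
  the intra-vs-inter test rather than an error.
* Exact permutation p-values include the identity relabelling, so `p > 0`
  always; two-sided comparisons use `|stat| >= |observed|` with a 1e-12
  floating-point guard so mirror-image relabellings count as ties.
* Consensus ties break in the fixed order `A < C < G < T < -`; `N` never
  wins a column, is excluded from GC content and from distance
  denominators, and is ignored by the variable-site scan.
* All alignment columns are 1-based everywhere (indices, reports, error
  positions).
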