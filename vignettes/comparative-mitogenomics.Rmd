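---
title: "Comparative mitogenomics and molecular typing of holopelagic Sargassum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics and molecular typing of holopelagic Sargassum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sargtype)
```

## The study system

Two holopelagic *Sargassum* species dominate the floating macroalgal rafts of
the North Atlantic: *S. fluitans* (form *III*) and *S. natans* (forms *I* and
*VIII*). The three forms are morphologically distinct but genetically almost
identical: their complete mitochondrial genomes are collinear, 34,727 bp long,
share one gene order over 65 genes, and differ at fewer than a hundred
nucleotide positions. The two *S. natans* forms differ at just 7 sites; each
differs from *S. fluitans III* at 93 and 96 sites respectively. Because the
formerly rare form *VIII* now drives massive "golden tide" strandings, a
molecular assay that assigns a drifting clump to its form — independent of
subjective morphology — is of direct management value.

`sargtype` re-implements this comparative analysis as a reusable, tested
pipeline:

1. a packaged 98-site **variant panel** (position, locus, plus-strand allele
   per form, amino-acid chain);
2. a **constraint-solving simulator** that builds three synthetic reference
   mitogenomes realizing that panel exactly, standing in for the deposited
   sequences;
3. **scanning and annotation** operations that recover the panel from the
   sequences (the two directions meet at a round-trip contract);
4. an **in-silico PCR and typing** module built on the diagnostic cox2/cox3
   primer panel;
5. a **distance-based phylogeny** (p-distance, neighbour joining, column
   bootstrap).

## The variant panel and the chain notation

Each panel row records the three forms' plus-strand alleles in the fixed
order (*fluitans III*, *natans I*, *natans VIII*) and an amino-acid *chain*.
The chain carries one entry per run of equal alleles: alleles `C,C,T` with a
Pro-to-Ser change print as `Pro > Ser`, a synonymous change with alleles
`C,T,T` prints `Ala > Ala`, and the fully three-state site 14516 prints
`Gly > Asp > Gly`. Non-coding sites print `-`. Note the rule is allele-run
based, not amino-acid based: a synonymous change still shows two entries.

## The constraint-solving generator

The deposited genomes are not packaged, so the simulator must construct
sequences in which every panel row is *simultaneously* true. For a coding row
this is a codon constraint: there must exist a strand, an in-codon offset and
two context bases such that substituting each form's (strand-adjusted) allele
yields that form's amino acid. `solve_codon_constraint()` searches the
2 strands x 3 offsets x 64 codons space deterministically (plus strand first,
offsets ascending, codons lexicographic). Within a gene all sites must share
one strand and one reading frame; `layout_genes()` solves that joint problem
per gene and fails loudly when a toy panel is infeasible.

Several rows pin the solution space in interesting ways:

* `tatC` 7237 (`Ile > Phe`), `orf129` 10783 (`Glu > Stop`) and `rps19` 12429
  (`Gln > Lys`) admit no plus-strand solution; those genes go on the minus
  strand.
* Rows whose chain contains `Stop` (10783 and `nad7` 34589, `Stop > Stop`)
  are pinned to the **terminal codon** of their gene. This keeps the package
  invariant that no CDS in any reference contains an *internal* stop codon.
  A side effect is that the fluitans copy of `orf129` ends in `GAA` rather
  than a terminator — an accepted artefact of the surrogate layout.
* `nad7` forces the genetic-code decision. Its site 33828 (`Leu > Leu`,
  alleles C/A) is satisfiable only at codon offset 2 (context `CT`), and with
  stops restricted to TAA/TAG its site 34589 (`Stop > Stop`, alleles G/A)
  would also need offset 2; the two positions are 761 bp apart and
  761 mod 3 = 2, so one reading frame cannot host both. Allowing TGA as a
  stop places 34589 at offset 1 (`TGA -> TAA`) and the frame closes. The
  generator therefore uses the **standard genetic code**, and the single TGA
  it emits is this terminal codon. Under translation table 4 (mold/protozoan
  mitochondria) that codon would read `Trp`, so the package does not claim
  code-invariance; the brown-algal code used by the original annotation is
  not recoverable from the printed table.

### Gene layout

One feature is created per panel locus (29 CDS, 23S/16S rRNA, three tRNAs)
with deterministic padding (45 bp around CDS sites, 30 bp around rRNA sites,
71 bp tRNA features), clamped so that the nine intergenic panel sites stay
outside every feature. Placeholder trn/orf features (fixed name list, 71 or
150 bp) fill the remaining gaps up to the 65-gene complement, so synteny
comparisons are meaningful. All placement is deterministic; only sequence
content uses the seeded RNG.

### Primer footprints

The two diagnostic assays impose placement constraints: each primer footprint
must be embedded verbatim, variant-free, in all three references, with the
assay's diagnostic sites strictly between the footprints. Footprints are
anchored at fixed nominal genomic windows (cox2 forward at 21,669, reverse
end 22,075; cox3 forward at 14,400, reverse end 14,817) and shifted by the
smallest amount (search order 0, +1, -1, ...) that avoids variant codons and
avoids forcing a stop codon into the host gene's frame through the fixed
bases. With the default layout the cox2 reverse footprint shifts by +1 for
exactly that reason. The cox3 amplicon window is chosen so it contains sites
14466 and 14516 (jointly separating all three forms) and excludes 15108; a
window placed further 5' would collide with the `rps11` variant at 14111,
which is why the amplicon sits where it does. The cox2 amplicon contains four
fluitans-vs-natans sites.

### Sequence content and AT calibration

Unconstrained non-coding positions are drawn i.i.d. with P(A)=P(T)=`at_fraction`/2.
CDS codons are drawn from the 61 non-stop codons with base probabilities
recalibrated (one `uniroot` solve) so that the *conditional* AT fraction of a
non-stop codon equals the target — naive rejection of stops would bias CDS
regions AT-poor by about 1.5%. Each generated reference lands within ±0.01
of the 0.638 target, which the test suite checks. Fixed elements (ATG starts,
TAA terminators, primer footprints, solved variant codons) cover ~2% of the
genome and perturb the fraction negligibly.

## What the simulator does and does not emulate

It emulates: collinear genomes with exact planted differences, realistic gene
density and AT content, reading frames free of internal stops, amplifiable
diagnostic regions, Sanger-style amplicon cohorts with label metadata and
i.i.d. substitution noise, and the toy marker panel (18S/5.8S identical,
ITS-2 one site, rbcL three sites) matching the published negative results.

It does not emulate: indels or structural variation (the study data contain
none between forms), within-form polymorphism, chromatogram-level error
structure (miscalls are clean base substitutions, not ambiguity codes),
sequencing coverage, or the real gene coordinates — the layout is a
constraint-satisfying surrogate, not a reconstruction of the deposited
annotation. Passing tests therefore demonstrate the pipeline's correctness
on data with the study's difference structure, not robustness to assembly or
alignment artefacts.

## Typing logic

`derive_diagnostic_profiles()` restricts diagnostic sites to the region
strictly between the primer footprints, so footprint bases (variant-free by
construction) never contribute evidence. A specimen's amplicon is anchored to
the reference product (directly when lengths match, else by best ungapped
offset), the allele is read at each profile position (anything outside
A/C/G/T reads as N), and a **confident call requires a single form consistent
with every observed non-N site across all supplied assays**. Majority voting
is deliberately rejected: the biological claim being exploited is that the
sites are fixed. A haplotype matching no form is `unknown`; assays that
individually match disjoint forms yield `conflict`.

A known limitation follows from the assay design itself: the two *natans*
forms are separated by exactly one site inside the amplicons (cox3 14516),
so a substitution error at that single position converts a specimen into the
other natans form's exact expected haplotype — internally consistent and
therefore confidently miscalled. With per-base noise ε the per-specimen
probability is ε/3, and the test suite's 20-seed noise experiment does
observe such events. Per-specimen typing cannot detect them; cohort-level
`verify_fixed_sites()` can flag the resulting within-form polymorphism.
Distinguishing fluitans from either natans form rests on six sites and is
robust to single errors.

## Phylogeny

Maximum-likelihood inference over a larger taxon set is out of scope; the
package computes the desk-scale analogue for the three in-scope genomes:
p-distances over all columns (N pairwise-excluded), neighbour joining (exact
three-point branch lengths for three taxa, `ape::nj` beyond), and a
column-resampling bootstrap. An unrooted three-taxon tree has no internal
edge, so "support for the (natans I, natans VIII) grouping" is reported as
the fraction of replicates in which that pair is strictly the closest —
precisely the pair NJ agglomerates against the third taxon. For four or more
taxa standard bipartition counting is used. Degenerate inputs (all distances
tied) report support 0.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; strand complementation
  happens only at codon extraction.
* `N` is treated as missing, never as a difference, in every comparison.
* Primer matching uses a 2-mismatch tolerance with a 3-base exact 3' clamp,
  the common in-silico PCR convention; products require a unique
  plus-strand-forward / minus-strand-reverse pairing within 2 kb.
* Synteny breakpoints are orientation-aware adjacencies of one annotation
  absent from the other, counted over the shared gene set.
* All randomness flows from one integer seed; cohort and marker generation
  derive their streams from `seed + 1` and `seed + 2` so the references are
  invariant to cohort settings. Repeated runs are byte-identical, which the
  pipeline test checks on the JSON report.
* Problem sizes in the default test run: full 34,727-bp references (built
  once and cached per session), scanner oracles on 2–10 kb trios, NJ
  recovery up to 8 taxa, 1000 bootstrap replicates, and a 20-seed noise
  experiment on 71-specimen cohorts.

## A worked pass

```{r pipeline, eval = FALSE}
report <- run_pipeline(generator_config(seed = 4727), bootstrap_replicates = 200)
print(report)
write_report(report, "sargassum_report.json")
```

The report carries the pairwise difference counts (7, 93, 96), the five
genes with amino-acid differences between the natans forms (`rpl5`, `rps19`,
`rps13`, `cox3`, `nad6`), the single 23S and 16S rRNA polymorphisms, the
diagnostic profiles, the 53/13/5 typing summary with zero unknown or
conflict calls, and the bootstrapped NJ tree in Newick form — each computed,
not copied, from the packaged panel via the synthetic references.
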